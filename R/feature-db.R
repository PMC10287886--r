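#' Feature databases
#'
#' A feature database is a tibble with one row per image: a character `id`
#' column (unique), a character `label` column (the image's class), an
#' optional `source` column (path the image was read from), and one numeric
#' column per feature dimension. Row order is meaningful: it is the stable
#' tie-break order used everywhere distances are sorted, so two runs over the
#' same database always produce the same ranking.
#'
#' `feature_db()` builds a database from a feature matrix plus metadata;
#' `as_feature_db()` validates an existing data frame (e.g. the result of
#' dplyr verbs) and restores the class.
#'
#' @param features numeric matrix, one row per image, one column per feature
#'   dimension. Column names are kept if present, otherwise `f0001`, `f0002`,
#'   ... are generated.
#' @param ids character vector of unique image identifiers, one per row.
#' @param labels character vector of class labels, one per row; labels must be
#'   non-empty strings.
#' @param source optional character vector of source paths.
#' @return A tibble of class `feature_db`.
#' @examples
#' db <- feature_db(matrix(rnorm(12), 4, 3),
#'                  ids = paste0("img", 1:4),
#'                  labels = c("a", "a", "b", "b"))
#' feature_dim(db)
#' feature_matrix(db)
#' @export
feature_db <- function(features, ids, labels, source = NULL) {
  features <- as.matrix(features)
  if (!is.numeric(features)) abort("`features` must be a numeric matrix.")
  n <- nrow(features)
  if (length(ids) != n || length(labels) != n) {
    abort(sprintf("`ids` (%d) and `labels` (%d) must match nrow(features) (%d).",
                  length(ids), length(labels), n))
  }
  cn <- colnames(features)
  if (is.null(cn)) cn <- sprintf("f%04d", seq_len(ncol(features)))
  colnames(features) <- cn
  df <- tibble(id = as.character(ids), label = as.character(labels))
  if (!is.null(source)) df$source <- as.character(source)
  out <- dplyr::bind_cols(df, as_tibble(features))
  as_feature_db(out)
}

#' @rdname feature_db
#' @param x a data frame with `id`, `label` and numeric feature columns.
#' @export
as_feature_db <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  if (!all(c("id", "label") %in% names(x))) {
    abort("A feature database needs `id` and `label` columns.")
  }
  fc <- feature_cols(x)
  if (length(fc) < 1L) abort("A feature database needs at least one numeric feature column.")
  if (nrow(x) < 1L) abort("A feature database needs at least one record.")
  if (anyDuplicated(x$id)) {
    abort(sprintf("Duplicated image ids: %s.",
                  paste(unique(x$id[duplicated(x$id)]), collapse = ", ")))
  }
  if (any(is.na(x$label) | !nzchar(x$label))) abort("Class labels must be non-empty strings.")
  m <- as.matrix(x[fc])
  if (!all(is.finite(m))) abort("All feature values must be finite.")
  class(x) <- unique(c("feature_db", class(x)))
  x
}

# Feature columns are every numeric column outside the reserved metadata set.
feature_cols <- function(db) {
  reserved <- c("id", "label", "source")
  names(db)[vapply(db, is.numeric, logical(1)) & !names(db) %in% reserved]
}

#' @rdname feature_db
#' @param db a feature database.
#' @export
feature_matrix <- function(db) {
  m <- as.matrix(db[feature_cols(db)])
  rownames(m) <- db$id
  m
}

#' @rdname feature_db
#' @export
feature_dim <- function(db) length(feature_cols(db))

#' @rdname feature_db
#' @export
db_classes <- function(db) unique(db$label)

#' @export
print.feature_db <- function(x, ...) {
  cat(sprintf("# A feature database: %d images, %d classes, %d features\n",
              nrow(x), length(unique(x$label)), feature_dim(x)))
  NextMethod()
}

# Resolve a query given as id or numeric vector against a database.
# Returns list(vector, id or NA).
resolve_query <- function(db, query) {
  if (is.character(query) && length(query) == 1L) {
    i <- match(query, db$id)
    if (is.na(i)) abort(sprintf("Query id '%s' is not in the database.", query))
    list(vec = feature_matrix(db)[i, ], id = query)
  } else if (is.numeric(query)) {
    if (length(query) != feature_dim(db)) {
      abort(sprintf("Query has %d components but the database has %d feature dimensions.",
                    length(query), feature_dim(db)))
    }
    if (!all(is.finite(query))) abort("Query vector must be finite.")
    list(vec = as.numeric(query), id = NA_character_)
  } else {
    abort("`query` must be a single image id or a numeric feature vector.")
  }
}
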