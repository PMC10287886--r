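#' Euclidean distance between two feature vectors
#'
#' The similarity measure used in both stages of the retrieval pipeline:
#' \eqn{d(x, y) = \sqrt{\sum_i (x_i - y_i)^2}}. Features are compared raw —
#' no normalisation or scaling is applied before the distance.
#'
#' @param x,y numeric vectors of equal length with finite components.
#' @return A single non-negative number.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4)) # 5
#' @export
euclidean_distance <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) abort("`x` and `y` must be numeric vectors.")
  if (length(x) != length(y)) {
    abort(sprintf("Dimension mismatch: length(x) = %d, length(y) = %d.",
                  length(x), length(y)))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("All components must be finite.")
  sqrt(sum((as.numeric(x) - as.numeric(y))^2))
}

# Distances from one probe vector to every row of a matrix, in double
# precision. No sqrt shortcut here: reported distances are true Euclidean.
probe_distances <- function(m, probe) {
  unname(sqrt(rowSums(sweep(m, 2L, probe)^2)))
}

#' Rank database images by distance to a probe
#'
#' Computes the Euclidean distance from `query` to every candidate record and
#' returns them distance-ascending. Exactly tied distances keep database row
#' order, so the ranking is deterministic.
#'
#' @param db a [feature_db()].
#' @param query a single image id present in `db`, or a numeric feature
#'   vector of the database's dimension.
#' @param candidates optional character vector of ids to restrict the search
#'   to; must all be present in `db`.
#' @param exclude optional character vector of ids to drop (e.g. the query's
#'   own record).
#' @return A tibble `(rank, id, label, distance)` sorted by distance.
#' @examples
#' db <- feature_db(rbind(c(0, 5), c(0, 0), c(0, 2)),
#'                  ids = c("a", "b", "c"), labels = c("x", "x", "y"))
#' rank_images(db, c(0, 0))
#' @export
rank_images <- function(db, query, candidates = NULL, exclude = NULL) {
  db <- as_feature_db(db)
  q <- resolve_query(db, query)
  keep <- rep(TRUE, nrow(db))
  if (!is.null(candidates)) {
    missing <- setdiff(candidates, db$id)
    if (length(missing)) {
      abort(sprintf("Candidate ids not in database: %s.",
                    paste(head(missing, 5L), collapse = ", ")))
    }
    keep <- db$id %in% candidates
  }
  if (!is.null(exclude)) keep <- keep & !db$id %in% exclude
  if (!any(keep)) abort("No candidate records to rank.")
  idx <- which(keep)
  d <- probe_distances(feature_matrix(db)[idx, , drop = FALSE], q$vec)
  ord <- order(d, seq_along(d))               # stable: ties keep row order
  tibble(rank = seq_along(ord),
         id = db$id[idx][ord],
         label = db$label[idx][ord],
         distance = d[ord])
}

#' Keep the first k entries of a ranking
#'
#' @param ranked a ranking tibble as returned by [rank_images()].
#' @param k positive integer; if `k` exceeds the list length the whole list is
#'   returned.
#' @return The first `min(k, nrow(ranked))` rows, order preserved.
#' @export
top_k <- function(ranked, k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    abort("`k` must be a single integer >= 1.")
  }
  head(ranked, n = as.integer(k))
}
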