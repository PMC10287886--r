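#' Lossless on-disk feature store
#'
#' A feature store is a directory with three sidecar files: `manifest.tsv`
#' (UTF-8 TSV: `row_index`, `id`, `label`, `source`) so records stay
#' greppable and diffable; `features.feather` (Apache Arrow IPC file) holding
#' the dense feature matrix with bit-exact doubles; and `meta.json`
#' (store version, record count, dimension, feature column names, extractor
#' name if known). `read_feature_db(write_feature_db(db, path))` reproduces
#' the database exactly: ids, labels, order and every feature value.
#'
#' @param db a [feature_db()].
#' @param path store directory (created if needed).
#' @return `write_feature_db()` returns `path` invisibly;
#'   `read_feature_db()` returns the [feature_db()].
#' @examples
#' db <- simulate_feature_db(2, 3, dim = 4, separation = 10, seed = 1)
#' p <- file.path(tempdir(), "store-example")
#' read_feature_db(write_feature_db(db, p))
#' @export
write_feature_db <- function(db, path) {
  db <- as_feature_db(db)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fc <- feature_cols(db)
  manifest <- tibble(row_index = seq_len(nrow(db)), id = db$id, label = db$label,
                     source = if ("source" %in% names(db)) db$source else NA_character_)
  utils::write.table(manifest, file.path(path, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  arrow::write_feather(db[fc], file.path(path, "features.feather"))
  spec <- attr(db, "extractor")
  meta <- list(store_version = 1L, n_records = nrow(db), dim = length(fc),
               feature_names = fc,
               extractor = if (is.null(spec)) NULL else spec$name)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_feature_db
#' @export
read_feature_db <- function(path) {
  for (f in c("manifest.tsv", "features.feather", "meta.json")) {
    if (!file.exists(file.path(path, f))) {
      abort(sprintf("'%s' is not a feature store: missing %s.", path, f))
    }
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  if (is.null(meta$store_version) || meta$store_version != 1L) {
    abort(sprintf("Unknown feature store version '%s' (this package reads version 1).",
                  meta$store_version %||% "missing"))
  }
  manifest <- utils::read.table(file.path(path, "manifest.tsv"), sep = "\t",
                                header = TRUE, colClasses = "character",
                                quote = "", comment.char = "", encoding = "UTF-8")
  features <- arrow::read_feather(file.path(path, "features.feather"))
  if (nrow(manifest) != nrow(features)) {
    abort(sprintf("Corrupt store: manifest has %d rows but feature matrix has %d.",
                  nrow(manifest), nrow(features)))
  }
  if (ncol(features) != meta$dim) {
    abort(sprintf("Corrupt store: metadata declares dim %d but feature matrix has %d columns.",
                  meta$dim, ncol(features)))
  }
  src <- manifest$source
  db <- feature_db(as.matrix(features), ids = manifest$id, labels = manifest$label,
                   source = if (all(is.na(src) | src == "NA")) NULL else src)
  if (!is.null(meta$extractor)) attr(db, "extractor_name") <- meta$extractor
  db
}
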