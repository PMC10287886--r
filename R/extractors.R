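#' Feature extractor specifications
#'
#' An extractor spec names a feature extraction backend and its parameters.
#' Built in:
#'
#' * `"toy_histogram"` — a deterministic descriptor needing no pretrained
#'   weights: a `bins`-bin intensity histogram concatenated with a `bins`-bin
#'   histogram of gradient magnitudes, each block L1-normalised
#'   (`output_dim = 2 * bins`). Small, bit-stable, and class-separable on
#'   synthetic textures; intended for tests and pipeline plumbing, not for
#'   real diagnostic images.
#' * `"alexnet_fc6"`, `"vgg19_fc1"`, `"vgg19_fc2"`, `"vgg16_fc1"` — 4096-d
#'   activations of a pretrained CNN's fully connected layer. These backends
#'   require a CNN inference engine and weights that this package does not
#'   ship; requesting one raises an error explaining how to plug a backend in
#'   (never a silent fallback). Use [register_extractor()] to supply one, or
#'   load features computed elsewhere with [read_feature_db()].
#'
#' Custom extractors registered with [register_extractor()] are addressed by
#' their registered name.
#'
#' @param name extractor name.
#' @param bins histogram bins per block for `toy_histogram` (default 16).
#' @param ... further parameters passed to a registered custom extractor.
#' @return A list of class `extractor_spec` with `name`, `output_dim` and
#'   parameters.
#' @export
extractor_spec <- function(name = "toy_histogram", bins = 16, ...) {
  deep <- c(alexnet_fc6 = 4096L, vgg19_fc1 = 4096L, vgg19_fc2 = 4096L,
            vgg16_fc1 = 4096L)
  if (name == "toy_histogram") {
    if (bins < 1) abort("`bins` must be >= 1.")
    spec <- list(name = name, bins = as.integer(bins),
                 output_dim = 2L * as.integer(bins))
  } else if (name %in% names(deep)) {
    spec <- list(name = name, output_dim = deep[[name]])
  } else if (!is.null(.extractors[[name]])) {
    spec <- list(name = name, output_dim = .extractors[[name]]$output_dim,
                 params = list(...))
  } else {
    abort(sprintf("Unknown extractor '%s'. Built in: toy_histogram, %s; or register one with register_extractor().",
                  name, paste(names(deep), collapse = ", ")))
  }
  structure(spec, class = "extractor_spec")
}

.extractors <- new.env(parent = emptyenv())

#' Register a custom feature extractor backend
#'
#' Plugs an extraction function into the pipeline under a name usable in
#' [extractor_spec()]. This is the hook for deep CNN backends: wrap whatever
#' inference engine produces the fully-connected-layer activations and
#' register it here.
#'
#' @param name backend name.
#' @param fn `function(image, spec)` returning a numeric vector of length
#'   `output_dim`; must be deterministic for a fixed image and spec.
#' @param output_dim length of the returned vector.
#' @return `name`, invisibly.
#' @export
register_extractor <- function(name, fn, output_dim) {
  stopifnot(is.function(fn), output_dim >= 1)
  .extractors[[name]] <- list(fn = fn, output_dim = as.integer(output_dim))
  invisible(name)
}

#' Extract a feature vector from one image
#'
#' @param image a 2-D (grayscale) or 3-D (channels in the third dimension)
#'   numeric pixel array with finite values; channels are averaged to
#'   grayscale before the histogram descriptor.
#' @param spec an [extractor_spec()].
#' @return A numeric vector of length `spec$output_dim`.
#' @examples
#' v <- extract_features(matrix(0.5, 64, 64), extractor_spec("toy_histogram"))
#' length(v) # 32
#' @export
extract_features <- function(image, spec = extractor_spec()) {
  if (!inherits(spec, "extractor_spec")) abort("`spec` must be an extractor_spec.")
  if (!is.null(.extractors[[spec$name]])) {
    v <- .extractors[[spec$name]]$fn(image, spec)
    if (length(v) != spec$output_dim) {
      abort(sprintf("Extractor '%s' returned %d values, expected %d.",
                    spec$name, length(v), spec$output_dim))
    }
    return(as.numeric(v))
  }
  if (spec$name == "toy_histogram") return(toy_histogram(image, spec$bins))
  abort(sprintf(paste(
    "Deep backend '%s' is not available: no CNN inference engine or",
    "pretrained weights are installed. Either register a backend with",
    "register_extractor('%s', fn, output_dim = 4096) wrapping your own",
    "inference code, or compute features externally and load them with",
    "read_feature_db()."), spec$name, spec$name))
}

# bins-bin intensity histogram (+) bins-bin gradient-magnitude histogram,
# each block L1-normalised. Intensities are clamped to [0, 1]; gradient
# magnitudes of unit-range images lie in [0, sqrt(2)], the fixed bin range.
toy_histogram <- function(image, bins) {
  img <- as.array(image)
  if (!is.numeric(img) || length(img) == 0) abort("`image` must be a non-empty numeric array.")
  if (!all(is.finite(img))) abort("Pixel values must be finite.")
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  if (length(dim(img)) != 2L) abort("`image` must be a 2-D or 3-D array.")
  img <- pmin(pmax(img, 0), 1)
  h1 <- tabulate(pmin(floor(img * bins) + 1L, bins), nbins = bins)
  gx <- img[, -1, drop = FALSE] - img[, -ncol(img), drop = FALSE]
  gy <- img[-1, , drop = FALSE] - img[-nrow(img), , drop = FALSE]
  k <- min(nrow(gx), nrow(gy)); l <- min(ncol(gx), ncol(gy))
  g <- sqrt(gx[seq_len(k), seq_len(l), drop = FALSE]^2 +
            gy[seq_len(k), seq_len(l), drop = FALSE]^2)
  h2 <- tabulate(pmin(floor(g / sqrt(2) * bins) + 1L, bins), nbins = bins)
  l1 <- function(h) if (sum(h) > 0) h / sum(h) else h
  c(l1(h1), l1(h2))
}

#' Extract a feature database from a labelled image tree
#'
#' Walks `image_root`, which must contain one subdirectory per class, each
#' holding at least one readable image (PNG or TIFF with the installed
#' readers). Records are ordered by sorted (class, filename) so the resulting
#' database — and hence all downstream tie-breaking — is identical across
#' machines. Ids are `<class>/<filename>`.
#'
#' @param image_root directory with layout `<root>/<class>/<image>`.
#' @param spec an [extractor_spec()].
#' @param strict if `FALSE` (default), unreadable files are skipped with a
#'   warning and counted; if `TRUE`, the first unreadable file aborts.
#' @return A [feature_db()]; the number of skipped files is in attribute
#'   `"n_skipped"`.
#' @export
extract_database <- function(image_root, spec = extractor_spec(), strict = FALSE) {
  if (!dir.exists(image_root)) abort(sprintf("'%s' is not a directory.", image_root))
  classes <- sort(list.dirs(image_root, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) abort(sprintf("'%s' has no class subdirectories.", image_root))
  rows <- list(); ids <- character(); labels <- character(); paths <- character()
  n_skipped <- 0L
  for (cl in classes) {
    files <- sort(list.files(file.path(image_root, cl)))
    if (length(files) == 0) abort(sprintf("Class directory '%s' is empty.", cl))
    for (f in files) {
      p <- file.path(image_root, cl, f)
      img <- tryCatch(read_image(p), error = function(e) e)
      if (inherits(img, "error")) {
        if (strict) abort(sprintf("Failed to read '%s': %s", p, conditionMessage(img)))
        warn(sprintf("Skipping unreadable image '%s': %s", p, conditionMessage(img)))
        n_skipped <- n_skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- extract_features(img, spec)
      ids <- c(ids, paste0(cl, "/", f)); labels <- c(labels, cl); paths <- c(paths, p)
    }
  }
  if (length(rows) == 0) abort("No readable images found.")
  db <- feature_db(do.call(rbind, rows), ids = ids, labels = labels, source = paths)
  attr(db, "extractor") <- spec
  attr(db, "n_skipped") <- n_skipped
  db
}

# PNG and TIFF are the formats with pre-installed readers; other extensions
# error (DICOM/JPEG would need a reader this environment does not provide).
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    abort(sprintf("Unsupported image format '.%s' (supported: png, tif/tiff).", ext))
  }
}
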