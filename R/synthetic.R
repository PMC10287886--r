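#' Simulate a class-clustered feature database
#'
#' Generates a Gaussian-cluster stand-in for a labelled image feature
#' database: class centres sit on scaled orthogonal axes so that every pair of
#' centres is exactly `separation` apart, and each class's vectors are drawn
#' from an isotropic normal with standard deviation `sigma` around its
#' centre. The ratio `separation / sigma` controls how retrievable the
#' classes are: at large ratios every neighbourhood is pure, near zero the
#' labels are uninformative.
#'
#' Each class draws from its own RNG substream derived from `seed`, so adding
#' a class leaves earlier classes' vectors unchanged. The same spec always
#' yields the identical database.
#'
#' @param n_classes number of classes; labels are `class_00`, `class_01`, ...
#' @param class_sizes one size per class, or a single size recycled.
#' @param dim feature dimension; must be at least `n_classes` (the centres
#'   use orthogonal axes).
#' @param separation distance between every pair of class centres.
#' @param sigma within-class standard deviation per component (> 0).
#' @param seed integer seed.
#' @return A [feature_db()] with `n_classes * sum(class_sizes)` records,
#'   ordered by (class, index), with attribute `"centers"` holding the true
#'   class centres.
#' @examples
#' db <- simulate_feature_db(n_classes = 4, class_sizes = c(75, 50, 58, 41),
#'                           dim = 64, separation = 50, sigma = 1, seed = 7)
#' nrow(db) # 224
#' @export
simulate_feature_db <- function(n_classes, class_sizes, dim,
                                separation, sigma = 1, seed = 1) {
  if (n_classes < 1) abort("`n_classes` must be >= 1.")
  if (dim < n_classes) {
    abort(sprintf(paste("`dim` (%d) must be >= `n_classes` (%d) for",
                        "orthogonal-axis centre placement; increase `dim`."),
                  dim, n_classes))
  }
  if (separation < 0) abort("`separation` must be non-negative.")
  if (sigma <= 0) abort("`sigma` must be positive.")
  class_sizes <- rep_len(as.integer(class_sizes), n_classes)
  if (any(class_sizes < 1)) abort("All class sizes must be >= 1.")

  labels <- sprintf("class_%02d", seq_len(n_classes) - 1L)
  # pairwise distance between scaled axes e_i, e_j is s*sqrt(2), so scale
  # by separation/sqrt(2) to make every pair exactly `separation` apart
  centers <- matrix(0, n_classes, dim)
  for (c in seq_len(n_classes)) centers[c, c] <- separation / sqrt(2)
  rownames(centers) <- labels

  blocks <- vector("list", n_classes)
  for (c in seq_len(n_classes)) {
    m <- with_local_seed(substream_seed(seed, c), {
      matrix(rnorm(class_sizes[c] * dim, sd = sigma),
             class_sizes[c], dim, byrow = TRUE)
    })
    blocks[[c]] <- sweep(m, 2L, centers[c, ], `+`)
  }
  features <- do.call(rbind, blocks)
  ids <- unlist(lapply(seq_len(n_classes), function(c)
    sprintf("%s_%03d", labels[c], seq_len(class_sizes[c]))))
  db <- feature_db(features, ids = ids, labels = rep(labels, class_sizes))
  attr(db, "centers") <- centers
  db
}

# One substream per class, derived from the global seed with a fixed prime
# stride; kept inside 32-bit integer range.
substream_seed <- function(seed, class_index) {
  as.integer((as.numeric(seed) + 7919 * class_index) %% .Machine$integer.max)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a small synthetic labelled image tree
#'
#' Creates `<out_dir>/<class>/<i>.png` with one texture family per class:
#' each class has a distinct mean intensity and a distinct oriented grating
#' frequency, plus per-pixel uniform noise. The classes are separable by the
#' histogram descriptor at low noise, which makes the tree a self-contained
#' end-to-end fixture for extraction and retrieval.
#'
#' @param n_classes number of classes.
#' @param per_class images per class.
#' @param size image side length in pixels (square, default 64).
#' @param noise amplitude of the added uniform pixel noise (default 0.02).
#' @param seed integer seed; the same seed writes byte-identical images.
#' @param out_dir output directory.
#' @param force overwrite a non-empty `out_dir` (default `FALSE`: error).
#' @return `out_dir`, invisibly.
#' @export
simulate_image_tree <- function(n_classes, per_class, size = 64, noise = 0.02,
                                seed = 1, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force) {
    abort(sprintf("Output directory '%s' is non-empty; use `force = TRUE`.", out_dir))
  }
  xy <- outer(rep(1, size), seq_len(size)) / size
  for (c in seq_len(n_classes)) {
    label <- sprintf("class_%02d", c - 1L)
    cdir <- file.path(out_dir, label)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    base_mean <- 0.15 + 0.7 * (c - 1) / max(1, n_classes - 1)
    freq <- 2 + 3 * c
    phase_dir <- if (c %% 2 == 0) xy else t(xy)     # alternate orientation
    with_local_seed(substream_seed(seed, c), {
      for (i in seq_len(per_class)) {
        img <- base_mean + 0.12 * sin(2 * pi * freq * phase_dir) +
          matrix(runif(size^2, -noise, noise), size, size)
        img <- pmin(pmax(img, 0), 1)
        png::writePNG(img, file.path(cdir, sprintf("%03d.png", i)))
      }
    })
  }
  invisible(out_dir)
}

#' Worked six-component centroid example
#'
#' A small fixed fixture for the centroid expansion: five single-class
#' feature vectors truncated to six named components (`F1`...`F5`, `F4096`)
#' together with the component-wise mean they must produce. Useful as an
#' exactness check of [query_expansion()] at printed rounding.
#'
#' @return A list with `db` (a 5-record, 6-dimension [feature_db()], class
#'   `"example"`) and `expected_mean` (named numeric of length 6).
#' @examples
#' fx <- centroid_worked_example()
#' query_expansion(fx$db, fx$db$id)$mean_vector
#' @export
centroid_worked_example <- function() {
  members <- rbind(
    Img1 = c(0.99, -15.05, -5.02, -41.11, -23.11, 6.76),
    Img2 = c(2.21, -12.71, -3.55, -43.14, -23.29, 8.57),
    Img3 = c(-1.29, -13.40, -7.85, -39.39, -28.45, 8.29),
    Img4 = c(-1.48, -11.07, -3.12, -37.64, -23.31, 13.11),
    Img5 = c(-6.69, -7.70, 1.03, -40.86, -22.97, 6.07))
  colnames(members) <- c("F1", "F2", "F3", "F4", "F5", "F4096")
  list(
    db = feature_db(members, ids = rownames(members),
                    labels = rep("example", 5)),
    expected_mean = c(F1 = -1.252, F2 = -11.986, F3 = -3.702,
                      F4 = -40.428, F5 = -24.226, F4096 = 8.56))
}
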