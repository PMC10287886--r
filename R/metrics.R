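#' Retrieval precision and recall at a cutoff
#'
#' Relevance is class membership: a retrieved image is relevant iff its class
#' equals the query's class. `precision_at()` divides the relevant count by
#' the number of images retrieved; `recall_at()` divides it by the number of
#' images of the query's class in the whole database.
#'
#' @param db a [feature_db()].
#' @param result_ids ids of the retrieved images, best first.
#' @param query_class the query image's class label.
#' @return A fraction in `[0, 1]`.
#' @export
precision_at <- function(db, result_ids, query_class) {
  db <- as_feature_db(db)
  if (length(result_ids) < 1L) abort("`result_ids` must be non-empty.")
  lab <- db$label[match(result_ids, db$id)]
  if (anyNA(lab)) {
    abort(sprintf("Result ids not in database: %s.",
                  paste(result_ids[is.na(lab)], collapse = ", ")))
  }
  sum(lab == query_class) / length(result_ids)
}

#' @rdname precision_at
#' @export
recall_at <- function(db, result_ids, query_class) {
  db <- as_feature_db(db)
  total <- sum(db$label == query_class)
  if (total == 0L) abort(sprintf("Class '%s' is absent from the database.", query_class))
  lab <- db$label[match(result_ids, db$id)]
  if (anyNA(lab)) {
    abort(sprintf("Result ids not in database: %s.",
                  paste(result_ids[is.na(lab)], collapse = ", ")))
  }
  sum(lab == query_class) / total
}

#' F-score of average precision and average recall
#'
#' Harmonic mean of the two averages, on the same percent scale:
#' \eqn{F = 2 \cdot ARP \cdot ARR / (ARP + ARR)}. When both inputs are zero
#' the harmonic mean is undefined; it is reported as 0 with a warning.
#'
#' @param arp,arr average retrieval precision / rate, in percent (vectorised).
#' @return F-score in percent.
#' @examples
#' f_score(40, 40)        # 40
#' f_score(66.91, 9.74)   # 17.00...
#' @export
f_score <- function(arp, arr) {
  if (any(arp < 0 | arr < 0)) abort("`arp` and `arr` must be non-negative.")
  out <- ifelse(arp + arr == 0, 0, 2 * arp * arr / (arp + arr))
  if (any(arp + arr == 0)) warn("F-score at ARP = ARR = 0 reported as 0.")
  out
}

#' Whole-database retrieval evaluation
#'
#' Runs the standard protocol: every image in the database serves once as the
#' query, an image is relevant iff it shares the query's class, and precision
#' and recall at each cutoff are averaged over all queries. ARP (average
#' retrieval precision) and ARR (average retrieval rate) are those means on a
#' percent scale; the F-score is their harmonic mean. Per-class (group-wise)
#' ARP averages only over that class's queries.
#'
#' @inheritParams retrieve
#' @param n integer vector of cutoffs (default `1:10`); metrics are reported
#'   at each.
#' @param per_query if `TRUE`, keep the per-query precision/recall table.
#' @return An object of class `retrieval_eval`: list with `metrics` (tibble
#'   `n, arp, arr, f_score`), `per_class` (tibble `label, n_queries, n, arp`),
#'   `per_query` (tibble or `NULL`) and the call parameters.
#' @examples
#' db <- simulate_feature_db(n_classes = 3, class_sizes = 10, dim = 8,
#'                           separation = 60, sigma = 1, seed = 1)
#' ev <- evaluate_retrieval(db, method = "direct", n = c(1, 5, 10))
#' tidy(ev)
#' @export
evaluate_retrieval <- function(db, method = c("expansion", "direct"),
                               k = 10, n = 1:10, include_query = TRUE,
                               restrict_to_class = FALSE, per_query = FALSE) {
  db <- as_feature_db(db)
  method <- match.arg(method)
  if (nrow(db) < 2L) abort("Evaluation needs at least 2 records.")
  n <- sort(unique(as.integer(n)))
  if (any(n < 1L)) abort("Cutoffs must be >= 1.")
  n_max <- max(n)
  class_sizes <- table(db$label)

  one_query <- function(qid) {
    res <- retrieve(db, qid, method = method, k = k, n = n_max,
                    include_query = include_query,
                    restrict_to_class = restrict_to_class)
    rel <- cumsum(res$ranking$label == db$label[match(qid, db$id)])
    navail <- nrow(res$ranking)
    at <- pmin(n, navail)
    tibble(query_id = qid,
           label = db$label[match(qid, db$id)],
           n = n,
           precision = rel[at] / at,
           recall = rel[at] / as.integer(class_sizes[[db$label[match(qid, db$id)]]]))
  }
  pq <- purrr::map_dfr(db$id, one_query)

  metrics <- pq |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(arp = 100 * mean(.data$precision),
                     arr = 100 * mean(.data$recall), .groups = "drop") |>
    dplyr::mutate(f_score = f_score(.data$arp, .data$arr))
  per_class <- pq |>
    dplyr::group_by(.data$label, .data$n) |>
    dplyr::summarise(n_queries = dplyr::n(),
                     arp = 100 * mean(.data$precision),
                     arr = 100 * mean(.data$recall), .groups = "drop")

  structure(
    list(metrics = metrics, per_class = per_class,
         per_query = if (per_query) pq else NULL,
         method = method, k = as.integer(k), cutoffs = n,
         include_query = include_query, n_images = nrow(db)),
    class = "retrieval_eval")
}

#' @export
print.retrieval_eval <- function(x, ...) {
  cat(sprintf("<retrieval_eval> method '%s', %d images as queries, k = %d\n",
              x$method, x$n_images, x$k))
  print(dplyr::mutate(x$metrics, dplyr::across(c("arp", "arr", "f_score"),
                                               ~ round(.x, 2))))
  invisible(x)
}

#' @describeIn evaluate_retrieval overall metrics, one row per cutoff.
#' @param x a `retrieval_eval` object.
#' @param ... unused.
#' @export
tidy.retrieval_eval <- function(x, ...) x$metrics

#' @describeIn evaluate_retrieval one-row summary at the largest cutoff.
#' @export
glance.retrieval_eval <- function(x, ...) {
  last <- dplyr::filter(x$metrics, .data$n == max(.data$n))
  tibble(method = x$method, n_images = x$n_images, k = x$k,
         n = last$n, arp = last$arp, arr = last$arr, f_score = last$f_score)
}

#' @describeIn evaluate_retrieval ARP/ARR/F curves over the cutoffs.
#' @param object a `retrieval_eval` object.
#' @export
autoplot.retrieval_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("arp", "arr", "f_score"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$cutoffs) +
    ggplot2::labs(x = "top-N cutoff", y = "percent",
                  title = sprintf("Retrieval performance (%s)", object$method)) +
    ggplot2::theme_minimal()
}

#' Write an evaluation report to CSV or JSON
#'
#' CSV holds the overall rows followed by per-class rows (column `label`,
#' empty for overall); JSON holds the same two tables under `metrics` and
#' `per_class` keys.
#'
#' @param x a `retrieval_eval` object.
#' @param path output file; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  overall <- dplyr::mutate(x$metrics, label = "", n_queries = x$n_images,
                           .before = 1)
  per_class <- dplyr::mutate(x$per_class, f_score = f_score(.data$arp, .data$arr))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(method = x$method, k = x$k,
                              metrics = x$metrics, per_class = per_class),
                         path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    both <- dplyr::bind_rows(overall,
                             dplyr::select(per_class, "label", "n_queries",
                                           "n", "arp", "arr", "f_score"))
    utils::write.csv(both, path, row.names = FALSE)
  }
  invisible(path)
}
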