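#' Per-class top-k rapid search
#'
#' The first stage of the expanded search: for every class in the database,
#' find the k images of that class closest to the query. Implemented as one
#' global ranking filtered by class, which is equivalent to ranking each class
#' separately (the relative order within a class is the same) but needs a
#' single scan.
#'
#' @inheritParams rank_images
#' @param k images kept per class (default 10). Classes with fewer than `k`
#'   members contribute all of their members.
#' @return A tibble `(label, rank, id, distance)` with `rank` restarting at 1
#'   within each class, distance-ascending, ties in database row order.
#' @export
per_class_top_k <- function(db, query, k = 10, exclude = NULL) {
  db <- as_feature_db(db)
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 1) {
    abort("`k` must be a single integer >= 1.")
  }
  ranked <- rank_images(db, query, exclude = exclude)
  ranked |>
    dplyr::group_by(.data$label) |>
    dplyr::slice_head(n = as.integer(k)) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("label", "rank", "id", "distance")
}

#' Build a class-centroid query expansion
#'
#' Averages the feature vectors of the given member images component-wise.
#' The result is a reformulated query for that class: its j-th component is
#' the arithmetic mean of the members' j-th components, accumulated in double
#' precision.
#'
#' @param db a [feature_db()].
#' @param member_ids ids of the member images, in rank order; all must exist
#'   in `db` and carry `label`.
#' @param label the class the members belong to. Defaults to the members'
#'   common label.
#' @return An object of class `query_expansion`: a list with `label`,
#'   `mean_vector` (named numeric) and `member_ids`.
#' @examples
#' db <- feature_db(rbind(c(1, 2), c(3, 6)), ids = c("a", "b"),
#'                  labels = c("x", "x"))
#' query_expansion(db, c("a", "b"))$mean_vector # c(2, 4)
#' @export
query_expansion <- function(db, member_ids, label = NULL) {
  db <- as_feature_db(db)
  if (length(member_ids) < 1L) abort("`member_ids` must be non-empty.")
  i <- match(member_ids, db$id)
  if (anyNA(i)) {
    abort(sprintf("Member ids not in database: %s.",
                  paste(member_ids[is.na(i)], collapse = ", ")))
  }
  labels <- db$label[i]
  if (is.null(label)) {
    label <- unique(labels)
    if (length(label) != 1L) {
      abort("Members span several classes; pass `label` only with same-class members.")
    }
  } else if (!all(labels == label)) {
    abort(sprintf("Members %s do not carry class '%s'.",
                  paste(member_ids[labels != label], collapse = ", "), label))
  }
  m <- feature_matrix(db)[i, , drop = FALSE]
  structure(
    list(label = label,
         mean_vector = colMeans(m),
         member_ids = as.character(member_ids)),
    class = "query_expansion")
}

#' @export
print.query_expansion <- function(x, ...) {
  cat(sprintf("<query_expansion> class '%s', %d members, dim %d\n",
              x$label, length(x$member_ids), length(x$mean_vector)))
  invisible(x)
}

#' Select the final expansion closest to the original query
#'
#' Among the candidate class centroids, picks the one whose mean vector has
#' the smallest Euclidean distance to the query. Ties are broken by position
#' in `expansions` (which follows database class order), so selection is
#' deterministic.
#'
#' @param query numeric feature vector of the original query.
#' @param expansions a list of [query_expansion()] objects.
#' @return The selected `query_expansion`, with an extra `distance` element
#'   recording its distance to the query.
#' @export
select_expansion <- function(query, expansions) {
  if (length(expansions) < 1L) abort("`expansions` must be non-empty.")
  d <- vapply(expansions, function(e) euclidean_distance(query, e$mean_vector),
              numeric(1))
  best <- which.min(d)                        # which.min takes the first tie
  out <- expansions[[best]]
  out$distance <- d[[best]]
  out
}

#' Two-stage retrieval with automatic query expansion
#'
#' Runs the full pipeline on a labelled feature database. With
#' `method = "expansion"` (the default) the search has two stages: a rapid
#' per-class top-`k` search with the original query; a class-centroid
#' expansion (mean of each class's top-ranked members); selection of the
#' centroid closest to the query; and a final search ranking the whole
#' database against the selected centroid. With `method = "direct"` the query
#' vector itself ranks the database, with no expansion.
#'
#' The process is fully automatic pseudo-relevance feedback: no user marks
#' results as relevant, the per-class top ranks stand in for relevance
#' judgements.
#'
#' @inheritParams per_class_top_k
#' @param method `"expansion"` (two-stage, default) or `"direct"`.
#' @param n number of images to return from the final search (default 10).
#' @param include_query keep the query's own record in both stages when the
#'   query is a database member (default `TRUE`, the whole-database evaluation
#'   protocol; its self-match then ranks first at distance 0).
#' @param restrict_to_class if `TRUE`, the final search ranks only the
#'   selected centroid's class instead of the full database (default `FALSE`).
#' @return An object of class `retrieval`: list with `query_id`, `method`,
#'   `ranking` (tibble), `expansion` (the selected centroid, expansion method
#'   only), `class_expansions` (all candidates), `k`, `n`.
#' @examples
#' db <- simulate_feature_db(n_classes = 3, class_sizes = 12, dim = 8,
#'                           separation = 60, sigma = 1, seed = 1)
#' res <- retrieve(db, db$id[1], k = 10, n = 5)
#' tidy(res)
#' @export
retrieve <- function(db, query, method = c("expansion", "direct"),
                     k = 10, n = 10, include_query = TRUE,
                     restrict_to_class = FALSE) {
  db <- as_feature_db(db)
  method <- match.arg(method)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    abort("`n` must be a single integer >= 1.")
  }
  q <- resolve_query(db, query)
  exclude <- if (!include_query && !is.na(q$id)) q$id else NULL

  expansion <- NULL
  class_expansions <- NULL
  if (method == "direct") {
    probe <- q$vec
  } else {
    rapid <- per_class_top_k(db, q$vec, k = k, exclude = exclude)
    class_expansions <- lapply(
      split(rapid$id, factor(rapid$label, levels = unique(rapid$label))),
      function(ids) query_expansion(db, ids))
    expansion <- select_expansion(q$vec, unname(class_expansions))
    probe <- expansion$mean_vector
  }
  candidates <- if (isTRUE(restrict_to_class) && !is.null(expansion)) {
    setdiff(db$id[db$label == expansion$label], exclude)
  } else NULL
  ranking <- top_k(rank_images(db, probe, candidates = candidates,
                               exclude = exclude), n)
  structure(
    list(query_id = q$id, method = method, ranking = ranking,
         expansion = expansion, class_expansions = class_expansions,
         k = as.integer(k), n = as.integer(n)),
    class = "retrieval")
}

#' @export
print.retrieval <- function(x, ...) {
  cat(sprintf("<retrieval> query '%s', method '%s'%s\n",
              ifelse(is.na(x$query_id), "external", x$query_id), x$method,
              if (!is.null(x$expansion))
                sprintf(", expansion class '%s'", x$expansion$label) else ""))
  print(x$ranking)
  invisible(x)
}

#' @describeIn retrieve the final ranking as a tibble, one row per retrieved
#'   image.
#' @param x a `retrieval` object.
#' @param ... unused.
#' @export
tidy.retrieval <- function(x, ...) x$ranking

#' @describeIn retrieve one-row summary: query id, method, selected expansion
#'   class and its distance to the query.
#' @export
glance.retrieval <- function(x, ...) {
  tibble(query_id = x$query_id, method = x$method,
         expansion_class = if (is.null(x$expansion)) NA_character_ else x$expansion$label,
         expansion_distance = if (is.null(x$expansion)) NA_real_ else x$expansion$distance,
         k = x$k, n = x$n)
}

#' @describeIn retrieve distance-vs-rank plot of the final ranking, coloured
#'   by class label.
#' @param object a `retrieval` object.
#' @export
autoplot.retrieval <- function(object, ...) {
  ggplot2::ggplot(object$ranking,
                  ggplot2::aes(x = .data$rank, y = .data$distance,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linewidth = 0.3) +
    ggplot2::labs(x = "rank", y = "Euclidean distance", colour = "class",
                  title = sprintf("Retrieval (%s) for query %s",
                                  object$method,
                                  ifelse(is.na(object$query_id), "external",
                                         object$query_id))) +
    ggplot2::theme_minimal()
}
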