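test_that("per-class top-k matches filtering a global ranking by class", {
  db <- rand_db(80, dim = 8, n_classes = 4, seed = 21)
  probe <- feature_matrix(db)[3, ]
  got <- per_class_top_k(db, probe, k = 5)
  glob <- rank_images(db, probe)
  for (cl in db_classes(db)) {
    want <- head(glob$id[glob$label == cl], 5)
    expect_identical(got$id[got$label == cl], want)
  }
})

test_that("per-class top-k returns whole classes smaller than k", {
  db <- feature_db(matrix(rnorm(5 * 3), 5, 3),
                   ids = letters[1:5], labels = c("x", "x", "x", "y", "y"))
  got <- per_class_top_k(db, rnorm(3), k = 10)
  expect_identical(sum(got$label == "x"), 3L)
  expect_identical(sum(got$label == "y"), 2L)
  # a database member ranks first within its own class
  got2 <- per_class_top_k(db, "d", k = 10)
  expect_identical(got2$id[got2$label == "y" & got2$rank == 1], "d")
})

test_that("centroid expansion is the component-wise mean", {
  fx <- centroid_worked_example()
  qe <- query_expansion(fx$db, fx$db$id)
  expect_identical(round(qe$mean_vector, 3), round(fx$expected_mean, 3))
  expect_identical(qe$label, "example")
  expect_identical(qe$member_ids, fx$db$id)

  # single member: identity
  db <- rand_db(10, dim = 5, seed = 31)
  expect_equal(query_expansion(db, db$id[4])$mean_vector,
               feature_matrix(db)[4, ])

  # 20 random vectors vs a one-component-at-a-time oracle
  db20 <- feature_db(matrix(rnorm(20 * 7), 20, 7),
                     ids = sprintf("m%02d", 1:20), labels = rep("z", 20))
  qe20 <- query_expansion(db20, db20$id)
  m <- feature_matrix(db20)
  for (j in seq_len(ncol(m))) {
    s <- 0
    for (i in seq_len(nrow(m))) s <- s + m[i, j]
    expect_equal(unname(qe20$mean_vector[j]), s / nrow(m))
  }
})

test_that("expansion rejects empty or mixed-class member sets", {
  db <- rand_db(10, dim = 4, n_classes = 2, seed = 32)
  expect_error(query_expansion(db, character(0)), "non-empty")
  expect_error(query_expansion(db, "ghost"), "not in database")
  two_classes <- db$id[match(c("c01", "c02"), db$label)]
  expect_error(query_expansion(db, two_classes, label = "c01"), "do not carry")
})

test_that("final-expansion selection is the distance argmin with first-tie wins", {
  db <- feature_db(rbind(c(3, 4), c(5, 12)), ids = c("a", "b"),
                   labels = c("x", "y"))
  e1 <- query_expansion(db, "a"); e2 <- query_expansion(db, "b")
  sel <- select_expansion(c(0, 0), list(e1, e2))
  expect_identical(sel$label, "x")
  expect_identical(sel$distance, 5)
  # query equal to a mean -> that expansion, distance 0
  sel0 <- select_expansion(c(5, 12), list(e1, e2))
  expect_identical(sel0$label, "y")
  expect_identical(sel0$distance, 0)
  # exact tie: first in list order wins
  tied <- select_expansion(c(4, 8), list(e1, e2))
  expect_identical(tied$label, "x")

  set.seed(33)
  means <- lapply(1:10, function(i) rnorm(6))
  dbm <- feature_db(do.call(rbind, means), ids = sprintf("e%02d", 1:10),
                    labels = sprintf("c%02d", 1:10))
  qes <- lapply(dbm$id, function(id) query_expansion(dbm, id))
  q <- rnorm(6)
  d <- vapply(means, function(m) oracle_distance(q, m), numeric(1))
  expect_identical(select_expansion(q, qes)$label,
                   dbm$label[which.min(d)])
  expect_error(select_expansion(q, list()), "non-empty")
})

test_that("two-stage retrieval reproduces the worked-example centroid", {
  fx <- centroid_worked_example()
  res <- retrieve(fx$db, feature_matrix(fx$db)["Img1", ], k = 5, n = 5)
  expect_identical(round(res$expansion$mean_vector, 3),
                   round(fx$expected_mean, 3))
  expect_identical(res$expansion$label, "example")
  # single class: final ranking equals direct ranking against the class mean
  expect_identical(res$ranking,
                   top_k(rank_images(fx$db, res$expansion$mean_vector), 5))
})

test_that("well-separated clusters give pure retrievals of the query's class", {
  db <- simulate_feature_db(n_classes = 4, class_sizes = 12, dim = 16,
                            separation = 60, sigma = 1, seed = 17)
  for (qid in db$id[c(1, 13, 25, 40)]) {
    res <- retrieve(db, qid, k = 10, n = 10)
    expect_identical(res$expansion$label, db$label[match(qid, db$id)])
    expect_true(all(res$ranking$label == db$label[match(qid, db$id)]))
  }
})

test_that("k = 1 with the query kept makes the selected centroid the query itself", {
  db <- rand_db(30, dim = 6, n_classes = 3, seed = 41)
  qid <- db$id[7]
  res <- retrieve(db, qid, k = 1, n = 5, include_query = TRUE)
  expect_equal(res$expansion$mean_vector, feature_matrix(db)[7, ])
  expect_identical(res$expansion$distance, 0)
  expect_identical(res$ranking$id[1], qid)
})

test_that("retrieval is deterministic and invariant to class relabelling", {
  db <- rand_db(40, dim = 6, n_classes = 4, seed = 43)
  r1 <- retrieve(db, db$id[5], k = 5, n = 10)
  r2 <- retrieve(db, db$id[5], k = 5, n = 10)
  expect_identical(r1$ranking, r2$ranking)

  relab <- setNames(sprintf("renamed_%s", db_classes(db)), db_classes(db))
  db2 <- as_feature_db(dplyr::mutate(db, label = unname(relab[label])))
  r3 <- retrieve(db2, db2$id[5], k = 5, n = 10)
  expect_identical(r3$ranking$id, r1$ranking$id)
  expect_identical(r3$ranking$distance, r1$ranking$distance)
  expect_identical(r3$expansion$label, unname(relab[r1$expansion$label]))
})

test_that("query exclusion removes the self-match from both stages", {
  db <- rand_db(30, dim = 6, n_classes = 3, seed = 44)
  qid <- db$id[2]
  res <- retrieve(db, qid, k = 5, n = 29, include_query = FALSE)
  expect_false(qid %in% res$ranking$id)
  member_ids <- unlist(lapply(res$class_expansions, function(e) e$member_ids))
  expect_false(qid %in% member_ids)
})

test_that("restricting the final search to the selected class filters the ranking", {
  db <- simulate_feature_db(n_classes = 3, class_sizes = 8, dim = 8,
                            separation = 40, sigma = 1, seed = 45)
  res <- retrieve(db, db$id[1], k = 5, n = 24, restrict_to_class = TRUE)
  expect_true(all(res$ranking$label == res$expansion$label))
  expect_lte(nrow(res$ranking), 8)
})

test_that("retrieval accessors tidy and glance expose the result", {
  db <- rand_db(20, dim = 4, seed = 46)
  res <- retrieve(db, db$id[1], k = 3, n = 5)
  expect_identical(tidy(res), res$ranking)
  g <- glance(res)
  expect_identical(g$query_id, db$id[1])
  expect_identical(g$method, "expansion")
  expect_error(retrieve(db, "absent"), "not in the database")
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
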