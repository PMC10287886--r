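# Random labelled feature database for property tests.
rand_db <- function(n = 50, dim = 8, n_classes = 4, seed = 1) {
  set.seed(seed)
  feature_db(matrix(rnorm(n * dim), n, dim),
             ids = sprintf("img%03d", seq_len(n)),
             labels = sample(sprintf("c%02d", seq_len(n_classes)), n,
                             replace = TRUE))
}

# Independent brute-force oracles, deliberately written as plain loops so
# they share no code with the package internals.
oracle_distance <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[[i]] - y[[i]])^2
  sqrt(s)
}

oracle_ranking <- function(db, probe) {
  m <- feature_matrix(db)
  d <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) d[i] <- oracle_distance(m[i, ], probe)
  ord <- sort.list(d, method = "radix")   # stable sort by construction
  data.frame(id = db$id[ord], distance = d[ord])
}
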