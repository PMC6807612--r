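test_that("signal assignment follows the per-mode rules", {
  el <- granges0("chr1", c(1000, 50000), c(2000, 51000))
  pk <- granges0("chr1", c(1100, 1500, 900), c(1300, 1900, 1050))
  S4Vectors::mcols(pk)$value <- c(5, 9, 2)
  expect_equal(assign_signal(el, pk, "max_value"), c(9, 0))
  expect_equal(assign_signal(el, pk, "count"), c(3, 0))
  expect_equal(assign_signal(el, pk, "signal_track"), c(9, 0))
  expect_equal(assign_signal(el, GenomicRanges::GRanges(), "max_value"),
               c(0, 0))
})

test_that("Z-normalization matches the population-sd formula", {
  sm <- znormalize(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(sm$z), c(-1.224744871, 0, 1.224744871),
               tolerance = 1e-8)
  expect_warning(sm2 <- znormalize(cbind(a = 1:4, b = c(4, 4, 4, 4))),
                 "constant")
  expect_equal(as.numeric(sm2$z[, "b"]), rep(0, 4))
  set.seed(17)
  raw <- matrix(rlnorm(600), nrow = 100)
  sm3 <- znormalize(raw)
  expect_true(all(abs(colMeans(sm3$z)) < 1e-9))
  pop_sd <- sqrt(colMeans(sm3$z^2) - colMeans(sm3$z)^2)
  expect_true(all(abs(pop_sd - 1) < 1e-9))
  ## un-normalize reconstructs the raw matrix
  back <- sweep(sweep(sm3$z, 2, sm3$delta, "*"), 2, sm3$mu, "+")
  expect_equal(back, raw, tolerance = 1e-9)
})

test_that("Pearson-distance clustering recovers two planted signatures", {
  set.seed(23)
  n <- 100
  mu1 <- c(3, 3, 0.5, 0.5); mu2 <- c(0.5, 0.5, 3, 3)
  mat <- rbind(matrix(rnorm(4 * n, rep(mu1, each = n), 0.2), nrow = n),
               matrix(rnorm(4 * n, rep(mu2, each = n), 0.2), nrow = n))
  truth <- rep(1:2, each = n)
  res <- cluster_pairs(mat, k = 2)
  expect_equal(ari(res$labels, truth), 1.0)
})

test_that("clustering handles duplicates, k = n and degenerate rows", {
  mat <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 1, 4), c(2, 2, 2))
  res <- cluster_pairs(mat, k = 3)
  expect_equal(res$labels[1], res$labels[2])  # duplicates co-cluster
  res_n <- cluster_pairs(mat[1:3, ] + matrix(rnorm(9, sd = 0.01), 3),
                         k = 3)
  expect_equal(sort(res_n$labels), 1:3)
  expect_error(cluster_pairs(mat, k = 1))
  expect_error(cluster_pairs(mat, k = 5))
})

test_that("clustering is invariant to row order and row-wise affine maps", {
  set.seed(29)
  sim <- simulate_signal_matrix(default_factor_signatures(),
                                n_per_cluster = 30, sigma = 0.3, seed = 3)
  res <- cluster_pairs(sim$mat, k = 6)
  perm <- sample(nrow(sim$mat))
  res_p <- cluster_pairs(sim$mat[perm, ], k = 6)
  expect_equal(ari(res_p$labels, res$labels[perm]), 1.0)
  scale <- runif(nrow(sim$mat), 0.5, 4)
  shift <- rnorm(nrow(sim$mat))
  aff <- sim$mat * scale + shift
  res_a <- cluster_pairs(aff, k = 6)
  expect_equal(ari(res_a$labels, res$labels), 1.0)
})

test_that("cluster summaries report means and skip undersized tests", {
  pairs <- data.table::data.table(raw_count = c(10, 20, 5, 7, 100),
                                  target_fpkm = c(1, 2, 3, 4, 5))
  labels <- c(1, 1, 2, 2, 3)
  s <- cluster_summaries(labels, pairs)
  expect_equal(s$mean_raw_count[s$cluster == 1], 15)
  expect_true(s$test_skipped[s$cluster == 3])   # single member
  expect_false(s$test_skipped[s$cluster == 1])
  one <- cluster_summaries(rep(1, 5), pairs)
  expect_true(one$test_skipped)                 # no "rest" group
})

test_that("cluster agreement matches clusters greedily", {
  a <- rep(1:2, each = 5)
  expect_equal(cluster_agreement(a, a), 100)
  b <- a; b[1] <- 2
  expect_equal(cluster_agreement(a, b), 90)
  ## random relabeling agrees at about chance level 1/k
  set.seed(37)
  a <- sample(5, 1000, replace = TRUE)
  b <- sample(5, 1000, replace = TRUE)
  expect_equal(cluster_agreement(a, b), 100 / 5, tolerance = 0.25)
})

test_that("the signal matrix concatenates enhancer and promoter sides", {
  pairs <- data.table::data.table(enh_idx = c(1, 2), prom_idx = c(1, 1),
                                  enh_id = c("E1", "E2"),
                                  gene_id = c("G1", "G1"))
  enh <- granges0("chr1", c(1000, 9000), c(2000, 10000))
  prom <- granges0("chr1", 50000, 52500)
  pk <- granges0("chr1", c(1100, 50500), c(1200, 50600))
  S4Vectors::mcols(pk)$value <- c(4, 7)
  mat <- build_signal_matrix(pairs, enh, prom,
                             list(F1 = list(ranges = pk,
                                            mode = "max_value")))
  expect_equal(colnames(mat), c("F1_enh", "F1_prom"))
  expect_equal(unname(mat[, "F1_enh"]), c(4, 0))
  expect_equal(unname(mat[, "F1_prom"]), c(7, 7))
})
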