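test_that("interaction frequency counts reads bridging the two elements", {
  E <- granges0("chr1", 1000, 2000)
  P <- granges0("chr1", 50000, 52500)
  ct <- data.table::data.table(
    chrom = "chr1",
    pos1 = c(1500, 51000, 1200, 1100, 900000),
    pos2 = c(50100, 1800, 1300, 52000, 900100),
    count = c(1, 1, 5, 1, 2))
  ## rows: E-P, P-E (swapped), both-in-E, E-P, unrelated
  expect_equal(interaction_frequency(ct, E, P), 3)
  expect_equal(interaction_frequency(ct[5, ], E, P), 0)
  expect_equal(interaction_frequency(ct[0, ], E, P), 0)
  ## invariance to end order and record order
  swapped <- data.table::data.table(chrom = ct$chrom, pos1 = ct$pos2,
                                    pos2 = ct$pos1, count = ct$count)
  expect_equal(interaction_frequency(normalize_contacts(swapped), E, P), 3)
  expect_equal(interaction_frequency(ct[sample(5), ], E, P), 3)
})

test_that("pair significance is the exact binomial upper tail", {
  model <- structure(list(bin_edges = c(0, 1e6), expected_prob = 0.1,
                          n_pairs = 1, total_contacts = 10),
                     class = "decay_model")
  ## frozen by brute-force summation: 1 - P(0) - P(1) - P(2)
  expect_equal(pair_significance(3, 100, model), 0.0701908264,
               tolerance = 1e-9)
  expect_equal(pair_significance(0, 100, model), 1)
  model$expected_prob <- 1
  expect_equal(pair_significance(7, 100, model), 1)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  set.seed(42)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
})

test_that("decay fit recovers a d^-1 generating curve", {
  set.seed(101)
  n_pairs <- 5000
  d <- runif(n_pairs, 5e4, 2e6)
  N <- 1e5
  p_true <- d^-1 / sum(d^-1)
  counts <- rpois(n_pairs, N * p_true)
  pairs <- data.table::data.table(distance = d, raw_count = counts)
  model <- fit_decay(counts_as_contacts(counts), pairs, n_bins = 50)
  expect_equal(sum(model$expected_prob * model$n_pairs) *
                 model$total_contacts, sum(counts), tolerance = 0.01)
  expect_true(all(diff(model$expected_prob) <= 1e-15))
  ## per-bin fitted probability within 15% of the generating curve
  bin <- findInterval(d, model$bin_edges, all.inside = TRUE)
  truth_bin <- tapply(p_true, bin, mean)
  fit_bin <- model$expected_prob[as.integer(names(truth_bin))]
  expect_true(all(abs(fit_bin / truth_bin - 1) < 0.15))
})

test_that("distance-independent contacts give a flat decay curve", {
  set.seed(102)
  n_pairs <- 4000
  counts <- rpois(n_pairs, 25)
  pairs <- data.table::data.table(distance = runif(n_pairs, 1e4, 1e6),
                                  raw_count = counts)
  model <- fit_decay(counts_as_contacts(counts), pairs, n_bins = 20)
  expect_lt(max(model$expected_prob) / min(model$expected_prob), 1.1)
})

test_that("a single bin gives the global mean probability", {
  counts <- c(2, 0, 4)
  pairs <- data.table::data.table(distance = c(1e4, 2e4, 3e4),
                                  raw_count = counts)
  model <- fit_decay(counts_as_contacts(counts), pairs, n_bins = 1)
  expect_equal(model$expected_prob, 6 / (6 * 3))
})

test_that("fit_decay rejects degenerate inputs and reduces bins", {
  pairs <- data.table::data.table(distance = c(1e4, 2e4),
                                  raw_count = c(1, 2))
  expect_warning(fit_decay(counts_as_contacts(c(1, 2)), pairs, n_bins = 50),
                 "reducing bins")
  zero <- data.table::data.table(chrom = "chr1", pos1 = 1, pos2 = 2,
                                 count = 0)
  expect_error(fit_decay(zero, pairs), "all-zero")
})

test_that("build_ep_pairs applies the strict FDR cutoff and class labels", {
  set.seed(7)
  enh <- granges0("chr1", c(10000, 400000), c(11000, 401000),
                  id = c("E1", "E2"))
  S4Vectors::mcols(enh)$elncRNA_ids <-
    IRanges::CharacterList(list("L1", character(0)))
  genes <- data.table::data.table(
    chrom = "chr1", start = c(100000, 600000), end = c(120000, 620000),
    strand = "+", gene_id = c("G1", "G2"), biotype = "protein_coding",
    fpkm = c(5, 1))
  prom <- define_promoters(genes)
  ## strong planted contacts E1-G1, background elsewhere
  ct <- data.table::data.table(
    chrom = "chr1",
    pos1 = c(rep(10500, 60), 400500, 10400),
    pos2 = c(rep(99000, 60), 598500, 598000),
    count = c(rep(1, 60), 1, 1))
  res <- build_ep_pairs(ct, enh, prom, fdr_threshold = 0.001, n_bins = 2)
  expect_true(all(res$tested$raw_count >= 1))
  expect_true(all(res$retained$q_value < 0.001))
  expect_equal(res$retained$enh_id, "E1")
  expect_equal(res$retained$class_label, "elncRNA_associated")
  other <- res$tested[res$tested$enh_id == "E2", ]
  expect_equal(other$class_label, "non_elncRNA")
  ## retention is exactly the strict "<" rule over the tested set
  expect_equal(nrow(res$retained), sum(res$tested$q_value < 0.001))
  loose <- build_ep_pairs(ct, enh, prom, fdr_threshold = 0.5, n_bins = 2)
  expect_gte(nrow(loose$retained), nrow(res$retained))
})

test_that("group comparison reproduces the pooled t-test", {
  r <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t, -3.674234614, tolerance = 1e-8)
  expect_equal(r$p, 0.021311641, tolerance = 1e-8)
  expect_equal(r$df, 4)
  same <- compare_groups(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$t, 0)
  expect_error(compare_groups(5, c(1, 2)), "at least 2")
  ## agrees with the hand-evaluated formula on random draws
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), mean = 0.5)
    manual <- t_bruteforce(a, b)
    r <- compare_groups(a, b)
    expect_equal(r$t, manual$t, tolerance = 1e-10)
    expect_equal(r$p, manual$p, tolerance = 1e-10)
  }
})
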