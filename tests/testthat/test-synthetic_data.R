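small_cfg <- function(...) {
  sim_config(n_chroms = 2, chrom_length = 1e7, n_coding_genes = 60,
             n_lncRNAs = 150, n_enhancers = 120, n_loops = 30,
             total_contacts = 5e4, ...)
}

test_that("generation is deterministic for a fixed config", {
  cfg <- small_cfg(seed = 42)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  generate(cfg, out_dir = d1)
  generate(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
})

test_that("no active enhancers means no planted elncRNAs", {
  b <- generate(small_cfg(frac_active_enhancers = 0, seed = 2))
  expect_length(b$truth$elncRNA_ids, 0)
  expect_length(b$gro_peaks, 0)
})

test_that("the planted contact multiplier is realized in mean counts", {
  cc <- simulate_class_counts(n_per_class = 2000, total_contacts = 2e6,
                              decay_exponent = 1, multiplier = 1.3,
                              seed = 10)
  m_e <- mean(cc$raw_count[cc$class == "elncRNA_associated"])
  m_o <- mean(cc$raw_count[cc$class == "non_elncRNA"])
  expect_gt(m_e / m_o, 1.25)
  expect_lt(m_e / m_o, 1.35)
})

test_that("generated contacts follow the configured distance decay", {
  cc <- simulate_class_counts(n_per_class = 20000, total_contacts = 1e6,
                              decay_exponent = 1, multiplier = 1,
                              min_distance = 2e4, max_distance = 2e6,
                              seed = 11)
  cc <- cc[cc$class == "non_elncRNA", ]
  bins <- cut(log(cc$distance), breaks = 20)
  mc <- tapply(cc$raw_count, bins, mean)
  md <- tapply(log(cc$distance), bins, mean)
  fit <- lm(log(mc) ~ md)
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("truth tables are self-consistent with the emitted data", {
  b <- generate(small_cfg(seed = 5))
  genes <- b$genes
  coding <- genes[genes$biotype == "protein_coding", ]
  lnc <- genes[genes$biotype == "lncRNA", ]
  prom <- define_promoters(coding)
  kept <- suppressMessages(filter_enhancers(b$enhancers, coding, prom))
  ## every planted-invalid enhancer is removed by the filter
  invalid <- b$truth$enhancers$enh_id[!b$truth$enhancers$planted_valid]
  expect_length(intersect(S4Vectors::mcols(kept)$id, invalid), 0)
  ## every planted elncRNA is recovered by the calling rule
  ann <- call_active_enhancers(kept, b$gro_peaks, max_gap = 1000)
  called <- call_elncRNAs(lnc, ann, quiet = TRUE)$elncRNA_ids
  expect_true(all(b$truth$elncRNA_ids %in% called))
  ## planted pair counts match the emitted contact list
  pr <- b$truth$pairs[b$truth$pairs$raw_count > 0, ][1:5, ]
  enh_tab <- b$truth$enhancers
  for (i in seq_len(nrow(pr))) {
    e <- enh_tab[enh_tab$enh_id == pr$enh_id[i], ]
    g <- coding[coding$gene_id == pr$gene_id[i], ]
    freq <- interaction_frequency(
      b$contacts, granges0(e$chrom, e$start, e$end),
      define_promoters(g))
    expect_gte(freq, pr$raw_count[i])
  }
})

test_that("a written bundle reads back equivalent", {
  cfg <- small_cfg(seed = 8)
  d <- file.path(tempdir(), "bundle_rt")
  b <- generate(cfg, out_dir = d)
  rb <- read_bundle(d)
  expect_equal(rb$genes, b$genes)
  expect_equal(granges_to_table(rb$enhancers)[, 1:3],
               granges_to_table(b$enhancers)[, 1:3])
  expect_equal(rb$contacts$count, b$contacts$count)
  expect_equal(nrow(rb$loops), nrow(b$loops))
  expect_equal(sort(names(rb$factors)), sort(names(b$factors)))
})

test_that("null bundles carry no planted structure", {
  bn <- generate_null(small_cfg(seed = 3))
  expect_equal(bn$config$elnc_pair_multiplier, 1)
  expect_null(bn$config$factor_signatures)
  expect_null(bn$truth$clusters)
})

test_that("null bundles show no class effect and chance-level clustering", {
  ## no planted multiplier: the class comparison is not significant
  for (s in 1:3) {
    cc <- simulate_class_counts(n_per_class = 1000,
                                total_contacts = 1e5, multiplier = 1,
                                seed = 700 + s)
    r <- compare_groups(cc$raw_count[cc$class == "elncRNA_associated"],
                        cc$raw_count[cc$class == "non_elncRNA"])
    expect_gt(r$p, 0.001)
  }
  ## no planted signatures: clustering of iid noise is chance-level
  set.seed(71)
  mat <- matrix(rnorm(600 * 20, mean = 1, sd = 0.5), nrow = 600)
  truth <- rep(1:6, each = 100)
  res <- cluster_pairs(suppressWarnings(znormalize(mat))$z, k = 6)
  expect_lt(abs(ari(res$labels, truth)), 0.05)
})

test_that("infeasible configurations are rejected with a capacity message", {
  expect_error(sim_config(n_coding_genes = 1e5, chrom_length = 2e6),
               "infeasible placement")
  expect_error(sim_config(frac_elncRNA = 1.4), "fractions")
  expect_error(sim_config(elnc_pair_multiplier = 0.5), "multiplier")
})
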