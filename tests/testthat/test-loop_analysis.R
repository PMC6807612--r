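toy_loops <- function(n = 20, span = 5e5, chrom = "chr1", gap = 6e5) {
  start <- (seq_len(n) - 1) * gap
  loop_set(data.frame(chrom = chrom, start1 = start, end1 = start + 1e4,
                      start2 = start + span - 1e4, end2 = start + span))
}

test_that("loop density concentrates where features are planted", {
  loops <- toy_loops()
  ## all features at the anchors
  pts <- c(loops$start1 + 100, loops$end2 - 100)
  f <- granges0(rep(loops$chrom, 2), pts, pts + 1)
  prof <- loop_density_profile(loops, f, n_rel_bins = 10)
  expect_equal(sum(prof$counts), prof$n_in_loop)
  expect_equal(sum(prof$counts[c(1, 10)]), length(f))
  expect_equal(sum(prof$counts[2:9]), 0)
  ## a feature outside every loop contributes nothing
  out <- granges0("chr2", 5, 6)
  both <- suppressWarnings(c(f, out))  # distinct seqlevels are expected
  prof2 <- loop_density_profile(loops, both, n_rel_bins = 10)
  expect_equal(prof2$n_in_loop, length(f))
})

test_that("uniform in-loop features give a flat relative profile", {
  set.seed(55)
  loops <- toy_loops()
  n <- 10000
  li <- sample(nrow(loops), n, replace = TRUE)
  pos <- floor(loops$start1[li] +
                 runif(n) * (loops$end2[li] - loops$start1[li]))
  f <- granges0(loops$chrom[li], pos, pos + 1)
  prof <- loop_density_profile(loops, f, n_rel_bins = 20)
  expected <- n / 20
  tol <- 3 * sqrt(n * (1 / 20) * (19 / 20))
  expect_true(all(abs(prof$counts - expected) < tol))
})

test_that("loop density errors on empty inputs", {
  loops <- toy_loops()
  expect_error(loop_density_profile(loops[0, ], granges0("chr1", 1, 2)))
  expect_error(loop_density_profile(loops, GenomicRanges::GRanges()))
})

test_that("anchor enrichment reflects planted overlap", {
  sizes <- c(chr1 = 2e7)
  ## anchors covering 1% of the chromosome
  astart <- seq(0, 2e7 - 2e5, by = 2e6)
  anchors <- granges0("chr1", astart, astart + 2e4)
  ## features planted inside anchors
  fstart <- rep(astart, each = 3) + c(1000, 5000, 9000)
  feats <- granges0("chr1", fstart, fstart + 500)
  enr <- anchor_enrichment(feats, anchors, sizes, n_random = 2000, seed = 5)
  expect_equal(enr$observed, 1)
  expect_equal(enr$fold, 1 / 0.01, tolerance = 0.2)
  ## no overlap at all
  far <- granges0("chr1", 1e6, 1e6 + 100)
  enr0 <- anchor_enrichment(far, anchors[1], sizes, n_random = 5000,
                            seed = 1)
  expect_equal(enr0$fold, 0)
})

test_that("anchor enrichment is seeded and permutation-invariant", {
  set.seed(77)
  sizes <- c(chr1 = 1e7, chr2 = 1e7)
  feats <- random_intervals(100, seed = 8, max_start = 9e6)
  anchors <- random_intervals(50, seed = 9, max_start = 9e6,
                              max_width = 20000)
  e1 <- anchor_enrichment(feats, anchors, sizes, n_random = 300, seed = 4)
  e2 <- anchor_enrichment(feats, anchors, sizes, n_random = 300, seed = 4)
  expect_identical(e1, e2)
  e3 <- anchor_enrichment(feats[sample(100)], anchors, sizes,
                          n_random = 300, seed = 4)
  expect_equal(e3$fold, e1$fold)
})

test_that("anchor peak profiles localize and scale correctly", {
  anchors <- granges0("chr1", seq(1e6, 5e6, by = 1e6),
                      seq(1e6, 5e6, by = 1e6) + 10000)
  mids <- (GenomicRanges::start(anchors) - 1 +
             GenomicRanges::end(anchors)) / 2
  peaks <- granges0("chr1", floor(mids) - 50, floor(mids) + 50)
  prof <- anchor_peak_profile(anchors, peaks, flank = 5000, binsize = 1000)
  central <- which(prof$bin_centers == 500)  # bin holding offset 0
  expect_equal(prof$values[central], 1)
  expect_true(all(prof$values[-central] == 0))
  expect_equal(sum(prof$values), 1)  # one peak per anchor, all in-window
  empty <- anchor_peak_profile(anchors, GenomicRanges::GRanges(),
                               flank = 5000, binsize = 1000)
  expect_true(all(empty$values == 0))
  ## uniform peak density rho per bp -> about rho * binsize per bin
  set.seed(12)
  rho <- 1 / 2000
  ps <- sort(sample.int(6e6, 6e6 * rho))
  upeaks <- granges0("chr1", ps, ps + 1)
  prof2 <- anchor_peak_profile(anchors, upeaks, flank = 50000,
                               binsize = 1000)
  expect_equal(mean(prof2$values), rho * 1000, tolerance = 0.1)
})

test_that("anchors partition by elncRNA content", {
  anchors <- granges0("chr1", c(0, 1e6), c(1e4, 1e6 + 1e4),
                      id = c("A1", "A2"))
  elnc <- granges0("chr1", 5000, 8000)
  part <- partition_anchors_by_elncRNA(anchors, elnc)
  expect_equal(S4Vectors::mcols(part$containing)$id, "A1")
  expect_equal(S4Vectors::mcols(part$other)$id, "A2")
  none <- partition_anchors_by_elncRNA(anchors, GenomicRanges::GRanges())
  expect_length(none$containing, 0)
  expect_length(none$other, 2)
})

test_that("elncRNA-target anchors require a retained significant contact", {
  set.seed(13)
  anchors <- granges0("chr1", c(0, 4e6), c(1e4, 4e6 + 1e4),
                      id = c("A1", "A2"))
  genes <- granges0("chr1", c(1e6, 6e6), c(1e6 + 5e3, 6e6 + 5e3),
                    id = c("L1", "L2"))
  ## heavy planted contact A1-L1; background singletons elsewhere
  ct <- data.table::data.table(
    chrom = "chr1",
    pos1 = c(rep(5000, 80), 4e6 + 5000, 5000),
    pos2 = c(rep(1e6 + 1000, 80), 6e6 + 2500, 6e6 + 100),
    count = 1)
  hit <- find_elncRNA_target_anchors(anchors, genes, ct,
                                     fdr_threshold = 0.001, n_bins = 2)
  expect_equal(S4Vectors::mcols(hit)$id, "A1")
  none <- find_elncRNA_target_anchors(anchors, genes, ct[0, ])
  expect_length(none, 0)
})
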