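## small in-code fixtures shared across test files

write_tmp <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## random intervals on a 2-chromosome toy genome
random_intervals <- function(n, seed, max_start = 1e6, max_width = 5000) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(max_start, n)
  width <- sample.int(max_width, n)
  granges0(chrom, start, start + width)
}

## independent step-up BH, straight from the definition
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## pooled-variance two-sided t by hand
t_bruteforce <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), na + nb - 2))
}

## adjusted Rand index (independent of the package's agreement measure)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  nch <- choose(sum(tab), 2)
  exp_idx <- sum_a * sum_b / nch
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

## minimal contact table whose only role is to carry total count N
counts_as_contacts <- function(counts, chrom = "chr1") {
  k <- counts[counts > 0]
  if (length(k) == 0) k <- 1
  data.table::data.table(chrom = chrom, pos1 = seq_along(k),
                         pos2 = seq_along(k) + 10, count = as.numeric(k))
}
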