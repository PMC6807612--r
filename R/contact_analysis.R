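## Enhancer-promoter pair construction from Hi-C contact lists:
## interaction frequency, distance-decay binomial significance (a
## simplified one-pass fit-HiC-style model), BH FDR filtering and
## elncRNA-association labels.

.midpoint0 <- function(gr) {
  ## midpoint in 0-based coordinates
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}

.points_gr <- function(chrom, pos0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1, width = 1))
}

#' Interaction frequency of one enhancer-promoter pair
#'
#' Sum of contact counts over records with one end inside the enhancer and
#' the other inside the promoter, in either end order. Ends are bp points;
#' "inside" uses the half-open interval convention.
#'
#' @param contacts contact `data.table` (chrom, pos1, pos2, count).
#' @param enhancer,promoter single-interval `GRanges`.
#' @return nonnegative numeric count.
#' @export
interaction_frequency <- function(contacts, enhancer, promoter) {
  stopifnot(length(enhancer) == 1, length(promoter) == 1)
  counts <- count_pair_contacts(contacts, enhancer, promoter)
  if (nrow(counts) == 0) 0 else sum(counts$count)
}

#' Count contacts for all enhancer x promoter combinations
#'
#' Vectorized contact assignment: returns the total count of records with
#' one end in the enhancer and the other in the promoter for every
#' (enhancer, promoter) index pair with at least one such record.
#'
#' @param contacts contact `data.table`.
#' @param enhancers,promoters `GRanges`.
#' @return `data.table` with columns enh_idx, prom_idx, count.
#' @export
count_pair_contacts <- function(contacts, enhancers, promoters) {
  empty <- data.table(enh_idx = integer(), prom_idx = integer(),
                      count = numeric())
  if (nrow(contacts) == 0 || length(enhancers) == 0 ||
      length(promoters) == 0) {
    return(empty)
  }
  pts1 <- .points_gr(contacts$chrom, contacts$pos1)
  pts2 <- .points_gr(contacts$chrom, contacts$pos2)
  link <- function(pts_e, pts_p) {
    he <- GenomicRanges::findOverlaps(pts_e, enhancers, ignore.strand = TRUE)
    hp <- GenomicRanges::findOverlaps(pts_p, promoters, ignore.strand = TRUE)
    de <- data.table(rec = queryHits(he), enh_idx = subjectHits(he))
    dp <- data.table(rec = queryHits(hp), prom_idx = subjectHits(hp))
    merge(de, dp, by = "rec", allow.cartesian = TRUE)
  }
  both <- rbind(link(pts1, pts2), link(pts2, pts1))
  if (nrow(both) == 0) return(empty)
  ## a record whose two ends fall in overlapping elements in both
  ## orientations is counted once per orientation of distinct (E,P) roles;
  ## identical (rec, E, P) duplicates (possible only when E and P overlap
  ## the same point) are dropped.
  both <- unique(both)
  both$count <- contacts$count[both$rec]
  out <- both[, list(count = sum(count)), by = c("enh_idx", "prom_idx")]
  out[]
}

#' Enumerate candidate enhancer-promoter pairs
#'
#' All same-chromosome enhancer x promoter combinations with
#' midpoint-to-midpoint distance within the given range.
#'
#' @param enhancers,promoters `GRanges`.
#' @param min_distance,max_distance distance bounds in bp.
#' @return `data.table` with enh_idx, prom_idx, chrom and distance.
#' @export
candidate_ep_pairs <- function(enhancers, promoters, min_distance = 0,
                               max_distance = Inf) {
  chr_e <- as.character(GenomicRanges::seqnames(enhancers))
  chr_p <- as.character(GenomicRanges::seqnames(promoters))
  de <- data.table(enh_idx = seq_along(enhancers), chrom = chr_e,
                   mid_e = .midpoint0(enhancers))
  dp <- data.table(prom_idx = seq_along(promoters), chrom = chr_p,
                   mid_p = .midpoint0(promoters))
  pairs <- merge(de, dp, by = "chrom", allow.cartesian = TRUE)
  pairs$distance <- abs(pairs$mid_e - pairs$mid_p)
  pairs <- pairs[pairs$distance >= min_distance &
                 pairs$distance <= max_distance, ]
  pairs[, c("chrom", "enh_idx", "prom_idx", "distance")]
}

## weighted pool-adjacent-violators, nonincreasing fit
.pava_nonincreasing <- function(y, w) {
  n <- length(y)
  val <- y; wt <- w; size <- rep(1L, n)
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    val[m] <- y[i]; wt[m] <- w[i]; size[m] <- 1L
    while (m > 1L && val[m - 1L] < val[m]) {
      pooled <- (val[m - 1L] * wt[m - 1L] + val[m] * wt[m]) /
        (wt[m - 1L] + wt[m])
      val[m - 1L] <- pooled
      wt[m - 1L] <- wt[m - 1L] + wt[m]
      size[m - 1L] <- size[m - 1L] + size[m]
      m <- m - 1L
    }
  }
  rep(val[seq_len(m)], times = size[seq_len(m)])
}

#' Fit a distance-decay contact-probability model
#'
#' A simplified one-pass fit-HiC-style null: candidate pairs are sorted by
#' genomic distance and cut into equal-occupancy bins (each holding roughly
#' the same total contact count); the per-bin contact probability per
#' candidate pair is the bin's total count divided by (total contacts x
#' pairs in bin); pool-adjacent-violators smoothing enforces a monotone
#' nonincreasing probability-distance relationship.
#'
#' @param contacts contact `data.table`; `sum(count)` defines the binomial
#'   trial number N.
#' @param pairs candidate pair table with `distance` and `raw_count`
#'   columns (see [candidate_ep_pairs()] and [count_pair_contacts()]).
#' @param n_bins requested number of distance bins (default 100); reduced
#'   with a warning when there are fewer pairs than bins.
#' @return object of class `decay_model`: list with `bin_edges`,
#'   `expected_prob`, `n_pairs` per bin and `total_contacts`.
#' @export
fit_decay <- function(contacts, pairs, n_bins = 100) {
  stopifnot(n_bins >= 1, nrow(pairs) >= 1)
  N <- sum(contacts$count)
  if (N <= 0) stop("all-zero contacts: cannot fit a decay model")
  if (nrow(pairs) < n_bins) {
    warning(sprintf("only %d candidate pairs; reducing bins from %d",
                    nrow(pairs), n_bins))
    n_bins <- max(1L, nrow(pairs))
  }
  ord <- order(pairs$distance)
  d <- pairs$distance[ord]
  cnt <- pairs$raw_count[ord]
  total <- sum(cnt)
  if (total <= 0) stop("candidate pairs carry no contacts")
  target <- total / n_bins
  ## equal-occupancy assignment on cumulative count; zero-count pairs join
  ## the bin open at their distance rank
  bin <- pmin(n_bins, pmax(1L, ceiling(cumsum(cnt) / target)))
  bin <- cummax(bin)  # keep bins contiguous in distance order
  nb <- max(bin)
  sum_cnt <- tapply(cnt, bin, sum)
  n_pairs <- tapply(cnt, bin, length)
  prob <- as.numeric(sum_cnt) / (N * as.numeric(n_pairs))
  prob <- .pava_nonincreasing(prob, as.numeric(n_pairs))
  prob <- pmin(prob, 1)
  lo <- tapply(d, bin, min)
  hi <- tapply(d, bin, max)
  edges <- c(as.numeric(lo), as.numeric(hi[length(hi)]))
  structure(list(bin_edges = edges, expected_prob = prob,
                 n_pairs = as.numeric(n_pairs), total_contacts = N),
            class = "decay_model")
}

#' Binomial upper-tail significance of a pair
#'
#' P(X >= raw_count) with X ~ Binomial(N, p), N the model's total contact
#' count and p the expected per-pair probability of the pair's distance
#' bin. Distances outside the modeled range use the nearest bin.
#'
#' @param raw_count observed interaction frequency (vectorized).
#' @param distance pair distance in bp (vectorized).
#' @param model a `decay_model`.
#' @return numeric p-values.
#' @export
pair_significance <- function(raw_count, distance, model) {
  stopifnot(inherits(model, "decay_model"))
  idx <- findInterval(distance, model$bin_edges, all.inside = TRUE)
  idx <- pmin(pmax(idx, 1L), length(model$expected_prob))
  p <- model$expected_prob[idx]
  pbinom(raw_count - 1, size = model$total_contacts, prob = p,
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Order-preserving wrapper around `p.adjust(..., method = "BH")`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Build significant enhancer-promoter pairs
#'
#' Candidate pairs are all same-chromosome enhancer x promoter
#' combinations; pairs with at least one supporting contact are tested
#' against the distance-decay binomial null and retained at
#' `q < fdr_threshold` (strict). A pair is labelled "elncRNA_associated"
#' iff its enhancer carries at least one elncRNA id (see
#' [call_elncRNAs()]), else "non_elncRNA".
#'
#' @param contacts contact `data.table`.
#' @param enhancers annotated enhancer `GRanges` (with `elncRNA_ids`; a
#'   plain `GRanges` is accepted and labels all pairs "non_elncRNA").
#' @param promoters promoter `GRanges` (with `gene_id`, `fpkm`).
#' @param fdr_threshold FDR cutoff (default 0.001, strict "<").
#' @param n_bins decay-model bins (default 100).
#' @param min_distance,max_distance candidate distance range in bp.
#' @return list with `retained` and `tested` pair tables (coordinates
#'   0-based half-open) and the fitted `model`.
#' @export
build_ep_pairs <- function(contacts, enhancers, promoters,
                           fdr_threshold = 0.001, n_bins = 100,
                           min_distance = 0, max_distance = Inf) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  cand <- candidate_ep_pairs(enhancers, promoters, min_distance,
                             max_distance)
  if (nrow(cand) == 0) stop("no candidate enhancer-promoter pairs")
  cnts <- count_pair_contacts(contacts, enhancers, promoters)
  cand <- merge(cand, cnts, by = c("enh_idx", "prom_idx"), all.x = TRUE)
  cand$raw_count <- ifelse(is.na(cand$count), 0, cand$count)
  cand$count <- NULL
  model <- fit_decay(contacts, cand, n_bins)
  tested <- cand[cand$raw_count >= 1, ]
  tested$p_value <- pair_significance(tested$raw_count, tested$distance,
                                      model)
  tested$q_value <- bh_fdr(tested$p_value)
  etab <- granges_to_table(enhancers)
  ptab <- granges_to_table(promoters)
  has_elnc <- if (!is.null(mcols(enhancers)$elncRNA_ids)) {
    lengths(mcols(enhancers)$elncRNA_ids) > 0
  } else rep(FALSE, length(enhancers))
  tested <- data.table(
    chrom = tested$chrom,
    enh_start = etab$start[tested$enh_idx],
    enh_end = etab$end[tested$enh_idx],
    enh_id = etab$id[tested$enh_idx],
    prom_start = ptab$start[tested$prom_idx],
    prom_end = ptab$end[tested$prom_idx],
    gene_id = if (!is.null(mcols(promoters)$gene_id)) {
      mcols(promoters)$gene_id[tested$prom_idx]
    } else ptab$id[tested$prom_idx],
    target_fpkm = if (!is.null(mcols(promoters)$fpkm)) {
      mcols(promoters)$fpkm[tested$prom_idx]
    } else NA_real_,
    distance = tested$distance,
    raw_count = tested$raw_count,
    p_value = tested$p_value,
    q_value = tested$q_value,
    class_label = ifelse(has_elnc[tested$enh_idx], "elncRNA_associated",
                         "non_elncRNA"),
    enh_idx = tested$enh_idx,
    prom_idx = tested$prom_idx
  )
  retained <- tested[tested$q_value < fdr_threshold, ]
  list(retained = retained[], tested = tested[], model = model)
}

#' Two-group Student's t comparison
#'
#' Two-sided pooled-variance Student's t-test on a metric measured in two
#' groups (Welch's variant behind a flag).
#'
#' @param a,b numeric vectors (both of length >= 2).
#' @param welch use Welch's unequal-variance t-test instead.
#' @return list with `mean_a`, `mean_b`, `t`, `p`, `df`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations")
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(mean_a = mean(a), mean_b = mean(b),
       t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n_a = length(a), n_b = length(b))
}

#' Compare two pair groups on a metric
#'
#' @param pairsA,pairsB pair tables from [build_ep_pairs()].
#' @param metric "raw_count" or "target_fpkm".
#' @param welch use Welch's t-test.
#' @return see [compare_groups()].
#' @export
compare_pair_groups <- function(pairsA, pairsB,
                                metric = c("raw_count", "target_fpkm"),
                                welch = FALSE) {
  metric <- match.arg(metric)
  compare_groups(pairsA[[metric]], pairsB[[metric]], welch = welch)
}
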