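## Chromatin-loop analyses: relative lncRNA density across loops, anchor
## fold enrichment against random length-matched regions, peak-count
## metaprofiles around anchors, and elncRNA-target anchor identification.

#' Representative points of features
#'
#' TSS for stranded features, midpoint otherwise (0-based bp).
#'
#' @param features `GRanges`.
#' @return numeric vector of 0-based positions.
#' @export
feature_points <- function(features) {
  str <- as.character(GenomicRanges::strand(features))
  s0 <- GenomicRanges::start(features) - 1
  e0 <- GenomicRanges::end(features)
  ifelse(str == "+", s0, ifelse(str == "-", e0 - 1, floor((s0 + e0) / 2)))
}

#' Relative density of features across loops
#'
#' Each in-loop feature point is mapped to its relative position between
#' the outer loop boundaries (0 at the start of anchor 1, 1 at the end of
#' anchor 2) and histogrammed over `n_rel_bins` bins. Values are the bin
#' fraction of all features rescaled to a per-10 kb density using the mean
#' loop span, matching a fixed-window density read off profiles of
#' unequal-length loops.
#'
#' @param loops a `loop_set`.
#' @param features `GRanges` (genes: TSS used; else midpoint).
#' @param n_rel_bins number of relative-position bins (default 40).
#' @return list of class `meta_profile`: `bin_centers` (relative units),
#'   `values` (density per 10 kb), `counts` per bin, `n_features`,
#'   `n_in_loop`, `mean_span`.
#' @export
loop_density_profile <- function(loops, features, n_rel_bins = 40) {
  stopifnot(n_rel_bins >= 2)
  if (nrow(loops) == 0) stop("no loops")
  if (length(features) == 0) stop("no features")
  pts <- feature_points(features)
  chrom <- as.character(GenomicRanges::seqnames(features))
  dtf <- data.table(chrom = chrom, pos = pts, fid = seq_along(features))
  dtl <- data.table(chrom = loops$chrom, lo = loops$start1,
                    hi = loops$end2, lid = seq_len(nrow(loops)))
  j <- merge(dtf, dtl, by = "chrom", allow.cartesian = TRUE)
  j <- j[j$pos >= j$lo & j$pos < j$hi, ]
  counts <- rep(0, n_rel_bins)
  if (nrow(j) > 0) {
    rel <- (j$pos - j$lo) / (j$hi - j$lo)
    bin <- pmin(n_rel_bins, floor(rel * n_rel_bins) + 1L)
    tb <- tabulate(bin, nbins = n_rel_bins)
    counts <- as.numeric(tb)
  }
  mean_span <- mean(loops$end2 - loops$start1)
  bin_bp <- mean_span / n_rel_bins
  values <- (counts / length(features)) * (10000 / bin_bp)
  structure(list(bin_centers = (seq_len(n_rel_bins) - 0.5) / n_rel_bins,
                 values = values, counts = counts,
                 n_features = length(features), n_in_loop = nrow(j),
                 mean_span = mean_span),
            class = "meta_profile")
}

#' Fold enrichment of features over loop anchors
#'
#' Numerator: mean number of anchors each feature overlaps. Denominator:
#' the same statistic over length-matched, chromosome-matched random
#' intervals, averaged over `n_random` independent draws. Random starts
#' are uniform within the chromosome, rejecting placements beyond the
#' chromosome end.
#'
#' @param features `GRanges`.
#' @param anchors `GRanges` of loop anchors.
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param n_random number of random draws (default 1000).
#' @param seed integer seed for the random draws.
#' @return list with `fold`, `observed`, `expected`.
#' @export
anchor_enrichment <- function(features, anchors, chrom_sizes,
                              n_random = 1000, seed = 1) {
  stopifnot(n_random >= 1, length(features) > 0)
  obs <- mean(GenomicRanges::countOverlaps(features, anchors,
                                           ignore.strand = TRUE))
  ## canonical order so the seeded draws (hence the fold) are invariant
  ## under permutation of the feature list
  features <- features[order(as.character(GenomicRanges::seqnames(features)),
                             GenomicRanges::start(features),
                             GenomicRanges::width(features))]
  chrom <- as.character(GenomicRanges::seqnames(features))
  len <- GenomicRanges::width(features)
  if (!all(chrom %in% names(chrom_sizes))) {
    stop("chrom_sizes missing entries for some feature chromosomes")
  }
  maxstart <- chrom_sizes[chrom] - len  # 0-based start upper bound
  if (any(maxstart < 0)) stop("feature longer than its chromosome")
  nf <- length(features)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  starts <- floor(runif(nf * n_random, min = 0,
                        max = rep(maxstart + 1, n_random)))
  rnd <- granges0(rep(chrom, n_random), starts,
                  starts + rep(len, n_random))
  exp_mean <- sum(GenomicRanges::countOverlaps(rnd, anchors,
                                               ignore.strand = TRUE)) /
    (nf * n_random)
  fold <- if (exp_mean == 0) NA_real_ else obs / exp_mean
  list(fold = fold, observed = obs, expected = exp_mean)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Peak-count metaprofile around anchor midpoints
#'
#' Mean number of peaks (by peak midpoint) per bin over windows of
#' half-width `flank` centered on anchor midpoints.
#'
#' @param anchors `GRanges` (a group of anchors; partition upstream of
#'   this call to compare groups).
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param flank half-window in bp (default 50000).
#' @param binsize bin width in bp (default 1000).
#' @return `meta_profile` with `bin_centers` as bp offsets from the anchor
#'   midpoint.
#' @export
anchor_peak_profile <- function(anchors, peaks, flank = 50000,
                                binsize = 1000) {
  stopifnot(flank > 0, binsize > 0)
  n_bins <- as.integer(ceiling(2 * flank / binsize))
  counts <- rep(0, n_bins)
  if (length(anchors) > 0 && length(peaks) > 0) {
    amid <- .midpoint0(anchors)
    pmid <- .midpoint0(peaks)
    da <- data.table(chrom = as.character(GenomicRanges::seqnames(anchors)),
                     amid = amid, aid = seq_along(anchors))
    dp <- data.table(chrom = as.character(GenomicRanges::seqnames(peaks)),
                     pmid = pmid)
    j <- merge(da, dp, by = "chrom", allow.cartesian = TRUE)
    off <- j$pmid - j$amid
    j <- j[off >= -flank & off < flank, ]
    if (nrow(j) > 0) {
      off <- j$pmid - j$amid
      bin <- floor((off + flank) / binsize) + 1L
      counts <- as.numeric(tabulate(bin, nbins = n_bins))
    }
  }
  centers <- -flank + (seq_len(n_bins) - 0.5) * binsize
  values <- if (length(anchors) > 0) counts / length(anchors) else counts
  structure(list(bin_centers = centers, values = values, counts = counts,
                 n_features = length(anchors)),
            class = "meta_profile")
}

#' Partition anchors by elncRNA content
#'
#' @param anchors `GRanges` of loop anchors.
#' @param elncRNA_genes `GRanges` of elncRNA gene spans.
#' @return list with `containing` and `other` anchor `GRanges`.
#' @export
partition_anchors_by_elncRNA <- function(anchors, elncRNA_genes) {
  has <- if (length(elncRNA_genes) > 0) {
    IRanges::overlapsAny(anchors, elncRNA_genes, ignore.strand = TRUE)
  } else rep(FALSE, length(anchors))
  list(containing = anchors[has], other = anchors[!has])
}

#' Identify elncRNA-target loop anchors
#'
#' Anchors with at least one retained significant Hi-C contact to an
#' elncRNA gene region. Significance comes from the same machinery as
#' enhancer-promoter pairs, applied to anchor x elncRNA-gene candidates.
#'
#' @param anchors `GRanges` of loop anchors.
#' @param elncRNA_genes `GRanges` of elncRNA gene spans.
#' @param contacts contact `data.table`.
#' @param fdr_threshold FDR cutoff (default 0.001).
#' @param n_bins decay-model bins.
#' @return `GRanges` subset of anchors (possibly empty).
#' @export
find_elncRNA_target_anchors <- function(anchors, elncRNA_genes, contacts,
                                        fdr_threshold = 0.001,
                                        n_bins = 100) {
  if (length(anchors) == 0 || length(elncRNA_genes) == 0 ||
      nrow(contacts) == 0) {
    return(anchors[integer(0)])
  }
  res <- tryCatch(
    build_ep_pairs(contacts, anchors, elncRNA_genes,
                   fdr_threshold = fdr_threshold, n_bins = n_bins),
    error = function(e) NULL)
  if (is.null(res) || nrow(res$retained) == 0) return(anchors[integer(0)])
  anchors[sort(unique(res$retained$enh_idx))]
}
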