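## Structuring-factor signal assignment, Z-score normalization,
## Pearson-distance hierarchical clustering of enhancer-promoter pairs,
## cluster summaries and cross-panel agreement.

#' Assign a structuring-factor signal to elements
#'
#' Signal of a factor on an element: the maximum overlapping peak value
#' ("max_value", MACS peak values), the number of overlapping peaks
#' ("count", merged-TF panels), or the maximum overlapping track value
#' ("signal_track", e.g. G4-seq bedGraph). Elements overlapping nothing
#' score 0.
#'
#' @param elements `GRanges`.
#' @param factor_peaks `GRanges`; `mcols()$value` required for modes other
#'   than "count".
#' @param mode one of "max_value", "count", "signal_track".
#' @return numeric vector, one value per element.
#' @export
assign_signal <- function(elements,
                          factor_peaks,
                          mode = c("max_value", "count", "signal_track")) {
  mode <- match.arg(mode)
  out <- rep(0, length(elements))
  if (length(elements) == 0 || length(factor_peaks) == 0) return(out)
  if (mode == "count") {
    return(as.numeric(GenomicRanges::countOverlaps(elements, factor_peaks,
                                                   ignore.strand = TRUE)))
  }
  vals <- mcols(factor_peaks)$value
  if (is.null(vals)) stop("factor_peaks need a 'value' column for mode ", mode)
  hits <- GenomicRanges::findOverlaps(elements, factor_peaks,
                                      ignore.strand = TRUE)
  if (length(hits) > 0) {
    mx <- tapply(vals[subjectHits(hits)], queryHits(hits), max)
    out[as.integer(names(mx))] <- as.numeric(mx)
  }
  out
}

#' Build the pairs x factors signal matrix
#'
#' One row per enhancer-promoter pair; two columns per factor (enhancer
#' side and promoter side).
#'
#' @param pairs pair table from [build_ep_pairs()] (needs `enh_idx`,
#'   `prom_idx`).
#' @param enhancers,promoters the element `GRanges` the indices refer to.
#' @param factors named list; each entry a list with `ranges` (`GRanges`)
#'   and `mode` (see [assign_signal()]).
#' @return numeric matrix with columns "<factor>_enh", "<factor>_prom".
#' @export
build_signal_matrix <- function(pairs, enhancers, promoters, factors) {
  stopifnot(length(names(factors)) == length(factors))
  cols <- list()
  for (nm in names(factors)) {
    f <- factors[[nm]]
    ev <- assign_signal(enhancers, f$ranges, f$mode)
    pv <- assign_signal(promoters, f$ranges, f$mode)
    cols[[paste0(nm, "_enh")]] <- ev[pairs$enh_idx]
    cols[[paste0(nm, "_prom")]] <- pv[pairs$prom_idx]
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- paste(pairs$enh_id, pairs$gene_id, sep = "|")
  mat
}

#' Z-score normalize a signal matrix by column
#'
#' Z = (x - mu) / delta per column, with mu the column mean and delta the
#' population (divide-by-n) standard deviation over all rows. Constant
#' columns map to all zeros with a warning.
#'
#' @param raw numeric matrix (>= 2 rows).
#' @return list of class `signal_matrix`: `raw`, `z`, `mu`, `delta`.
#' @export
znormalize <- function(raw) {
  raw <- as.matrix(raw)
  stopifnot(nrow(raw) >= 2)
  n <- nrow(raw)
  mu <- colMeans(raw)
  delta <- sqrt(colMeans(raw^2) - mu^2)
  delta[delta < 0] <- 0  # guard against negative rounding error
  const <- delta <= .Machine$double.eps^0.5 * pmax(abs(mu), 1)
  if (any(const)) {
    warning(sprintf("%d constant column(s) mapped to all-zero Z scores",
                    sum(const)))
  }
  denom <- ifelse(const, 1, delta)
  z <- sweep(sweep(raw, 2, mu, "-"), 2, denom, "/")
  z[, const] <- 0
  structure(list(raw = raw, z = z, mu = mu, delta = delta),
            class = "signal_matrix")
}

#' Hierarchical clustering of pairs on normalized signals
#'
#' Agglomerative clustering with distance 1 - Pearson correlation between
#' row vectors and average linkage, cut to exactly `k` clusters. Rows with
#' zero variance (undefined correlation) sit at distance 1 from every
#' other row.
#'
#' @param z numeric matrix of normalized signals (rows = pairs).
#' @param k number of clusters (2 <= k <= nrow(z)).
#' @return list of class `cluster_result`: `labels` (1..k per row), `k`,
#'   `tree` (the `hclust` object).
#' @export
cluster_pairs <- function(z, k) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (k < 2 || k > n) stop("k must be in [2, nrow(z)]")
  cc <- suppressWarnings(cor(t(z)))
  cc[is.na(cc)] <- 0  # zero-variance rows: distance 1 to all others
  d <- as.dist(1 - cc)
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  structure(list(labels = unname(labels), k = k, tree = tree),
            class = "cluster_result")
}

#' Per-cluster summaries of enhancer-promoter pairs
#'
#' For each cluster: size, mean and median interaction frequency, mean
#' target-gene FPKM, mean associated-elncRNA FPKM, and two-sided pooled
#' Student's t-tests of the cluster against all remaining pairs on
#' interaction frequency and target expression. Tests are skipped (NA with
#' `test_skipped = TRUE`) when either side has fewer than 2 members.
#'
#' @param result `cluster_result` (or an integer label vector).
#' @param pairs pair table aligned with the labels.
#' @param elnc_fpkm optional numeric vector (per pair) of the mean FPKM of
#'   the enhancer's associated elncRNAs; NA where none.
#' @return `data.table`, one row per cluster.
#' @export
cluster_summaries <- function(result, pairs, elnc_fpkm = NULL) {
  labels <- if (inherits(result, "cluster_result")) result$labels else result
  stopifnot(length(labels) == nrow(pairs))
  if (is.null(elnc_fpkm)) elnc_fpkm <- rep(NA_real_, nrow(pairs))
  ks <- sort(unique(labels))
  rows <- lapply(ks, function(kk) {
    inK <- labels == kk
    rest <- !inK
    tt <- function(metric) {
      x <- metric[inK]; y <- metric[rest]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 2 || length(y) < 2) {
        list(t = NA_real_, p = NA_real_, skipped = TRUE)
      } else {
        r <- compare_groups(x, y)
        list(t = r$t, p = r$p, skipped = FALSE)
      }
    }
    t_if <- tt(pairs$raw_count)
    t_ex <- tt(pairs$target_fpkm)
    data.table(
      cluster = kk, n = sum(inK),
      mean_raw_count = mean(pairs$raw_count[inK]),
      median_raw_count = median(pairs$raw_count[inK]),
      mean_target_fpkm = mean(pairs$target_fpkm[inK], na.rm = TRUE),
      mean_elnc_fpkm = if (all(is.na(elnc_fpkm[inK]))) NA_real_ else
        mean(elnc_fpkm[inK], na.rm = TRUE),
      t_raw_count = t_if$t, p_raw_count = t_if$p,
      t_target_fpkm = t_ex$t, p_target_fpkm = t_ex$p,
      test_skipped = t_if$skipped || t_ex$skipped
    )
  })
  do.call(rbind, rows)
}

#' Agreement between two clusterings of the same rows
#'
#' Clusters of B are matched to clusters of A greedily on the contingency
#' table (largest cell first, each cluster matched at most once);
#' agreement is the percentage of rows whose B cluster is the one matched
#' to their A cluster.
#'
#' @param labelsA,labelsB `cluster_result` objects or label vectors over
#'   the same rows.
#' @return percentage in \[0, 100\].
#' @export
cluster_agreement <- function(labelsA, labelsB) {
  a <- if (inherits(labelsA, "cluster_result")) labelsA$labels else labelsA
  b <- if (inherits(labelsB, "cluster_result")) labelsB$labels else labelsB
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  matched <- 0
  while (length(tab) > 0 && nrow(tab) > 0 && ncol(tab) > 0 &&
         max(tab) > 0) {
    idx <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
    matched <- matched + tab[idx[1], idx[2]]
    tab <- tab[-idx[1], -idx[2], drop = FALSE]
  }
  100 * matched / length(a)
}
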