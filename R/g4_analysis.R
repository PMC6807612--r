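## G-quadruplex analyses: signal density profiles around elements and the
## two-group classification of lncRNAs by promoter vs gene-body G4 density.

#' Total G4 mass overlapping each region
#'
#' Mass is signal value x overlapping bp summed over G4 intervals (value
#' taken as 1 when the G4 set carries no `value` column).
#'
#' @param regions `GRanges`.
#' @param g4 `GRanges` of G4 intervals, optionally with `mcols()$value`.
#' @return numeric vector of masses, one per region.
#' @export
g4_mass <- function(regions, g4) {
  out <- rep(0, length(regions))
  if (length(regions) == 0 || length(g4) == 0) return(out)
  vals <- mcols(g4)$value
  if (is.null(vals)) vals <- rep(1, length(g4))
  hits <- GenomicRanges::findOverlaps(regions, g4, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  ov <- GenomicRanges::pintersect(regions[queryHits(hits)],
                                  g4[subjectHits(hits)],
                                  ignore.strand = TRUE)
  mass <- GenomicRanges::width(ov) * vals[subjectHits(hits)]
  agg <- tapply(mass, queryHits(hits), sum)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' G-quadruplex profile around elements
#'
#' Mean per-bin G4 signal across element-centered windows. With a plain
#' interval set (no `value` column) the profile counts G4 interval
#' midpoints per bin per element; with a signal track (bedGraph values)
#' it is the mean per-bp signal in each bin. With `reference = "tss"` the
#' window centers on the element's TSS and minus-strand windows are
#' flipped so upstream lies at negative offsets.
#'
#' @param elements `GRanges`.
#' @param g4 `GRanges`, optionally with `value`.
#' @param flank half-window in bp (default 2000).
#' @param binsize bin width in bp (default 100).
#' @param reference "midpoint" or "tss".
#' @return `meta_profile` with bp-offset `bin_centers` and `values`.
#' @export
g4_profile <- function(elements, g4, flank = 2000, binsize = 100,
                       reference = c("midpoint", "tss")) {
  reference <- match.arg(reference)
  stopifnot(flank > 0, binsize > 0)
  n_bins <- as.integer(ceiling(2 * flank / binsize))
  centers <- -flank + (seq_len(n_bins) - 0.5) * binsize
  empty <- structure(list(bin_centers = centers,
                          values = rep(0, n_bins),
                          n_features = length(elements)),
                     class = "meta_profile")
  if (length(elements) == 0 || length(g4) == 0) return(empty)
  ref <- if (reference == "tss") feature_points(elements) else
    .midpoint0(elements)
  str <- as.character(GenomicRanges::strand(elements))
  flip <- reference == "tss" & str == "-"
  de <- data.table(chrom = as.character(GenomicRanges::seqnames(elements)),
                   ref = ref, flip = flip, eid = seq_along(elements))
  signal_mode <- !is.null(mcols(g4)$value)
  vals <- mcols(g4)$value
  if (is.null(vals)) vals <- rep(1, length(g4))
  dg <- data.table(chrom = as.character(GenomicRanges::seqnames(g4)),
                   s = GenomicRanges::start(g4) - 1,
                   e = GenomicRanges::end(g4),
                   value = vals)
  j <- merge(de, dg, by = "chrom", allow.cartesian = TRUE)
  if (nrow(j) == 0) return(empty)
  if (!signal_mode) {
    ## count interval midpoints per bin
    off <- (j$s + j$e) / 2 - j$ref
    off[j$flip] <- -off[j$flip]
    keep <- off >= -flank & off < flank
    if (!any(keep)) return(empty)
    bin <- floor((off[keep] + flank) / binsize) + 1L
    counts <- tabulate(bin, nbins = n_bins)
    values <- as.numeric(counts) / length(elements)
  } else {
    ## value-weighted bp overlap per bin
    a <- j$s - j$ref; b <- j$e - j$ref
    fa <- a; fa[j$flip] <- -b[j$flip]
    fb <- b; fb[j$flip] <- -a[j$flip]
    a <- pmax(fa, -flank); b <- pmin(fb, flank)
    keep <- b > a
    if (!any(keep)) return(empty)
    a <- a[keep]; b <- b[keep]; v <- j$value[keep]
    b1 <- floor((a + flank) / binsize) + 1L
    b2 <- ceiling((b + flank) / binsize)
    b2 <- pmin(b2, n_bins)
    nspan <- b2 - b1 + 1L
    seg <- rep(seq_along(a), nspan)
    bin <- unlist(lapply(seq_along(a),
                         function(i) seq.int(b1[i], b2[i])))
    bin_lo <- -flank + (bin - 1L) * binsize
    ovl <- pmin(b[seg], bin_lo + binsize) - pmax(a[seg], bin_lo)
    mass <- tapply(ovl * v[seg], bin, sum)
    counts <- rep(0, n_bins)
    counts[as.integer(names(mass))] <- as.numeric(mass)
    values <- counts / (length(elements) * binsize)
  }
  structure(list(bin_centers = centers, values = values,
                 n_features = length(elements)),
            class = "meta_profile")
}

#' Classify lncRNAs by promoter vs gene-body G4 density
#'
#' Per gene, the G4 density (mass per bp, see [g4_mass()]) of its promoter
#' and of its gene body (gene span minus any promoter overlap) are
#' compared: promoter_biased iff promoter density strictly exceeds body
#' density; ties (including zero-zero) fall to body_biased and their count
#' is reported. Genes whose body vanishes after subtracting the promoter
#' are excluded with a warning.
#'
#' @param genes gene table of the lncRNAs to classify.
#' @param promoters promoter `GRanges` aligned row-for-row with `genes`.
#' @param g4 G4 `GRanges` (optional `value`).
#' @param quiet suppress the tie-count message.
#' @return `data.table`: gene_id, promoter_density, body_density, group,
#'   fpkm.
#' @export
group_by_g4_location <- function(genes, promoters, g4, quiet = FALSE) {
  stopifnot(nrow(genes) == length(promoters))
  gene_gr <- genes_to_granges(genes)
  ## body = gene span minus its promoter overlap; computed arithmetically
  ## as (gene mass - overlap mass) / (gene length - overlap length)
  inter <- GenomicRanges::pintersect(gene_gr, promoters,
                                     ignore.strand = TRUE,
                                     drop.nohit.ranges = FALSE)
  inter_w <- ifelse(mcols(inter)$hit, GenomicRanges::width(inter), 0)
  inter_m <- ifelse(mcols(inter)$hit, g4_mass(inter, g4), 0)
  body_len <- GenomicRanges::width(gene_gr) - inter_w
  drop <- body_len <= 0
  if (any(drop)) {
    warning(sprintf("%d gene(s) excluded: zero-length body after removing %s",
                    sum(drop), "the promoter"))
  }
  keep <- which(!drop)
  prom_density <- g4_mass(promoters[keep], g4) /
    GenomicRanges::width(promoters[keep])
  body_mass <- g4_mass(gene_gr[keep], g4) - inter_m[keep]
  body_mass <- pmax(body_mass, 0)
  body_density <- body_mass / body_len[keep]
  group <- ifelse(prom_density > body_density, "promoter_biased",
                  "body_biased")
  n_ties <- sum(prom_density == body_density)
  if (!quiet && n_ties > 0) {
    message(sprintf("group_by_g4_location: %d tie(s) assigned body_biased",
                    n_ties))
  }
  data.table(gene_id = genes$gene_id[keep],
             promoter_density = prom_density,
             body_density = body_density,
             group = group,
             fpkm = genes$fpkm[keep])
}

#' Compare expression between G4-location groups
#'
#' Two-sided pooled Student's t-test on FPKM between promoter_biased and
#' body_biased lncRNAs.
#'
#' @param groups table from [group_by_g4_location()].
#' @param welch use Welch's t-test.
#' @return list with `mean_promoter_biased`, `mean_body_biased`, `t`, `p`.
#' @export
compare_group_expression <- function(groups, welch = FALSE) {
  a <- groups$fpkm[groups$group == "promoter_biased"]
  b <- groups$fpkm[groups$group == "body_biased"]
  if (length(a) == 0 || length(b) == 0) stop("both G4 groups must be non-empty")
  r <- compare_groups(a, b, welch = welch)
  list(mean_promoter_biased = r$mean_a, mean_body_biased = r$mean_b,
       t = r$t, p = r$p, n_promoter_biased = r$n_a, n_body_biased = r$n_b)
}
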