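## Element definitions: promoters, filtered enhancers, active enhancers,
## elncRNAs and lncRNA expression categories.

#' Define promoters around transcription start sites
#'
#' A promoter extends a fixed distance upstream and downstream of each TSS,
#' strand-aware, clamped at the chromosome start. Defaults are 2 kb
#' upstream and 0.5 kb downstream. Each row of the gene table contributes
#' one promoter at its 5' end.
#'
#' @param genes gene table (see [read_gene_table()]).
#' @param upstream,downstream extent in bp on the transcribed-strand
#'   upstream/downstream sides of the TSS.
#' @return `GRanges` of promoters with `id`, `gene_id` and `fpkm` metadata.
#' @export
define_promoters <- function(genes, upstream = 2000, downstream = 500) {
  stopifnot(upstream >= 0, downstream >= 0)
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  ## 0-based half-open windows; the minus-strand window mirrors the plus one
  ## around the TSS base.
  start0 <- ifelse(plus, tss - upstream, tss - downstream + 1)
  end0 <- ifelse(plus, tss + downstream, tss + upstream + 1)
  start0 <- pmax(start0, 0)
  gr <- granges0(genes$chrom, start0, end0, genes$strand, id = genes$gene_id)
  mcols(gr)$gene_id <- genes$gene_id
  mcols(gr)$fpkm <- genes$fpkm
  gr
}

#' Exclude enhancers falling in coding promoters or gene bodies
#'
#' Retains enhancers that overlap (by >= 1 bp) neither a protein-coding
#' gene body nor a coding-gene promoter. Input order is preserved.
#'
#' @param enhancers `GRanges` of enhancer regions.
#' @param coding_genes gene table restricted to protein-coding genes (rows
#'   with other biotypes are ignored).
#' @param promoters promoter `GRanges` derived from the coding genes.
#' @param quiet suppress the removal-count message.
#' @return filtered `GRanges`, with attributes `n_removed_body` and
#'   `n_removed_promoter`.
#' @export
filter_enhancers <- function(enhancers, coding_genes, promoters,
                             quiet = FALSE) {
  coding <- coding_genes[coding_genes$biotype == "protein_coding", ]
  bodies <- genes_to_granges(coding)
  in_body <- IRanges::overlapsAny(enhancers, bodies, ignore.strand = TRUE)
  in_prom <- IRanges::overlapsAny(enhancers, promoters, ignore.strand = TRUE)
  keep <- !(in_body | in_prom)
  if (!quiet) {
    message(sprintf(
      "filter_enhancers: removed %d in gene bodies, %d in promoters; %d kept",
      sum(in_body), sum(in_prom & !in_body), sum(keep)))
  }
  out <- enhancers[keep]
  attr(out, "n_removed_body") <- sum(in_body)
  attr(out, "n_removed_promoter") <- sum(in_prom & !in_body)
  out
}

#' Call active enhancers from transcriptional-regulatory peaks
#'
#' An enhancer is active iff it lies within `max_gap` bp of a GRO-seq
#' derived peak (gap 0 when overlapping or abutting).
#'
#' @param enhancers `GRanges` of (filtered) enhancers.
#' @param gro_peaks `GRanges` of peaks.
#' @param max_gap maximum gap in bp (default 1000).
#' @return the enhancers with logical `active` and empty `elncRNA_ids`
#'   metadata (filled by [call_elncRNAs()]).
#' @export
call_active_enhancers <- function(enhancers, gro_peaks, max_gap = 1000) {
  stopifnot(max_gap >= 0)
  active <- rep(FALSE, length(enhancers))
  if (length(gro_peaks) > 0 && length(enhancers) > 0) {
    hits <- GenomicRanges::distanceToNearest(enhancers, gro_peaks,
                                             ignore.strand = TRUE)
    d <- rep(NA_real_, length(enhancers))
    d[queryHits(hits)] <- mcols(hits)$distance
    active <- !is.na(d) & d <= max_gap
  }
  mcols(enhancers)$active <- active
  mcols(enhancers)$elncRNA_ids <- IRanges::CharacterList(
    rep(list(character(0)), length(enhancers)))
  enhancers
}

#' Identify elncRNAs from lncRNA / active-enhancer overlap
#'
#' A lncRNA is an elncRNA iff its gene span overlaps at least one active
#' enhancer. Each active enhancer records the ids of the elncRNAs it
#' overlaps.
#'
#' @param lncRNAs gene table restricted to lncRNA biotype.
#' @param enhancers annotated enhancers from [call_active_enhancers()].
#' @param quiet suppress the fraction message.
#' @return list with `elncRNA_ids` (character), `enhancers` (with
#'   back-links in `elncRNA_ids`), and `fraction` of lncRNAs called.
#' @export
call_elncRNAs <- function(lncRNAs, enhancers, quiet = FALSE) {
  stopifnot(!is.null(mcols(enhancers)$active))
  lnc_gr <- genes_to_granges(lncRNAs)
  act <- which(mcols(enhancers)$active)
  ids <- character(0)
  if (length(act) > 0 && length(lnc_gr) > 0) {
    hits <- GenomicRanges::findOverlaps(enhancers[act], lnc_gr,
                                        ignore.strand = TRUE)
    ids <- unique(lncRNAs$gene_id[subjectHits(hits)])
    by_enh <- split(lncRNAs$gene_id[subjectHits(hits)],
                    factor(queryHits(hits), levels = seq_along(act)))
    links <- mcols(enhancers)$elncRNA_ids
    links[act] <- IRanges::CharacterList(lapply(by_enh, unique))
    mcols(enhancers)$elncRNA_ids <- links
  }
  frac <- if (nrow(lncRNAs)) length(ids) / nrow(lncRNAs) else 0
  if (!quiet) {
    message(sprintf("call_elncRNAs: %d / %d lncRNAs (%.2f%%) are elncRNAs",
                    length(ids), nrow(lncRNAs), 100 * frac))
  }
  list(elncRNA_ids = ids, enhancers = enhancers, fraction = frac)
}

#' Classify lncRNA expression levels
#'
#' Genes with FPKM >= `threshold` are expressed; the expressed set is split
#' at its median FPKM into equal low/high halves. Values strictly below the
#' median are low, strictly above are high; ties at the median go to the
#' low half until the halves balance (low receives the extra member when
#' the expressed count is odd). Deterministic, no randomness.
#'
#' @param fpkm numeric FPKM vector.
#' @param threshold expression threshold (default 0.21 FPKM).
#' @return character vector of labels: "not_expressed", "low" or "high".
#' @export
classify_expression <- function(fpkm, threshold = 0.21) {
  stopifnot(threshold > 0)
  labels <- rep("not_expressed", length(fpkm))
  expressed <- which(fpkm >= threshold)
  if (length(expressed) > 0) {
    ord <- expressed[order(fpkm[expressed])]
    n_low <- ceiling(length(ord) / 2)
    labels[ord[seq_len(n_low)]] <- "low"
    if (n_low < length(ord)) {
      labels[ord[(n_low + 1):length(ord)]] <- "high"
    }
  }
  labels
}
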