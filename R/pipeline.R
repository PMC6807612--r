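## End-to-end orchestration: annotate -> contacts -> loops -> cluster ->
## g4 -> report, with a flat key/value summary of every headline
## comparison and TSV intermediates.

.safe_compare <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    return(list(mean_a = if (length(a)) mean(a) else NA_real_,
                mean_b = if (length(b)) mean(b) else NA_real_,
                t = NA_real_, p = NA_real_, n_a = length(a),
                n_b = length(b), skipped = TRUE))
  }
  c(compare_groups(a, b, welch = welch), skipped = FALSE)
}

#' Run the full elncRNA / chromatin-interaction analysis
#'
#' Executes the stages in dependency order on a synthetic bundle (from
#' [generate()]) or a bundle directory (see [read_bundle()]): element
#' annotation, enhancer-promoter pair calling, loop-anchor profiling,
#' structuring-factor clustering and G4 classification. All thresholds
#' are exposed with the analysis defaults (2 kb/0.5 kb promoters, 1 kb
#' activity gap, 0.21 FPKM, FDR < 0.001, 10/6 clusters).
#'
#' @param input bundle list or directory path.
#' @param out_dir optional directory for TSV intermediates and the report.
#' @param upstream,downstream promoter window (bp).
#' @param max_gap enhancer-activity gap to GRO-seq peaks (bp).
#' @param expressed_threshold FPKM threshold for expressed lncRNAs.
#' @param fdr_threshold retained-pair FDR cutoff (strict "<").
#' @param n_bins decay-model distance bins.
#' @param k_elnc,k_other cluster counts for elncRNA-associated and other
#'   pairs (clamped to the available row count, reported as `k_used`).
#' @param n_rel_bins loop relative-density bins.
#' @param n_random random draws for anchor enrichment.
#' @param flank,binsize anchor peak-profile window/bin (bp).
#' @param g4_flank,g4_binsize G4 profile window/bin (bp).
#' @param seed seed for the stochastic steps (anchor enrichment).
#' @param quiet suppress stage messages.
#' @return list of class `run_report` with per-stage results and a flat
#'   `summary` key/value `data.table`.
#' @export
run_all <- function(input, out_dir = NULL,
                    upstream = 2000, downstream = 500, max_gap = 1000,
                    expressed_threshold = 0.21,
                    fdr_threshold = 0.001, n_bins = 100,
                    k_elnc = 10, k_other = 6,
                    n_rel_bins = 40, n_random = 1000,
                    flank = 50000, binsize = 1000,
                    g4_flank = 2000, g4_binsize = 100,
                    seed = 1, quiet = TRUE) {
  bundle <- if (is.character(input)) read_bundle(input) else input
  for (nm in c("genes", "enhancers", "gro_peaks", "contacts", "loops")) {
    if (is.null(bundle[[nm]])) stop("input bundle lacks '", nm, "'")
  }
  genes <- bundle$genes
  coding <- genes[genes$biotype == "protein_coding", ]
  lnc <- genes[genes$biotype == "lncRNA", ]

  ## --- annotate ---------------------------------------------------------
  promoters <- define_promoters(coding, upstream, downstream)
  enh_f <- filter_enhancers(bundle$enhancers, coding, promoters,
                            quiet = quiet)
  ann <- call_active_enhancers(enh_f, bundle$gro_peaks, max_gap)
  elnc <- call_elncRNAs(lnc, ann, quiet = quiet)
  ann <- elnc$enhancers
  lnc_expr <- classify_expression(lnc$fpkm, expressed_threshold)
  annotate <- list(
    n_enhancers_in = length(bundle$enhancers),
    n_enhancers_kept = length(enh_f),
    n_removed_body = attr(enh_f, "n_removed_body"),
    n_removed_promoter = attr(enh_f, "n_removed_promoter"),
    n_active = sum(mcols(ann)$active),
    elncRNA_ids = elnc$elncRNA_ids,
    elncRNA_fraction = elnc$fraction,
    expression_labels = lnc_expr)

  ## --- contacts ---------------------------------------------------------
  ep <- build_ep_pairs(bundle$contacts, ann, promoters,
                       fdr_threshold = fdr_threshold, n_bins = n_bins)
  ret <- ep$retained
  is_e <- ret$class_label == "elncRNA_associated"
  cmp_if <- .safe_compare(ret$raw_count[is_e], ret$raw_count[!is_e])
  cmp_fpkm <- .safe_compare(ret$target_fpkm[is_e], ret$target_fpkm[!is_e])
  ## high/low expressed elncRNA split applied to pairs via the enhancer's
  ## associated elncRNAs
  elnc_fpkm_lookup <- setNames(lnc$fpkm, lnc$gene_id)
  elnc_expr_lookup <- setNames(lnc_expr, lnc$gene_id)
  pair_links <- mcols(ann)$elncRNA_ids[ret$enh_idx]
  pair_elnc_fpkm <- vapply(seq_len(nrow(ret)), function(i) {
    ids <- pair_links[[i]]
    if (length(ids) == 0) NA_real_ else
      mean(elnc_fpkm_lookup[ids], na.rm = TRUE)
  }, numeric(1))
  pair_elnc_class <- vapply(seq_len(nrow(ret)), function(i) {
    ids <- pair_links[[i]]
    if (length(ids) == 0) return(NA_character_)
    cl <- elnc_expr_lookup[ids]
    if (any(cl == "high")) "high" else if (any(cl == "low")) "low" else
      "not_expressed"
  }, character(1))
  cmp_if_expr <- .safe_compare(
    ret$raw_count[is_e & pair_elnc_class %in% "high"],
    ret$raw_count[is_e & pair_elnc_class %in% "low"])
  contacts_stage <- list(
    n_tested = nrow(ep$tested), n_retained = nrow(ret),
    n_elnc_pairs = sum(is_e), n_other_pairs = sum(!is_e),
    interaction_frequency = cmp_if,
    target_expression = cmp_fpkm,
    interaction_frequency_by_elnc_expression = cmp_if_expr,
    model = ep$model, pairs = ret, tested = ep$tested,
    pair_elnc_fpkm = pair_elnc_fpkm)

  ## --- loops ------------------------------------------------------------
  lnc_gr <- genes_to_granges(lnc)
  is_elnc_gene <- lnc$gene_id %in% elnc$elncRNA_ids
  elnc_gr <- lnc_gr[is_elnc_gene]
  other_gr <- lnc_gr[!is_elnc_gene]
  prof_elnc <- if (length(elnc_gr) > 0)
    loop_density_profile(bundle$loops, elnc_gr, n_rel_bins) else NULL
  prof_other <- if (length(other_gr) > 0)
    loop_density_profile(bundle$loops, other_gr, n_rel_bins) else NULL
  enr <- if (length(elnc_gr) > 0)
    anchor_enrichment(elnc_gr, loop_anchors(bundle$loops),
                      bundle$chrom_sizes, n_random = n_random,
                      seed = seed) else NULL
  part <- partition_anchors_by_elncRNA(loop_anchors(bundle$loops), elnc_gr)
  cmp_anchor_reads <- .safe_compare(
    mcols(part$containing)$anchor_reads, mcols(part$other)$anchor_reads)
  peak_profiles <- list()
  for (nm in intersect(c("YY1", "mergedTF"), names(bundle$factors))) {
    pk <- bundle$factors[[nm]]$ranges
    peak_profiles[[nm]] <- list(
      containing = anchor_peak_profile(part$containing, pk, flank, binsize),
      other = anchor_peak_profile(part$other, pk, flank, binsize))
  }
  target_anchors <- find_elncRNA_target_anchors(
    loop_anchors(bundle$loops), elnc_gr, bundle$contacts,
    fdr_threshold = fdr_threshold, n_bins = n_bins)
  loops_stage <- list(
    density_elnc = prof_elnc, density_other = prof_other,
    anchor_enrichment = enr,
    n_anchors_containing = length(part$containing),
    n_anchors_other = length(part$other),
    anchor_reads = cmp_anchor_reads,
    peak_profiles = peak_profiles,
    n_target_anchors = length(target_anchors))

  ## --- cluster ----------------------------------------------------------
  cluster_stage <- list(skipped = TRUE)
  if (length(bundle$factors) > 0 && nrow(ret) >= 4) {
    factors <- bundle$factors
    raw <- build_signal_matrix(ret, ann, promoters, factors)
    sm <- suppressWarnings(znormalize(raw))
    clus_one <- function(rows, k) {
      if (sum(rows) < 3) return(NULL)
      k_used <- min(k, sum(rows) - 1)
      if (k_used < 2) return(NULL)
      res <- cluster_pairs(sm$z[rows, , drop = FALSE], k_used)
      summ <- cluster_summaries(res, ret[rows, ],
                                contacts_stage$pair_elnc_fpkm[rows])
      list(result = res, summaries = summ, k_used = k_used)
    }
    cl_e <- clus_one(is_e, k_elnc)
    cl_o <- clus_one(!is_e, k_other)
    ## robustness: re-cluster elncRNA pairs on the 6-factor panel
    agree <- NA_real_
    if (!is.null(cl_e)) {
      p6 <- default_factor_panel("panel6")$name
      keep_cols <- colnames(sm$z)[sub("_(enh|prom)$", "", colnames(sm$z))
                                  %in% p6]
      if (length(keep_cols) >= 2) {
        res6 <- cluster_pairs(sm$z[is_e, keep_cols, drop = FALSE],
                              min(6, cl_e$k_used))
        agree <- cluster_agreement(cl_e$result, res6)
      }
    }
    cluster_stage <- list(skipped = FALSE, matrix = sm,
                          elnc = cl_e, other = cl_o,
                          agreement_panel6 = agree)
  }

  ## --- g4 ---------------------------------------------------------------
  g4_stage <- list(skipped = TRUE)
  if (length(bundle$g4) > 0) {
    enh_is_e <- lengths(mcols(ann)$elncRNA_ids) > 0
    prof_enh_e <- g4_profile(ann[enh_is_e], bundle$g4, g4_flank,
                             g4_binsize, "midpoint")
    prof_enh_o <- g4_profile(ann[!enh_is_e], bundle$g4, g4_flank,
                             g4_binsize, "midpoint")
    hi <- is_elnc_gene & lnc_expr == "high"
    lo <- is_elnc_gene & lnc_expr == "low"
    prof_tss_hi <- g4_profile(lnc_gr[hi], bundle$g4, g4_flank,
                              g4_binsize, "tss")
    prof_tss_lo <- g4_profile(lnc_gr[lo], bundle$g4, g4_flank,
                              g4_binsize, "tss")
    elnc_tab <- lnc[is_elnc_gene, ]
    g4_groups <- NULL; g4_cmp <- NULL
    if (nrow(elnc_tab) > 0) {
      elnc_prom <- define_promoters(elnc_tab, upstream, downstream)
      g4_groups <- suppressWarnings(
        group_by_g4_location(elnc_tab, elnc_prom, bundle$g4, quiet = quiet))
      if (all(c("promoter_biased", "body_biased") %in% g4_groups$group)) {
        g4_cmp <- .safe_compare(
          g4_groups$fpkm[g4_groups$group == "promoter_biased"],
          g4_groups$fpkm[g4_groups$group == "body_biased"])
      }
    }
    g4_stage <- list(skipped = FALSE,
                     profile_enh_elnc = prof_enh_e,
                     profile_enh_other = prof_enh_o,
                     profile_tss_high = prof_tss_hi,
                     profile_tss_low = prof_tss_lo,
                     groups = g4_groups, expression = g4_cmp)
  }

  report <- structure(list(annotate = annotate, contacts = contacts_stage,
                           loops = loops_stage, cluster = cluster_stage,
                           g4 = g4_stage,
                           params = list(upstream = upstream,
                                         downstream = downstream,
                                         max_gap = max_gap,
                                         expressed_threshold =
                                           expressed_threshold,
                                         fdr_threshold = fdr_threshold,
                                         n_bins = n_bins, k_elnc = k_elnc,
                                         k_other = k_other, seed = seed)),
                      class = "run_report")
  report$summary <- report_summary(report)
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Flat key/value summary of a run
#'
#' @param report a `run_report`.
#' @return `data.table` with `key` and `value` columns.
#' @export
report_summary <- function(report) {
  a <- report$annotate; ct <- report$contacts; lp <- report$loops
  num <- function(x) if (is.null(x) || length(x) == 0) NA_real_ else
    as.numeric(x[1])
  rows <- list(
    enhancers_in = num(a$n_enhancers_in),
    enhancers_kept = num(a$n_enhancers_kept),
    enhancers_removed_body = num(a$n_removed_body),
    enhancers_removed_promoter = num(a$n_removed_promoter),
    active_enhancers = num(a$n_active),
    n_elncRNA = length(a$elncRNA_ids),
    elncRNA_fraction = num(a$elncRNA_fraction),
    pairs_tested = num(ct$n_tested),
    pairs_retained = num(ct$n_retained),
    pairs_elnc = num(ct$n_elnc_pairs),
    pairs_other = num(ct$n_other_pairs),
    mean_if_elnc = num(ct$interaction_frequency$mean_a),
    mean_if_other = num(ct$interaction_frequency$mean_b),
    t_if = num(ct$interaction_frequency$t),
    p_if = num(ct$interaction_frequency$p),
    mean_fpkm_elnc_targets = num(ct$target_expression$mean_a),
    mean_fpkm_other_targets = num(ct$target_expression$mean_b),
    p_fpkm = num(ct$target_expression$p),
    mean_if_high_expr = num(
      ct$interaction_frequency_by_elnc_expression$mean_a),
    mean_if_low_expr = num(
      ct$interaction_frequency_by_elnc_expression$mean_b),
    anchor_enrichment_fold = num(lp$anchor_enrichment$fold),
    anchors_containing = num(lp$n_anchors_containing),
    anchors_other = num(lp$n_anchors_other),
    mean_anchor_reads_containing = num(lp$anchor_reads$mean_a),
    mean_anchor_reads_other = num(lp$anchor_reads$mean_b),
    p_anchor_reads = num(lp$anchor_reads$p),
    target_anchors = num(lp$n_target_anchors),
    cluster_agreement_panel6 = if (isTRUE(report$cluster$skipped))
      NA_real_ else num(report$cluster$agreement_panel6),
    g4_mean_fpkm_promoter_biased = if (isTRUE(report$g4$skipped))
      NA_real_ else num(report$g4$expression$mean_a),
    g4_mean_fpkm_body_biased = if (isTRUE(report$g4$skipped))
      NA_real_ else num(report$g4$expression$mean_b),
    g4_p_expression = if (isTRUE(report$g4$skipped)) NA_real_ else
      num(report$g4$expression$p))
  out <- data.table(k = names(rows), value = unname(unlist(rows)))
  data.table::setnames(out, "k", "key")
  out[]
}

#' Write report TSVs and a text summary
#'
#' @param report a `run_report`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(report$summary, file.path(out_dir, "report_summary.tsv"),
         sep = "\t")
  fwrite(report$contacts$pairs, file.path(out_dir, "pairs_retained.tsv"),
         sep = "\t")
  fwrite(report$contacts$tested, file.path(out_dir, "pairs_tested.tsv"),
         sep = "\t")
  if (!isTRUE(report$cluster$skipped)) {
    if (!is.null(report$cluster$elnc)) {
      fwrite(report$cluster$elnc$summaries,
             file.path(out_dir, "cluster_summaries_elnc.tsv"), sep = "\t")
    }
    if (!is.null(report$cluster$other)) {
      fwrite(report$cluster$other$summaries,
             file.path(out_dir, "cluster_summaries_other.tsv"), sep = "\t")
    }
  }
  if (!isTRUE(report$g4$skipped) && !is.null(report$g4$groups)) {
    fwrite(report$g4$groups, file.path(out_dir, "g4_groups.tsv"),
           sep = "\t")
  }
  prof_tab <- function(p, group) {
    if (is.null(p)) return(NULL)
    data.table(bin = p$bin_centers, value = p$values, group = group)
  }
  profs <- rbind(prof_tab(report$loops$density_elnc, "elncRNA"),
                 prof_tab(report$loops$density_other, "other_lncRNA"))
  if (!is.null(profs)) {
    fwrite(profs, file.path(out_dir, "loop_density_profiles.tsv"),
           sep = "\t")
  }
  txt <- c("elncloop run report",
           sprintf("  %-34s %s", report$summary$key,
                   formatC(report$summary$value, digits = 6,
                           format = "g")))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("elncloop run report\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-34s %s\n", s$key[i],
                formatC(s$value[i], digits = 6, format = "g")))
  }
  invisible(x)
}
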