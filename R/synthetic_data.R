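## Seeded synthetic-data generator. Emits a toy genome whose statistical
## structure matches what the analysis assumes: genes and lncRNAs,
## enhancers respecting the coding-region exclusion rules, GRO-seq peaks
## colocated with active enhancers, power-law distance-decay Hi-C contacts
## with a planted contact-frequency multiplier on elncRNA-associated
## pairs, loops with anchor-proximal lncRNA placement, per-factor peak
## signals with planted cluster signatures, and G4 signal with a planted
## promoter-vs-gene-body bias. Truth tables record every planted label.

#' Default structuring-factor signatures
#'
#' Six raw-scale mean signal vectors over the 10-factor panel (enhancer
#' and promoter side per factor), mimicking the recurring motifs of
#' factor-signal heatmaps: architectural-only (CTCF/RAD21/SMC3),
#' RNAPII+YY1, merged-TF-rich, G4-rich, promoter-only signal, and a
#' low-signal cluster. The low cluster keeps a weak residual baseline on
#' the enhancer-side TF columns no other signature occupies: a perfectly
#' flat mean profile has no correlation structure at all and could not
#' form a cluster under a Pearson-distance metric, whereas quiescent
#' pairs in real data retain weak dispersed TF binding.
#'
#' @param factors character vector of factor names.
#' @return numeric matrix, clusters x (2 x factors), with dimnames.
#' @export
default_factor_signatures <- function(factors = default_factor_panel()$name) {
  cols <- c(paste0(factors, "_enh"), paste0(factors, "_prom"))
  sig <- matrix(1, nrow = 6, ncol = length(cols),
                dimnames = list(paste0("sig", 1:6), cols))
  hi <- function(row, nms, value = 8) {
    nms <- intersect(nms, cols)
    sig[row, nms] <<- value
  }
  hi(1, c("CTCF_enh", "RAD21_enh", "SMC3_enh",
          "CTCF_prom", "RAD21_prom", "SMC3_prom"))
  hi(2, c("POLR2A_enh", "YY1_enh", "POLR2A_prom", "YY1_prom"))
  hi(3, c("mergedTF_enh", "mergedTF_prom"), value = 10)
  hi(4, c("G4_enh", "G4_prom"))
  hi(5, c("YY1_prom", "HDGF_prom", "GATAD2B_prom", "GABPA_prom"))
  sig[6, ] <- 0.5
  hi(6, c("HDGF_enh", "GATAD2B_enh", "GABPA_enh"), value = 1.5)
  sig
}

#' Default 10-factor structuring panel
#'
#' CTCF, RAD21, SMC3, RNA POLII (POLR2A), YY1, HDGF, GATAD2B, GABPA, the
#' G-quadruplex signal and the merged-TF peak set, with their signal
#' assignment modes. Presets "panel6" (architectural + POLII + merged TFs
#' + G4) and "panel16" (six extra chromatin TFs) support robustness
#' re-clustering.
#'
#' @param preset "panel10", "panel6" or "panel16".
#' @return `data.table` with columns name and mode.
#' @export
default_factor_panel <- function(preset = c("panel10", "panel6", "panel16")) {
  preset <- match.arg(preset)
  base <- data.table(
    name = c("CTCF", "RAD21", "SMC3", "POLR2A", "YY1", "HDGF", "GATAD2B",
             "GABPA", "G4", "mergedTF"),
    mode = c(rep("max_value", 8), "signal_track", "count"))
  switch(preset,
    panel10 = base,
    panel6 = base[base$name %in% c("CTCF", "RAD21", "SMC3", "POLR2A",
                                   "G4", "mergedTF"), ],
    panel16 = rbind(base, data.table(
      name = c("NRF1", "HSF1", "NRSF", "MAX", "MAZ", "CHD1"),
      mode = "max_value")))
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic generator with validation.
#' Contact counts per candidate pair are Poisson with expectation
#' proportional to distance^(-decay_exponent), scaled so expectations sum
#' to `total_contacts`, and multiplied by `elnc_pair_multiplier` for
#' elncRNA-associated pairs.
#'
#' @param n_chroms,chrom_length genome shape (bp).
#' @param n_coding_genes,n_lncRNAs,n_enhancers element counts.
#' @param frac_active_enhancers fraction of enhancers near a GRO-seq peak.
#' @param frac_elncRNA fraction of lncRNAs planted as elncRNAs.
#' @param frac_lncRNA_near_anchors fraction of lncRNAs placed within 10%
#'   relative distance of a loop anchor.
#' @param n_loops,anchor_width loop geometry.
#' @param decay_exponent alpha in the d^-alpha contact decay.
#' @param total_contacts expected total intrachromosomal contact count.
#' @param elnc_pair_multiplier planted contact-frequency fold (>= 1).
#' @param factor_signatures clusters x columns mean-signal matrix (see
#'   [default_factor_signatures()]); NULL for no planted signatures.
#' @param signature_noise raw-scale Gaussian noise sd on factor signals.
#' @param g4_promoter_bias_frac fraction of elncRNAs planted
#'   promoter-biased for G4.
#' @param fpkm_meanlog,fpkm_sdlog lognormal expression parameters for
#'   expressed lncRNAs.
#' @param frac_invalid_enhancers fraction of extra enhancers planted
#'   inside coding promoters/bodies (known filter casualties).
#' @param min_pair_distance,max_pair_distance candidate pair distance
#'   range (bp).
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_chroms = 2, chrom_length = 2e7,
                       n_coding_genes = 120, n_lncRNAs = 400,
                       n_enhancers = 260,
                       frac_active_enhancers = 0.5,
                       frac_elncRNA = 0.25,
                       frac_lncRNA_near_anchors = 0.6,
                       n_loops = 60, anchor_width = 10000,
                       decay_exponent = 1, total_contacts = 2e5,
                       elnc_pair_multiplier = 1.3,
                       factor_signatures = default_factor_signatures(),
                       signature_noise = 1,
                       g4_promoter_bias_frac = 0.5,
                       fpkm_meanlog = 1.5, fpkm_sdlog = 1,
                       frac_invalid_enhancers = 0.1,
                       min_pair_distance = 20000,
                       max_pair_distance = 2e6,
                       seed = 1) {
  cfg <- as.list(environment())
  counts <- c(n_chroms, chrom_length, n_coding_genes, n_lncRNAs,
              n_enhancers, n_loops, anchor_width, total_contacts)
  if (any(counts <= 0)) stop("all counts and sizes must be positive")
  fr <- c(frac_active_enhancers, frac_elncRNA, frac_lncRNA_near_anchors,
          g4_promoter_bias_frac, frac_invalid_enhancers)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (elnc_pair_multiplier < 1) stop("elnc_pair_multiplier must be >= 1")
  ## capacity: total footprint must fit with room for rejection sampling
  ## loops may overlap each other; only exclusive placements count here
  footprint <- n_coding_genes * 55000 + n_lncRNAs * 10000 +
    n_enhancers * 2000
  if (footprint > 0.8 * n_chroms * chrom_length) {
    stop("infeasible placement: element footprint (", footprint,
         " bp) exceeds 80% of the genome; enlarge chrom_length")
  }
  if (chrom_length < 1.2e6) {
    stop("infeasible placement: chrom_length too short for loop spans")
  }
  structure(cfg, class = "sim_config")
}

.place_uniform <- function(n, width, chrom_sizes) {
  chrom <- sample(names(chrom_sizes), n, replace = TRUE)
  start <- floor(runif(n, 0, chrom_sizes[chrom] - width))
  data.table(chrom = chrom, start = start, end = start + width)
}

## sample n intervals of `width` bp keeping gap > min_gap from `avoid`
.place_avoiding <- function(n, width, chrom_sizes, avoid, min_gap = 0,
                            what = "elements") {
  got <- NULL
  for (i in 1:200) {
    need <- n - if (is.null(got)) 0 else nrow(got)
    if (need <= 0) break
    cand <- .place_uniform(max(need * 3, 10), width, chrom_sizes)
    if (length(avoid) > 0) {
      gr <- granges0(cand$chrom, cand$start, cand$end)
      d <- suppressWarnings(GenomicRanges::distanceToNearest(
        gr, avoid, ignore.strand = TRUE))
      dist <- rep(Inf, length(gr))
      dist[queryHits(d)] <- mcols(d)$distance
      cand <- cand[dist > min_gap, ]
    }
    got <- rbind(got, cand)
  }
  if (is.null(got) || nrow(got) < n) {
    stop("infeasible placement: could not place ", n, " ", what)
  }
  got[seq_len(n), ]
}

#' Simulate distance-matched pair counts for two classes
#'
#' Draws one shared set of pair distances and, for each class, Poisson
#' contact counts with expectation proportional to
#' distance^(-decay_exponent); the elncRNA-associated class expectation is
#' multiplied by the planted fold. Sharing distances across classes
#' isolates the multiplier from distance composition.
#'
#' @param n_per_class pairs per class.
#' @param total_contacts expected total count across both classes.
#' @param decay_exponent alpha.
#' @param multiplier planted fold for the elncRNA class.
#' @param min_distance,max_distance distance range (bp).
#' @param seed RNG seed.
#' @return `data.table` with class ("elncRNA_associated"/"non_elncRNA"),
#'   distance and raw_count.
#' @export
simulate_class_counts <- function(n_per_class, total_contacts,
                                  decay_exponent = 1, multiplier = 1.3,
                                  min_distance = 20000,
                                  max_distance = 2e6, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  d <- runif(n_per_class, min_distance, max_distance)
  w <- d^(-decay_exponent)
  lam_base <- total_contacts * w / sum(w * (1 + multiplier))
  counts_other <- rpois(n_per_class, lam_base)
  counts_elnc <- rpois(n_per_class, lam_base * multiplier)
  data.table(
    class = rep(c("elncRNA_associated", "non_elncRNA"),
                each = n_per_class),
    distance = c(d, d),
    raw_count = as.numeric(c(counts_elnc, counts_other)))
}

#' Simulate a planted-signature signal matrix
#'
#' Rows are drawn per cluster as signature mean + iid Gaussian noise.
#'
#' @param signatures clusters x columns mean matrix.
#' @param n_per_cluster rows per cluster.
#' @param sigma noise standard deviation.
#' @param seed RNG seed.
#' @return list with `mat` (matrix) and `labels` (true cluster per row).
#' @export
simulate_signal_matrix <- function(signatures, n_per_cluster = 200,
                                   sigma = 0.3, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- nrow(signatures)
  labels <- rep(seq_len(k), each = n_per_cluster)
  mat <- signatures[labels, , drop = FALSE] +
    matrix(rnorm(length(labels) * ncol(signatures), sd = sigma),
           nrow = length(labels))
  rownames(mat) <- NULL
  list(mat = mat, labels = labels)
}

#' Generate a full synthetic input bundle
#'
#' Deterministic for a fixed config (seed included in the config). See
#' [sim_config()] for the generative model. When `out_dir` is given, the
#' bundle is also written in the pipeline's interchange formats (gene
#' table TSV, BED, contact TSV, BEDPE, per-factor narrowPeak/BED/bedGraph,
#' factor manifest TSV) plus `truth/*.tsv`.
#'
#' @param config a `sim_config`.
#' @param out_dir optional output directory.
#' @return list: `genes`, `enhancers` (`GRanges`, includes planted-invalid
#'   ones), `gro_peaks`, `contacts`, `loops`, `factors` (named list of
#'   `ranges`+`mode`), `g4`, `chrom_sizes`, `truth` (list of tables),
#'   `config`.
#' @export
generate <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  L <- config$chrom_length
  chrom_sizes <- setNames(rep(L, config$n_chroms),
                          paste0("chr", seq_len(config$n_chroms)))

  ## --- protein-coding genes -------------------------------------------
  ng <- config$n_coding_genes
  glen <- floor(runif(ng, 5000, 50000))
  gchrom <- sample(names(chrom_sizes), ng, replace = TRUE)
  tss <- floor(runif(ng, glen + 1, L - glen - 1))
  gstrand <- sample(c("+", "-"), ng, replace = TRUE)
  gstart <- ifelse(gstrand == "+", tss, tss - glen + 1)
  gend <- gstart + glen
  coding <- data.table(chrom = gchrom, start = gstart, end = gend,
                       strand = gstrand,
                       gene_id = sprintf("PCG%04d", seq_len(ng)),
                       biotype = "protein_coding",
                       fpkm = rlnorm(ng, meanlog = 3, sdlog = 1))
  promoters <- define_promoters(coding)
  coding_blocked <- c(
    granges0(coding$chrom, coding$start, coding$end),
    granges0(granges_to_table(promoters)$chrom,
             granges_to_table(promoters)$start,
             granges_to_table(promoters)$end))

  ## --- chromatin loops -------------------------------------------------
  nl <- config$n_loops
  span <- floor(runif(nl, 2e5, 1e6))
  lchrom <- sample(names(chrom_sizes), nl, replace = TRUE)
  lstart <- floor(runif(nl, 0, L - span - 1))
  aw <- config$anchor_width
  loops_dt <- data.table(chrom = lchrom, start1 = lstart,
                         end1 = lstart + aw,
                         start2 = lstart + span - aw,
                         end2 = lstart + span,
                         anchor_reads = 0)

  ## --- lncRNAs (some anchor-proximal), elncRNA subset ------------------
  nlnc <- config$n_lncRNAs
  llen <- floor(runif(nlnc, 1000, 10000))
  near <- runif(nlnc) < config$frac_lncRNA_near_anchors
  lchr <- character(nlnc); lpos <- numeric(nlnc)
  pick <- sample(nl, nlnc, replace = TRUE)
  rel <- runif(nlnc, 0, 0.10)
  side <- sample(c(1, 2), nlnc, replace = TRUE)
  anchor_pos <- ifelse(side == 1,
                       loops_dt$start1[pick] + rel * span[pick],
                       loops_dt$end2[pick] - rel * span[pick])
  upos <- floor(runif(nlnc, llen, L - llen - 1))
  lpos <- ifelse(near, floor(anchor_pos), upos)
  lpos <- pmin(pmax(lpos, llen), L - llen - 1)
  lchr <- ifelse(near, loops_dt$chrom[pick],
                 sample(names(chrom_sizes), nlnc, replace = TRUE))
  lstrand <- sample(c("+", "-"), nlnc, replace = TRUE)
  lnc_start <- ifelse(lstrand == "+", lpos, lpos - llen + 1)
  lnc <- data.table(chrom = lchr, start = lnc_start,
                    end = lnc_start + llen, strand = lstrand,
                    gene_id = sprintf("LNC%04d", seq_len(nlnc)),
                    biotype = "lncRNA", fpkm = 0)
  ## elncRNA hosts are active enhancers, so they cannot outnumber the
  ## configured active-enhancer quota
  n_elnc_target <- min(round(config$frac_elncRNA * nlnc),
                       round(config$frac_active_enhancers *
                               config$n_enhancers))
  elnc_candidates <- sample(nlnc)  # shuffled; skipped when blocked below

  ## --- enhancers --------------------------------------------------------
  ## planted elncRNA enhancers overlap their lncRNA while avoiding coding
  ## bodies/promoters; remaining active ones avoid all lncRNAs too.
  ## lncRNAs buried in coding regions cannot host a rule-respecting
  ## enhancer; such candidates are skipped and replaced from the pool
  ew <- 1000
  enh_list <- list()
  for (ii in elnc_candidates) {
    if (length(enh_list) >= n_elnc_target) break
    for (try in 1:50) {
      s <- floor(runif(1, lnc$start[ii] - ew + 1, lnc$end[ii] - 1))
      s <- max(s, 0)
      cand <- granges0(lnc$chrom[ii], s, s + ew)
      if (!any(IRanges::overlapsAny(cand, coding_blocked,
                                    ignore.strand = TRUE))) {
        enh_list[[length(enh_list) + 1]] <-
          data.table(chrom = lnc$chrom[ii], start = s, end = s + ew,
                     planted_elnc = lnc$gene_id[ii])
        break
      }
    }
  }
  if (length(enh_list) < n_elnc_target) {
    stop("infeasible placement: only ", length(enh_list), " of ",
         n_elnc_target, " elncRNA host enhancers could be placed")
  }
  elnc_enh <- if (length(enh_list)) do.call(rbind, enh_list) else
    data.table(chrom = character(), start = numeric(), end = numeric(),
               planted_elnc = character())
  n_active <- max(round(config$frac_active_enhancers * config$n_enhancers),
                  nrow(elnc_enh))
  lnc_gr <- granges0(lnc$chrom, lnc$start, lnc$end)
  n_free_active <- n_active - nrow(elnc_enh)
  free_active <- if (n_free_active > 0) {
    .place_avoiding(n_free_active, ew, chrom_sizes,
                    c(coding_blocked, lnc_gr), min_gap = 0,
                    what = "active enhancers")
  } else NULL
  active_enh <- rbind(elnc_enh,
                      if (!is.null(free_active)) {
                        data.table(free_active, planted_elnc = NA_character_)
                      })
  active_enh$planted_active <- TRUE

  ## GRO-seq peaks: one per active enhancer, within the 1 kb activity gap
  pk_off <- floor(runif(nrow(active_enh), -800, 800))
  pk_start <- pmax(active_enh$start + pk_off, 0)
  gro_peaks <- granges0(active_enh$chrom, pk_start, pk_start + 300,
                        id = sprintf("peak%04d", seq_len(nrow(active_enh))))

  n_inactive <- config$n_enhancers - n_active
  inactive_enh <- if (n_inactive > 0) {
    data.table(.place_avoiding(n_inactive, ew, chrom_sizes,
                               gro_peaks, min_gap = 1000,
                               what = "inactive enhancers"),
               planted_elnc = NA_character_, planted_active = FALSE)
  } else NULL
  ## also keep inactive enhancers out of coding regions
  if (!is.null(inactive_enh)) {
    gr <- granges0(inactive_enh$chrom, inactive_enh$start, inactive_enh$end)
    bad <- IRanges::overlapsAny(gr, coding_blocked, ignore.strand = TRUE)
    if (any(bad)) {
      repl <- .place_avoiding(sum(bad), ew, chrom_sizes,
                              c(coding_blocked, gro_peaks), min_gap = 1000,
                              what = "inactive enhancers")
      inactive_enh[bad, c("chrom", "start", "end")] <-
        repl[, c("chrom", "start", "end")]
    }
  }
  n_invalid <- round(config$frac_invalid_enhancers * config$n_enhancers)
  invalid_enh <- if (n_invalid > 0) {
    host <- sample(ng, n_invalid, replace = TRUE)
    s <- floor(runif(n_invalid, coding$start[host],
                     pmax(coding$start[host] + 1, coding$end[host] - ew)))
    data.table(chrom = coding$chrom[host], start = s, end = s + ew,
               planted_elnc = NA_character_, planted_active = FALSE)
  } else NULL
  enh_dt <- rbind(active_enh, inactive_enh, invalid_enh, fill = TRUE)
  enh_dt$planted_valid <- c(rep(TRUE, nrow(active_enh) +
                                  (if (is.null(inactive_enh)) 0 else
                                     nrow(inactive_enh))),
                            rep(FALSE, if (is.null(invalid_enh)) 0 else
                              nrow(invalid_enh)))
  enh_dt$enh_id <- sprintf("ENH%04d", seq_len(nrow(enh_dt)))
  enhancers <- granges0(enh_dt$chrom, enh_dt$start, enh_dt$end,
                        id = enh_dt$enh_id)

  ## --- elncRNA truth, G4 bias and lncRNA expression ---------------------
  is_elnc <- lnc$gene_id %in% elnc_enh$planted_elnc
  g4_promoter_biased <- is_elnc &
    (runif(nlnc) < config$g4_promoter_bias_frac)
  if (config$elnc_pair_multiplier == 1 &&
      is.null(config$factor_signatures)) {
    ## null-style bundle keeps one expression law for everything
    lnc$fpkm <- rlnorm(nlnc, config$fpkm_meanlog, config$fpkm_sdlog)
  } else {
    lnc$fpkm <- ifelse(!is_elnc,
                       rlnorm(nlnc, meanlog = -1, sdlog = 1.5),
                       ifelse(g4_promoter_biased,
                              rlnorm(nlnc, meanlog = 2, sdlog = 0.5),
                              rlnorm(nlnc, meanlog = 1, sdlog = 0.5)))
  }

  ## anchor reads: baseline Poisson, boosted where an anchor holds an elncRNA
  anchors <- loop_anchors(loop_set(loops_dt))
  elnc_gr <- lnc_gr[is_elnc]
  has_elnc <- IRanges::overlapsAny(anchors, elnc_gr, ignore.strand = TRUE)
  per_loop_boost <- tapply(has_elnc, mcols(anchors)$loop_id, any)
  boost <- unname(per_loop_boost[paste0("loop_", seq_len(nl))])
  boost[is.na(boost)] <- FALSE
  boost_mult <- if (config$elnc_pair_multiplier > 1) 1.5 else 1
  loops_dt$anchor_reads <- rpois(nl, 60 * ifelse(boost, boost_mult, 1))
  loops <- loop_set(loops_dt)

  ## --- Hi-C contacts ----------------------------------------------------
  valid_enh <- enh_dt[enh_dt$planted_valid, ]
  cand <- merge(
    data.table(chrom = valid_enh$chrom,
               enh_id = valid_enh$enh_id,
               e_start = valid_enh$start, e_end = valid_enh$end,
               e_mid = (valid_enh$start + valid_enh$end) / 2,
               elnc = !is.na(valid_enh$planted_elnc)),
    data.table(chrom = coding$chrom, gene_id = coding$gene_id,
               p_tab = seq_len(ng)),
    by = "chrom", allow.cartesian = TRUE)
  ptab <- granges_to_table(promoters)
  cand$p_start <- ptab$start[cand$p_tab]
  cand$p_end <- ptab$end[cand$p_tab]
  cand$p_mid <- (cand$p_start + cand$p_end) / 2
  cand$distance <- abs(cand$e_mid - cand$p_mid)
  cand <- cand[cand$distance >= config$min_pair_distance &
                 cand$distance <= config$max_pair_distance, ]
  if (nrow(cand) == 0) stop("no candidate pairs in the distance range")
  w <- cand$distance^(-config$decay_exponent) *
    ifelse(cand$elnc, config$elnc_pair_multiplier, 1)
  cand$lambda <- config$total_contacts * w / sum(w)
  cand$raw_count <- rpois(nrow(cand), cand$lambda)
  hot <- cand[cand$raw_count > 0, ]
  contacts <- normalize_contacts(data.table(
    chrom = hot$chrom,
    pos1 = floor(runif(nrow(hot), hot$e_start, hot$e_end)),
    pos2 = floor(runif(nrow(hot), hot$p_start, hot$p_end)),
    count = hot$raw_count))

  ## --- structuring-factor signals ---------------------------------------
  factors <- list()
  truth_clusters <- NULL
  sig <- config$factor_signatures
  panel <- default_factor_panel()
  if (!is.null(sig)) {
    k <- nrow(sig)
    enh_cluster <- sample(k, nrow(enh_dt), replace = TRUE)
    gene_cluster <- sample(k, ng, replace = TRUE)
    ## a gene paired with an elncRNA enhancer inherits that cluster so the
    ## two element sides of a pair share a signature
    first_pair <- hot[!duplicated(hot$gene_id) & hot$elnc, ]
    if (nrow(first_pair) > 0) {
      gi <- match(first_pair$gene_id, coding$gene_id)
      ei <- match(first_pair$enh_id, enh_dt$enh_id)
      gene_cluster[gi] <- enh_cluster[ei]
    }
    noise <- config$signature_noise
    g4_rows <- NULL
    for (fi in seq_len(nrow(panel))) {
      nm <- panel$name[fi]; mode <- panel$mode[fi]
      e_mu <- sig[enh_cluster, paste0(nm, "_enh")]
      p_mu <- sig[gene_cluster, paste0(nm, "_prom")]
      e_val <- pmax(0.1, e_mu + rnorm(nrow(enh_dt), sd = noise))
      p_val <- pmax(0.1, p_mu + rnorm(ng, sd = noise))
      if (mode == "count") {
        e_n <- rpois(nrow(enh_dt), e_mu)
        p_n <- rpois(ng, p_mu)
        mk <- function(chrom, start, end, nrep) {
          idx <- rep(seq_along(nrep), nrep)
          if (length(idx) == 0) return(GenomicRanges::GRanges())
          s <- floor(runif(length(idx), start[idx],
                           pmax(start[idx] + 1, end[idx] - 50)))
          granges0(chrom[idx], s, s + 50)
        }
        gr <- c(mk(enh_dt$chrom, enh_dt$start, enh_dt$end, e_n),
                mk(ptab$chrom, ptab$start, ptab$end, p_n))
        factors[[nm]] <- list(ranges = gr, mode = "count")
      } else {
        gr <- c(granges0(enh_dt$chrom, enh_dt$start, enh_dt$end),
                granges0(ptab$chrom, ptab$start, ptab$end))
        mcols(gr)$value <- c(e_val, p_val)
        factors[[nm]] <- list(ranges = gr,
                              mode = if (nm == "G4") "signal_track" else
                                "max_value")
        if (nm == "G4") g4_rows <- gr
      }
    }
    truth_clusters <- data.table(enh_id = enh_dt$enh_id,
                                 cluster = enh_cluster)
  } else {
    ## flat low signal everywhere (null bundle)
    for (fi in seq_len(nrow(panel))) {
      nm <- panel$name[fi]
      gr <- granges0(enh_dt$chrom, enh_dt$start, enh_dt$end)
      mcols(gr)$value <- pmax(0.1, rnorm(nrow(enh_dt), 1, 0.5))
      factors[[nm]] <- list(ranges = gr,
                            mode = if (nm == "G4") "signal_track" else
                              if (nm == "mergedTF") "count" else "max_value")
    }
  }

  ## --- G4 signal with planted promoter-vs-body bias ---------------------
  lnc_prom <- define_promoters(lnc)
  lp_tab <- granges_to_table(lnc_prom)
  bias_on <- config$elnc_pair_multiplier > 1 ||
    !is.null(config$factor_signatures)
  mkg4 <- function(tab, value) {
    gr <- granges0(tab$chrom, tab$start, tab$end)
    mcols(gr)$value <- value
    gr
  }
  g4_parts <- list()
  ei <- which(is_elnc)
  if (length(ei) > 0 && bias_on) {
    pb <- ei[g4_promoter_biased[ei]]
    bb <- setdiff(ei, pb)
    if (length(pb) > 0) {
      g4_parts$pb_prom <- mkg4(lp_tab[pb, ], 2)
      g4_parts$pb_body <- mkg4(lnc[pb, ], 0.2)
    }
    if (length(bb) > 0) {
      g4_parts$bb_prom <- mkg4(lp_tab[bb, ], 0.2)
      g4_parts$bb_body <- mkg4(lnc[bb, ], 2)
    }
  } else if (length(ei) > 0) {
    g4_parts$flat <- mkg4(lp_tab[ei, ], 0.5)
  }
  g4 <- if (length(g4_parts)) do.call(c, unname(g4_parts)) else
    GenomicRanges::GRanges()

  genes <- rbind(coding, lnc)
  truth <- list(
    enhancers = enh_dt,
    elncRNA_ids = lnc$gene_id[is_elnc],
    pairs = cand[, c("chrom", "enh_id", "gene_id", "distance", "lambda",
                     "raw_count", "elnc")],
    clusters = truth_clusters,
    g4_groups = data.table(
      gene_id = lnc$gene_id[is_elnc],
      group = ifelse(g4_promoter_biased[is_elnc], "promoter_biased",
                     "body_biased")))
  bundle <- list(genes = genes, enhancers = enhancers,
                 gro_peaks = gro_peaks, contacts = contacts, loops = loops,
                 factors = factors, g4 = g4, chrom_sizes = chrom_sizes,
                 truth = truth, config = config)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' Generate a null input bundle
#'
#' Same generative process with every planted effect removed: contact
#' multiplier forced to 1, no factor signatures, no G4 bias, lncRNAs
#' placed independently of loop anchors, one expression law for all
#' lncRNAs.
#'
#' @param config a `sim_config`.
#' @param out_dir optional output directory.
#' @return bundle as from [generate()].
#' @export
generate_null <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config$elnc_pair_multiplier <- 1
  config$factor_signatures <- NULL
  config$frac_lncRNA_near_anchors <- 0
  config$g4_promoter_bias_frac <- 0
  generate(config, out_dir = out_dir)
}

#' Write a bundle to disk in the pipeline's interchange formats
#'
#' @param bundle from [generate()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "factors"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  write_gene_table(bundle$genes, file.path(out_dir, "genes.tsv"))
  write_bed(bundle$enhancers, file.path(out_dir, "enhancers.bed"))
  write_bed(bundle$gro_peaks, file.path(out_dir, "gro_peaks.bed"))
  write_contacts(bundle$contacts, file.path(out_dir, "contacts.tsv"))
  write_bedpe(bundle$loops, file.path(out_dir, "loops.bedpe"))
  manifest <- NULL
  for (nm in names(bundle$factors)) {
    f <- bundle$factors[[nm]]
    tab <- granges_to_table(f$ranges)
    if (f$mode == "count") {
      path <- file.path("factors", paste0(nm, ".bed"))
      fwrite(tab[, c("chrom", "start", "end")],
             file.path(out_dir, path), sep = "\t", col.names = FALSE)
    } else {
      path <- file.path("factors", paste0(nm, ".narrowPeak"))
      np <- data.table(tab$chrom, tab$start, tab$end, ".", 0L, ".",
                       mcols(f$ranges)$value, -1, -1, -1)
      fwrite(np, file.path(out_dir, path), sep = "\t", col.names = FALSE)
    }
    manifest <- rbind(manifest,
                      data.table(name = nm, path = path, mode = f$mode))
  }
  fwrite(manifest, file.path(out_dir, "factor_manifest.tsv"), sep = "\t")
  g4tab <- granges_to_table(bundle$g4)
  g4v <- if (length(bundle$g4)) mcols(bundle$g4)$value else numeric(0)
  fwrite(data.table(g4tab$chrom, g4tab$start, g4tab$end, g4v),
         file.path(out_dir, "g4.bedgraph"), sep = "\t", col.names = FALSE)
  fwrite(data.table(chrom = names(bundle$chrom_sizes),
                    size = unname(bundle$chrom_sizes)),
         file.path(out_dir, "chrom_sizes.tsv"), sep = "\t")
  for (nm in names(bundle$truth)) {
    obj <- bundle$truth[[nm]]
    if (is.null(obj)) next
    if (!is.data.frame(obj)) obj <- data.table(value = obj)
    fwrite(obj, file.path(out_dir, "truth", paste0(nm, ".tsv")), sep = "\t")
  }
  invisible(out_dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return list shaped like the output of [generate()] (without truth's
#'   in-memory extras; truth tables are re-read from `truth/`).
#' @export
read_bundle <- function(dir) {
  manifest <- fread(file.path(dir, "factor_manifest.tsv"))
  factors <- list()
  for (i in seq_len(nrow(manifest))) {
    p <- file.path(dir, manifest$path[i])
    rng <- if (manifest$mode[i] == "count") read_bed(p) else
      read_narrowpeak(p)
    factors[[manifest$name[i]]] <- list(ranges = rng,
                                        mode = manifest$mode[i])
  }
  cs <- fread(file.path(dir, "chrom_sizes.tsv"))
  truth_files <- list.files(file.path(dir, "truth"), full.names = TRUE)
  truth <- lapply(truth_files, fread)
  names(truth) <- sub("\\.tsv$", "", basename(truth_files))
  list(genes = read_gene_table(file.path(dir, "genes.tsv")),
       enhancers = read_bed(file.path(dir, "enhancers.bed")),
       gro_peaks = read_bed(file.path(dir, "gro_peaks.bed")),
       contacts = read_contacts(file.path(dir, "contacts.tsv")),
       loops = read_bedpe(file.path(dir, "loops.bedpe"), score_col = 8),
       factors = factors,
       g4 = read_bedgraph(file.path(dir, "g4.bedgraph")),
       chrom_sizes = setNames(cs$size, cs$chrom),
       truth = truth)
}
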