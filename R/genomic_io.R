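## Readers/writers for the plain-text formats the pipeline touches and the
## small interval algebra shared by every other module. External tables are
## BED-style 0-based half-open; GRanges objects are 1-based closed.

#' Convert 0-based half-open coordinates to a GRanges
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand strand characters ("+", "-" or "."); "." maps to "*".
#' @param id optional identifiers, stored in `mcols(x)$id`.
#' @return A [GenomicRanges::GRanges] object.
#' @export
granges0 <- function(chrom, start, end, strand = ".", id = NULL) {
  if (length(start) == 0) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(id)) mcols(gr)$id <- character(0)
    return(gr)
  }
  if (any(start < 0)) stop("negative start coordinate")
  if (any(end <= start)) stop("end must exceed start (half-open intervals)")
  str <- rep_len(ifelse(strand == ".", "*", strand), length(start))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                               strand = str)
  if (!is.null(id)) mcols(gr)$id <- as.character(id)
  gr
}

#' Extract 0-based half-open coordinates from a GRanges
#'
#' @param gr a `GRanges`.
#' @return A `data.table` with columns chrom, start, end, strand, id.
#' @export
granges_to_table <- function(gr) {
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    id = if (!is.null(mcols(gr)$id)) mcols(gr)$id else NA_character_
  )
}

.read_lines_noncomment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & !grepl("^track", lines) & nzchar(lines)
  list(lines = lines[keep], lineno = which(keep))
}

.parse_coord <- function(x, path, lineno, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- is.na(v) | v != floor(v)
  if (any(bad)) {
    stop(sprintf("%s: line %d: non-integer %s coordinate '%s'",
                 path, lineno[which(bad)[1]], what, x[which(bad)[1]]))
  }
  as.numeric(v)
}

#' Read a BED file
#'
#' BED3 upward; column 4 (if present) becomes the id, column 6 the strand.
#' Comment and "track" lines are skipped. Coordinates are validated
#' (integer, end > start) with errors naming the offending line.
#'
#' @param path path to a BED file.
#' @return `GRanges` in file order with `mcols()$id` when present.
#' @export
read_bed <- function(path) {
  lr <- .read_lines_noncomment(path)
  if (length(lr$lines) == 0) return(GenomicRanges::GRanges())
  f <- strsplit(lr$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 3)) {
    stop(sprintf("%s: line %d: expected >= 3 tab-separated fields",
                 path, lr$lineno[which(nf < 3)[1]]))
  }
  chrom <- vapply(f, `[`, "", 1L)
  start <- .parse_coord(vapply(f, `[`, "", 2L), path, lr$lineno, "start")
  end <- .parse_coord(vapply(f, `[`, "", 3L), path, lr$lineno, "end")
  bad <- end <= start
  if (any(bad)) {
    stop(sprintf("%s: line %d: end (%d) <= start (%d)", path,
                 lr$lineno[which(bad)[1]], end[which(bad)[1]],
                 start[which(bad)[1]]))
  }
  id <- ifelse(nf >= 4, vapply(f, `[`, "", 4L), NA_character_)
  strand <- ifelse(nf >= 6, vapply(f, `[`, "", 6L), ".")
  strand[!strand %in% c("+", "-")] <- "."
  granges0(chrom, start, end, strand, id = id)
}

#' Write intervals as BED
#'
#' @param gr `GRanges` to write.
#' @param path output path.
#' @param extra_cols optional character vector of `mcols` columns appended
#'   after the strand column.
#' @export
write_bed <- function(gr, path, extra_cols = NULL) {
  tab <- granges_to_table(gr)
  tab$score <- 0L
  tab <- tab[, c("chrom", "start", "end", "id", "score", "strand")]
  tab$id[is.na(tab$id)] <- "."
  for (col in extra_cols) tab[[col]] <- mcols(gr)[[col]]
  fwrite(tab, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' 10-column ENCODE narrowPeak; column 7 (signalValue) is stored as
#' `mcols()$value`, column 4 as `id`.
#'
#' @param path path to a narrowPeak file.
#' @return `GRanges` with `value` metadata.
#' @export
read_narrowpeak <- function(path) {
  gr <- read_bed(path)
  lr <- .read_lines_noncomment(path)
  if (length(lr$lines) == 0) return(gr)
  f <- strsplit(lr$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 7)) {
    stop(sprintf("%s: line %d: narrowPeak needs >= 7 fields",
                 path, lr$lineno[which(nf < 7)[1]]))
  }
  mcols(gr)$value <- as.numeric(vapply(f, `[`, "", 7L))
  gr
}

#' Read a 4-column bedGraph signal file
#'
#' @param path path to a bedGraph file.
#' @return `GRanges` with numeric `mcols()$value`.
#' @export
read_bedgraph <- function(path) {
  lr <- .read_lines_noncomment(path)
  if (length(lr$lines) == 0) return(GenomicRanges::GRanges())
  f <- strsplit(lr$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 4)) {
    stop(sprintf("%s: line %d: bedGraph needs 4 fields",
                 path, lr$lineno[which(nf < 4)[1]]))
  }
  gr <- granges0(vapply(f, `[`, "", 1L),
                 .parse_coord(vapply(f, `[`, "", 2L), path, lr$lineno, "start"),
                 .parse_coord(vapply(f, `[`, "", 3L), path, lr$lineno, "end"))
  mcols(gr)$value <- as.numeric(vapply(f, `[`, "", 4L))
  gr
}

#' Read chromatin loops from BEDPE
#'
#' Anchors are normalized so anchor1 precedes anchor2 on the chromosome.
#' Interchromosomal lines are skipped with a warning reporting the count.
#'
#' @param path path to a BEDPE file (>= 6 columns).
#' @param score_col optional 1-based column index holding the Hi-C read
#'   count between the anchors (stored as `anchor_reads`, else 0).
#' @return A `data.table` of class `loop_set` with 0-based half-open columns
#'   chrom, start1, end1, start2, end2, anchor_reads, loop_id.
#' @export
read_bedpe <- function(path, score_col = NULL) {
  lr <- .read_lines_noncomment(path)
  if (length(lr$lines) == 0) {
    return(loop_set(data.table(chrom = character(), start1 = numeric(),
                               end1 = numeric(), start2 = numeric(),
                               end2 = numeric(), anchor_reads = numeric())))
  }
  f <- strsplit(lr$lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 6)) {
    stop(sprintf("%s: line %d: BEDPE needs >= 6 fields",
                 path, lr$lineno[which(nf < 6)[1]]))
  }
  c1 <- vapply(f, `[`, "", 1L); c2 <- vapply(f, `[`, "", 4L)
  inter <- c1 != c2
  if (any(inter)) {
    warning(sprintf("%s: skipped %d interchromosomal loop line(s)",
                    path, sum(inter)))
    f <- f[!inter]; c1 <- c1[!inter]
    if (length(f) == 0) {
      return(loop_set(data.table(chrom = character(), start1 = numeric(),
                                 end1 = numeric(), start2 = numeric(),
                                 end2 = numeric(), anchor_reads = numeric())))
    }
    lr$lineno <- lr$lineno[!inter]
  }
  s1 <- .parse_coord(vapply(f, `[`, "", 2L), path, lr$lineno, "start1")
  e1 <- .parse_coord(vapply(f, `[`, "", 3L), path, lr$lineno, "end1")
  s2 <- .parse_coord(vapply(f, `[`, "", 5L), path, lr$lineno, "start2")
  e2 <- .parse_coord(vapply(f, `[`, "", 6L), path, lr$lineno, "end2")
  reads <- if (!is.null(score_col)) {
    as.numeric(vapply(f, `[`, "", score_col))
  } else rep(0, length(f))
  swap <- s2 < s1
  tmp_s <- s1[swap]; tmp_e <- e1[swap]
  s1[swap] <- s2[swap]; e1[swap] <- e2[swap]
  s2[swap] <- tmp_s; e2[swap] <- tmp_e
  loop_set(data.table(chrom = c1, start1 = s1, end1 = e1,
                      start2 = s2, end2 = e2, anchor_reads = reads))
}

#' Construct a loop set
#'
#' @param df data.frame with columns chrom, start1, end1, start2, end2 and
#'   optionally anchor_reads (0-based half-open coordinates).
#' @return the validated `loop_set` data.table.
#' @export
loop_set <- function(df) {
  dt <- as.data.table(df)
  if (is.null(dt$anchor_reads)) dt$anchor_reads <- 0
  if (nrow(dt) > 0) {
    stopifnot(all(dt$end1 > dt$start1), all(dt$end2 > dt$start2),
              all(dt$start1 < dt$start2))
    if (any(dt$end1 > dt$start2)) stop("loop anchors overlap")
  }
  dt$loop_id <- if (nrow(dt)) paste0("loop_", seq_len(nrow(dt))) else character()
  class(dt) <- c("loop_set", class(data.table()))
  dt
}

#' Extract loop anchors as a GRanges
#'
#' @param loops a `loop_set`.
#' @param which "both", 1 or 2.
#' @return `GRanges` of anchors with `loop_id` and `side` metadata and an
#'   `id` of the form "<loop_id>_a<side>".
#' @export
loop_anchors <- function(loops, which = "both") {
  a1 <- granges0(loops$chrom, loops$start1, loops$end1,
                 id = paste0(loops$loop_id, "_a1"))
  a2 <- granges0(loops$chrom, loops$start2, loops$end2,
                 id = paste0(loops$loop_id, "_a2"))
  mcols(a1)$loop_id <- loops$loop_id; mcols(a1)$side <- 1L
  mcols(a2)$loop_id <- loops$loop_id; mcols(a2)$side <- 2L
  mcols(a1)$anchor_reads <- loops$anchor_reads
  mcols(a2)$anchor_reads <- loops$anchor_reads
  switch(as.character(which), "1" = a1, "2" = a2, both = c(a1, a2))
}

#' Write loops as BEDPE
#'
#' @param loops a `loop_set`.
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  out <- data.table(loops$chrom, loops$start1, loops$end1,
                    loops$chrom, loops$start2, loops$end2,
                    loops$loop_id, loops$anchor_reads)
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an intrachromosomal Hi-C contact list
#'
#' Tab-separated columns: chrom, pos1, pos2, count. Records are normalized
#' so pos1 <= pos2 (Hi-C read pairs are end-symmetric).
#'
#' @param path path to the contact TSV.
#' @return `data.table` with columns chrom, pos1, pos2, count.
#' @export
read_contacts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "pos1", "pos2", "count"))
  if (nrow(dt) && any(dt$count < 1)) stop("contact counts must be >= 1")
  normalize_contacts(dt)
}

#' Normalize contact records
#'
#' Orders ends so pos1 <= pos2 and coerces counts to numeric.
#'
#' @param contacts data.frame with chrom, pos1, pos2, count.
#' @return normalized `data.table`.
#' @export
normalize_contacts <- function(contacts) {
  dt <- as.data.table(contacts)
  swap <- dt$pos2 < dt$pos1
  if (any(swap)) {
    tmp <- dt$pos1[swap]
    dt[swap, "pos1"] <- dt$pos2[swap]
    dt[swap, "pos2"] <- tmp
  }
  dt$count <- as.numeric(dt$count)
  dt[]
}

#' Write a contact list
#' @param contacts contact `data.table`.
#' @param path output path.
#' @export
write_contacts <- function(contacts, path) {
  fwrite(contacts[, c("chrom", "pos1", "pos2", "count")], path,
         sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-model table
#'
#' Tab-separated with header: chrom, start, end, strand, gene_id, biotype,
#' fpkm. Coordinates 0-based half-open; biotype is "protein_coding" or
#' "lncRNA".
#'
#' @param path path to the gene table.
#' @return `data.table` of gene models.
#' @export
read_gene_table <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("chrom", "start", "end", "strand", "gene_id", "biotype", "fpkm")
  if (!all(need %in% names(dt))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(dt) && !all(dt$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'")
  }
  dt
}

#' Write a gene-model table
#' @param genes gene `data.table`.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  fwrite(genes, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Gene models as a GRanges
#'
#' @param genes gene table from [read_gene_table()].
#' @return `GRanges` with gene_id (as `id`), biotype and fpkm metadata.
#' @export
genes_to_granges <- function(genes) {
  gr <- granges0(genes$chrom, genes$start, genes$end, genes$strand,
                 id = genes$gene_id)
  mcols(gr)$biotype <- genes$biotype
  mcols(gr)$fpkm <- genes$fpkm
  gr
}

#' Transcription start sites of gene models
#'
#' The TSS is the 5' end of the gene span: `start` on "+", `end - 1` on "-"
#' (0-based coordinates).
#'
#' @param genes gene table.
#' @return numeric vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

#' Pairwise interval overlap
#'
#' TRUE iff the two intervals share at least one base pair (same chromosome,
#' half-open semantics). Strand is ignored. Vectorized over pairs.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return logical vector.
#' @export
overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b)) &
    GenomicRanges::start(a) <= GenomicRanges::end(b) &
    GenomicRanges::start(b) <= GenomicRanges::end(a)
}

#' Gap distance between two intervals
#'
#' Number of base pairs strictly between two intervals on the same
#' chromosome; 0 when they overlap or abut; NA (the undefined-distance
#' signal) when they lie on different chromosomes.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return numeric vector of distances, NA across chromosomes.
#' @export
gap_distance <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1) a <- rep(a, n)
  if (length(b) == 1) b <- rep(b, n)
  suppressWarnings(GenomicRanges::distance(a, b, ignore.strand = TRUE))
}
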