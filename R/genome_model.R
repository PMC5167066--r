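# Genome sequences and gene models.
#
# Coordinate conventions used throughout the package:
#   * internal genomic coordinates are 0-based half-open [start, end);
#   * GFF3 I/O converts at the boundary (1-based inclusive on disk);
#   * user-facing point positions (CLI, variants) are 1-based;
#   * protein positions are 1-based residue indices.

#' Construct a contig
#'
#' @param name contig identifier (non-empty).
#' @param sequence DNA string over `A,C,G,T,N` (upper case).
#' @return an object of class `contig` with fields `name`, `sequence`,
#'   `length`.
#' @export
contig <- function(name, sequence) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    format_error("contig name must be a non-empty string")
  sequence <- toupper(sequence)
  bad <- setdiff(unique(chars(sequence)), DNA_ALPHABET)
  if (length(bad))
    format_error(sprintf("contig %s: illegal sequence character(s): %s",
                         name, paste(bad, collapse = ", ")))
  structure(list(name = name, sequence = sequence, length = nchar(sequence)),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("<contig %s: %d bp>\n", x$name, x$length))
  invisible(x)
}

#' Look up a contig by name
#' @param genome list of [contig()] objects.
#' @param name contig name.
#' @keywords internal
get_contig <- function(genome, name) {
  for (ctg in genome) if (ctg$name == name) return(ctg)
  lookup_error(sprintf("unknown contig '%s'", name))
}

#' Fetch single bases of a contig at 0-based offsets
#' @keywords internal
contig_bases <- function(ctg, offsets0) {
  if (any(offsets0 < 0L) || any(offsets0 >= ctg$length))
    range_error(sprintf("offset out of range for contig %s (length %d)",
                        ctg$name, ctg$length))
  substring(ctg$sequence, offsets0 + 1L, offsets0 + 1L)
}

#' Read a genome FASTA file
#'
#' Sequences are upper-cased and `U` is converted to `T`.  Characters outside
#' `A,C,G,T,N` are rejected.
#'
#' @param path path to a (multi-record) FASTA file.
#' @return list of [contig()] objects.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) format_error(
                    sprintf("cannot parse FASTA %s: %s", path, conditionMessage(e))))
  if (length(set) == 0L) format_error(sprintf("empty FASTA file: %s", path))
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    format_error(sprintf("duplicate contig name(s) in %s: %s", path,
                         paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  lapply(seq_along(set), function(i) {
    seq <- gsub("U", "T", toupper(as.character(set[[i]])), fixed = TRUE)
    contig(nms[i], seq)
  })
}

#' Write a genome FASTA file (60-column wrap, deterministic bytes)
#' @param genome list of [contig()] objects.
#' @param path output path.
#' @export
write_genome <- function(genome, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (ctg in genome) {
    writeLines(paste0(">", ctg$name), con, sep = "\n")
    starts <- seq(1L, ctg$length, by = 60L)
    writeLines(substring(ctg$sequence, starts, pmin(starts + 59L, ctg$length)),
               con, sep = "\n")
  }
  invisible(path)
}

#' Construct a genomic interval (0-based half-open)
#'
#' @param contig contig name.
#' @param start 0-based inclusive start offset.
#' @param end 0-based exclusive end offset (`start < end`).
#' @param strand `"+"` or `"-"`.
#' @return object of class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand) {
  if (!(strand %in% c("+", "-"))) model_error("strand must be '+' or '-'")
  if (!(start >= 0 && start < end))
    model_error(sprintf("invalid interval [%d,%d)", start, end))
  structure(list(contig = contig, start = as.integer(start),
                 end = as.integer(end), strand = strand),
            class = "genomic_interval")
}

# internal: intervals are carried inside transcripts as a data.frame with
# integer columns start/end (0-based half-open), already sorted by start.
interval_df <- function(start, end) {
  df <- data.frame(start = as.integer(start), end = as.integer(end))
  df[order(df$start), , drop = FALSE]
}

check_intervals <- function(df, what, id) {
  if (any(df$start >= df$end))
    model_error(sprintf("transcript %s: empty/negative %s interval", id, what))
  if (nrow(df) > 1L && any(df$start[-1L] < df$end[-nrow(df)]))
    model_error(sprintf("transcript %s: overlapping %s intervals", id, what))
  df
}

#' Construct a transcript
#'
#' Exon and CDS intervals are 0-based half-open on a single contig and
#' strand, kept in ascending genomic order.  `phase0` is the phase of the
#' first CDS segment in transcription order: the number of leading bases that
#' belong to an upstream (unannotated) codon.
#'
#' @param id transcript identifier.
#' @param gene_id,gene_name parent gene identifier and display name.
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds data.frames with 0-based half-open `start`,`end` columns
#'   (any order; they are sorted).  Every CDS interval must be contained in
#'   some exon.
#' @param phase0 integer 0--2.
#' @return object of class `transcript`.
#' @export
transcript <- function(id, gene_id, gene_name, contig, strand, exons, cds,
                       phase0 = 0L) {
  if (!(strand %in% c("+", "-"))) model_error("strand must be '+' or '-'")
  if (!(phase0 %in% 0:2)) model_error("phase0 must be 0, 1 or 2")
  exons <- check_intervals(interval_df(exons$start, exons$end), "exon", id)
  cds <- check_intervals(interval_df(cds$start, cds$end), "CDS", id)
  for (i in seq_len(nrow(cds))) {
    inside <- any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    if (!inside)
      model_error(sprintf(
        "transcript %s: CDS [%d,%d) not contained in any exon",
        id, cds$start[i], cds$end[i]))
  }
  if (sum(cds$end - cds$start) < 3L)
    model_error(sprintf("transcript %s: total CDS length < 3", id))
  structure(list(id = id, gene_id = gene_id, gene_name = gene_name,
                 contig = contig, strand = strand, exons = exons, cds = cds,
                 phase0 = as.integer(phase0)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s) %s:%s %d exon(s), CDS %d bp, phase0=%d>\n",
              x$id, x$gene_id, x$contig, x$strand, nrow(x$exons),
              sum(x$cds$end - x$cds$start), x$phase0))
  invisible(x)
}

#' Construct a gene model
#' @param gene_id gene identifier.
#' @param gene_name display name.
#' @param transcripts non-empty list of [transcript()] objects sharing
#'   `gene_id`.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name, transcripts) {
  if (length(transcripts) == 0L)
    model_error(sprintf("gene %s has no transcripts", gene_id))
  for (t in transcripts)
    if (t$gene_id != gene_id)
      model_error(sprintf("transcript %s does not belong to gene %s",
                          t$id, gene_id))
  transcripts <- transcripts[order(vapply(transcripts, `[[`, "", "id"))]
  structure(list(gene_id = gene_id, gene_name = gene_name,
                 transcripts = transcripts),
            class = "gene_model")
}

#' Flatten gene models into a named list of transcripts (sorted by id)
#' @param gene_models list of [gene_model()] objects.
#' @export
all_transcripts <- function(gene_models) {
  ts <- unlist(lapply(gene_models, `[[`, "transcripts"), recursive = FALSE)
  ts <- ts[order(vapply(ts, `[[`, "", "id"))]
  stats::setNames(ts, vapply(ts, `[[`, "", "id"))
}

#' Read gene models from GFF3
#'
#' Recognises `gene`, `mRNA`/`transcript`, `exon` and `CDS` rows linked by
#' `ID`/`Parent` attributes.  Coordinates are converted from GFF3 1-based
#' inclusive to internal 0-based half-open.  The phase of the first CDS
#' segment in transcription order (the row with the smallest start on `+`,
#' the largest start on `-`) is trusted; downstream phases are recomputed
#' from cumulative CDS length, with a warning when the file disagrees.
#'
#' @param path path to a GFF3 file.
#' @return list of [gene_model()] objects, sorted by gene id.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) format_error(
                   sprintf("cannot parse GFF3 %s: %s", path, conditionMessage(e))))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
  } else rep(NA_character_, length(gr))
  nm <- if ("Name" %in% names(md)) as.character(md$Name) else rep(NA_character_, length(gr))
  phase <- if ("phase" %in% names(md)) as.integer(md$phase) else rep(NA_integer_, length(gr))

  start0 <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  end0 <- GenomicRanges::end(gr)
  ctg <- as.character(GenomicRanges::seqnames(gr))
  std <- as.character(GenomicRanges::strand(gr))

  gene_rows <- which(type == "gene")
  gene_names <- stats::setNames(ifelse(is.na(nm[gene_rows]), ids[gene_rows],
                                       nm[gene_rows]), ids[gene_rows])
  tx_rows <- which(type %in% c("mRNA", "transcript"))

  transcripts <- list()
  for (i in tx_rows) {
    tid <- ids[i]
    gid <- parents[i]
    ex <- which(type == "exon" & parents == tid)
    cd <- which(type == "CDS" & parents == tid)
    if (length(cd) == 0L) {
      warning(sprintf("transcript %s has no CDS; skipped", tid), call. = FALSE)
      next
    }
    strand_i <- std[i]
    # transcription-order-first CDS row carries the trusted phase
    first_cds <- if (strand_i == "+") cd[which.min(start0[cd])] else cd[which.max(start0[cd])]
    phase0 <- phase[first_cds]
    if (is.na(phase0)) phase0 <- 0L
    gname <- unname(gene_names[gid])
    if (length(gname) != 1L || is.na(gname)) gname <- gid
    tr <- transcript(
      id = tid, gene_id = gid,
      gene_name = gname,
      contig = ctg[i], strand = strand_i,
      exons = data.frame(start = start0[ex], end = end0[ex]),
      cds = data.frame(start = start0[cd], end = end0[cd]),
      phase0 = phase0)
    check_downstream_phases(tr, phase[cd][order(start0[cd])])
    transcripts[[tid]] <- tr
  }
  if (length(transcripts) == 0L)
    format_error(sprintf("no usable transcripts in %s", path))
  gids <- sort(unique(vapply(transcripts, `[[`, "", "gene_id")))
  lapply(gids, function(g) {
    ts <- Filter(function(t) t$gene_id == g, transcripts)
    gene_model(g, ts[[1L]]$gene_name, unname(ts))
  })
}

# recompute downstream CDS phases from cumulative length and compare with the
# file's phase column (ascending genomic order given in `file_phases`).
check_downstream_phases <- function(t, file_phases) {
  expected <- cds_segment_phases(t)         # ascending genomic order
  cmp <- !is.na(file_phases) & file_phases != expected
  # the transcription-order-first segment is trusted, not checked
  first_idx <- if (t$strand == "+") 1L else nrow(t$cds)
  cmp[first_idx] <- FALSE
  if (any(cmp))
    warning(sprintf(
      "transcript %s: GFF3 phase column disagrees with recomputed phase for %d CDS segment(s); recomputed values used",
      t$id, sum(cmp)), call. = FALSE)
  invisible(NULL)
}

# phases of all CDS segments in ascending genomic order, recomputed from
# cumulative length in transcription order
cds_segment_phases <- function(t) {
  lens <- t$cds$end - t$cds$start
  if (t$strand == "-") lens <- rev(lens)
  cum_before <- c(0L, cumsum(lens))[seq_along(lens)]
  ph <- (3L - ((cum_before - t$phase0) %% 3L)) %% 3L
  ph[1L] <- t$phase0
  if (t$strand == "-") ph <- rev(ph)
  as.integer(ph)
}

#' Write gene models as GFF3
#'
#' Emits `gene`, `mRNA`, `exon` and `CDS` rows with `ID`/`Parent`/`Name`
#' attributes, converting internal 0-based half-open coordinates back to
#' GFF3 1-based inclusive.  Output is deterministic byte-for-byte.
#'
#' @param gene_models list of [gene_model()] objects.
#' @param path output path.
#' @export
write_gene_models <- function(gene_models, path) {
  lines <- "##gff-version 3"
  row <- function(ctg, type, s0, e0, strand, phase, attrs)
    paste(ctg, "structmapr", type, s0 + 1L, e0, ".", strand,
          phase, attrs, sep = "\t")
  for (gm in gene_models) {
    ts <- gm$transcripts
    ctg <- ts[[1L]]$contig
    strand <- ts[[1L]]$strand
    gs <- min(vapply(ts, function(t) min(t$exons$start), 0L))
    ge <- max(vapply(ts, function(t) max(t$exons$end), 0L))
    lines <- c(lines, row(ctg, "gene", gs, ge, strand, ".",
                          sprintf("ID=%s;Name=%s", gm$gene_id, gm$gene_name)))
    for (t in ts) {
      lines <- c(lines, row(t$contig, "mRNA", min(t$exons$start),
                            max(t$exons$end), t$strand, ".",
                            sprintf("ID=%s;Parent=%s", t$id, t$gene_id)))
      for (i in seq_len(nrow(t$exons)))
        lines <- c(lines, row(t$contig, "exon", t$exons$start[i],
                              t$exons$end[i], t$strand, ".",
                              sprintf("ID=%s.exon%d;Parent=%s", t$id, i, t$id)))
      phases <- cds_segment_phases(t)
      for (i in seq_len(nrow(t$cds)))
        lines <- c(lines, row(t$contig, "CDS", t$cds$start[i],
                              t$cds$end[i], t$strand, phases[i],
                              sprintf("ID=%s.cds%d;Parent=%s", t$id, i, t$id)))
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Validate a transcript against the genome
#'
#' Returns findings (never raises):
#' * `"truncated"` — CDS length minus `phase0` is not divisible by 3;
#' * `"internal_stop"` — the translation contains a stop before the final
#'   codon;
#' * `"non_atg_start"` — the first complete codon is not `ATG`.
#'
#' An empty character vector means the transcript is clean.
#'
#' @param t a [transcript()].
#' @param genome list of [contig()] objects.
#' @return character vector of findings.
#' @export
validate_transcript <- function(t, genome) {
  findings <- character(0)
  cds_len <- sum(t$cds$end - t$cds$start)
  if ((cds_len - t$phase0) %% 3L != 0L) findings <- c(findings, "truncated")
  codons <- transcript_codons(t, genome)
  if (length(codons)) {
    aa <- translate_codon(codons)
    if (aa[1L] != "M" || codons[1L] != "ATG")
      findings <- c(findings, "non_atg_start")
    if (any(aa[-length(aa)] == "*")) findings <- c(findings, "internal_stop")
  }
  findings
}
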