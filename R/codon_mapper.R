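# Bidirectional arithmetic between genomic positions and protein positions
# of one transcript: codon extraction, strand handling, translation.
#
# Conventions: CDS bases are enumerated in transcription order (ascending
# genomic offsets on '+', descending on '-').  The first `phase0` bases are
# out-of-frame leader bases belonging to an upstream codon; they carry no
# residue.  The final complete codon is by GFF3 convention the stop codon
# and carries no residue either (checked against the genome when one is
# supplied; assumed otherwise).

#' Enumerate CDS bases of a transcript in transcription order
#'
#' @param t a [transcript()].
#' @return integer vector of 0-based genomic offsets, every CDS base exactly
#'   once, ascending for `+` and descending for `-` transcripts.  The first
#'   `t$phase0` entries are leader bases excluded from codon numbering.
#' @export
cds_base_order <- function(t) {
  offs <- unlist(lapply(seq_len(nrow(t$cds)), function(i)
    seq.int(t$cds$start[i], t$cds$end[i] - 1L)), use.names = FALSE)
  if (t$strand == "-") offs <- rev(offs)
  as.integer(offs)
}

# transcription-order codon strings of a transcript (leader bases dropped,
# trailing partial codon dropped)
transcript_codons <- function(t, genome) {
  ord <- cds_base_order(t)
  coding <- ord[seq_along(ord) > t$phase0]
  n_codon <- length(coding) %/% 3L
  if (n_codon == 0L) return(character(0))
  coding <- coding[seq_len(n_codon * 3L)]
  ctg <- get_contig(genome, t$contig)
  bases <- contig_bases(ctg, coding)
  if (t$strand == "-") bases <- complement_base(bases)
  m <- matrix(bases, nrow = 3L)
  paste0(m[1L, ], m[2L, ], m[3L, ])
}

#' Protein length of a transcript
#'
#' Number of residues encoded: complete codons after the leader bases, minus
#' the trailing stop.  When `genome` is supplied the last complete codon is
#' only excluded if it actually translates to a stop; without a genome the
#' GFF3 convention (CDS includes the stop codon) is assumed.
#'
#' @param t a [transcript()].
#' @param genome optional list of [contig()] objects.
#' @return integer residue count.
#' @export
protein_length <- function(t, genome = NULL) {
  cds_len <- sum(t$cds$end - t$cds$start)
  n_codon <- (cds_len - t$phase0) %/% 3L
  if (n_codon == 0L) return(0L)
  if (is.null(genome)) return(n_codon - 1L)
  codons <- transcript_codons(t, genome)
  if (translate_codon(codons[length(codons)]) == "*") n_codon - 1L else n_codon
}

#' Map a genomic offset to a protein position of one transcript
#'
#' @param t a [transcript()].
#' @param pos 0-based genomic offset.
#' @param genome optional genome (list of [contig()]); used only to decide
#'   whether the final codon is a stop (see [protein_length()]).
#' @return `NULL` when `pos` is intronic, intergenic, UTR, a leader base or
#'   in the stop codon; otherwise a list of class `protein_position` with
#'   `transcript_id`, `protein_pos` (1-based) and `codon_offset` (0--2, the
#'   transcription-order base of the codon that `pos` occupies).
#' @export
genomic_to_protein <- function(t, pos, genome = NULL) {
  ord <- cds_base_order(t)
  i <- match(as.integer(pos), ord)
  if (is.na(i)) return(NULL)
  k <- i - t$phase0                      # 1-based index among in-frame bases
  if (k < 1L) return(NULL)               # leader base
  plen <- protein_length(t, genome)
  protein_pos <- (k - 1L) %/% 3L + 1L
  if (protein_pos > plen) return(NULL)   # stop codon or trailing partial
  structure(list(transcript_id = t$id,
                 protein_pos = protein_pos,
                 codon_offset = (k - 1L) %% 3L),
            class = "protein_position")
}

#' Map a protein position to its codon's genomic locus
#'
#' @param t a [transcript()].
#' @param protein_pos 1-based residue index.
#' @param genome list of [contig()] objects.
#' @return a list of class `codon_locus` with `transcript_id`,
#'   `protein_pos`, `contig`, `strand`, `base_positions` (three 0-based
#'   genomic offsets in transcription order; non-contiguous when the codon
#'   spans an exon junction), `codon` (read in transcription order,
#'   reverse-complemented on `-`) and `amino_acid`.
#' @export
protein_to_codon <- function(t, protein_pos, genome) {
  plen <- protein_length(t, genome)
  if (!(is.numeric(protein_pos) && length(protein_pos) == 1L &&
        protein_pos >= 1 && protein_pos <= plen && protein_pos == floor(protein_pos)))
    range_error(sprintf(
      "protein_pos %s out of range for transcript %s (valid: 1..%d)",
      format(protein_pos), t$id, plen))
  protein_pos <- as.integer(protein_pos)
  ord <- cds_base_order(t)
  idx <- t$phase0 + 3L * (protein_pos - 1L) + 1:3
  base_positions <- ord[idx]
  ctg <- get_contig(genome, t$contig)
  bases <- contig_bases(ctg, base_positions)
  if (t$strand == "-") bases <- complement_base(bases)
  codon <- paste(bases, collapse = "")
  structure(list(transcript_id = t$id, protein_pos = protein_pos,
                 contig = t$contig, strand = t$strand,
                 base_positions = base_positions, codon = codon,
                 amino_acid = translate_codon(codon)),
            class = "codon_locus")
}

#' Translate a transcript's CDS
#'
#' Standard genetic code; codon 1 starts after the `phase0` leader bases;
#' a trailing stop is removed; an internal stop truncates the translation
#' with a warning; codons containing ambiguous bases yield `"X"`.
#'
#' @param t a [transcript()].
#' @param genome list of [contig()] objects.
#' @return protein sequence as a single string.
#' @export
translate_transcript <- function(t, genome) {
  codons <- transcript_codons(t, genome)
  if (length(codons) == 0L) return("")
  aa <- translate_codon(codons)
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    warning(sprintf("transcript %s: internal stop codon at residue %d; translation truncated",
                    t$id, stop_at[1L]), call. = FALSE)
    aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}
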