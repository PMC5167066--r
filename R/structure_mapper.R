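# Residue-level mapping between canonical sequence positions and structure
# residues (chain, author number, insertion code), plus composition of all
# stages into full genome <-> structure mapping.
#
# The mapping dialect is a TSV with header
#   pdb_id  chain_id  accession  canonical_pos  auth_num  ins_code  observed  res_name
# ("." = blank insertion code), one row per mapped residue, grouped by
# (pdb_id, chain_id, accession) and sorted by canonical_pos within a group.
# Unobserved residues (in the construct but without atomic coordinates) are
# kept with observed = 0 so coverage tracks can distinguish "in construct"
# from "resolved".

MAPPING_COLUMNS <- c("pdb_id", "chain_id", "accession", "canonical_pos",
                     "auth_num", "ins_code", "observed", "res_name")

#' Construct a residue mapping
#'
#' @param pdb_id 4-character structure identifier.
#' @param chain_id chain identifier.
#' @param accession canonical accession the mapping is expressed against.
#' @param pairs data.frame with columns `canonical_pos` (1-based, unique,
#'   ascending), `auth_num` (integer author residue number), `ins_code`
#'   (single character or `""`), `observed` (0/1), `res_name`.
#' @return object of class `residue_mapping`.
#' @export
residue_mapping <- function(pdb_id, chain_id, accession, pairs) {
  pairs <- as.data.frame(pairs)
  if (anyDuplicated(pairs$canonical_pos))
    format_error(sprintf("%s:%s/%s: duplicate canonical_pos",
                         pdb_id, chain_id, accession))
  key <- paste(pairs$auth_num, pairs$ins_code)
  if (anyDuplicated(key))
    format_error(sprintf("%s:%s/%s: duplicate structure residue key",
                         pdb_id, chain_id, accession))
  if (is.unsorted(pairs$canonical_pos))
    format_error(sprintf("%s:%s/%s: rows not monotonic in canonical_pos",
                         pdb_id, chain_id, accession))
  if (any(pairs$canonical_pos < 1L))
    format_error(sprintf("%s:%s/%s: canonical_pos must be >= 1",
                         pdb_id, chain_id, accession))
  pairs$canonical_pos <- as.integer(pairs$canonical_pos)
  pairs$auth_num <- as.integer(pairs$auth_num)
  pairs$observed <- as.integer(pairs$observed)
  rownames(pairs) <- NULL
  structure(list(pdb_id = pdb_id, chain_id = chain_id, accession = accession,
                 pairs = pairs),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  cat(sprintf("<residue_mapping %s:%s vs %s: %d residue(s), %d observed>\n",
              x$pdb_id, x$chain_id, x$accession, nrow(x$pairs),
              sum(x$pairs$observed)))
  invisible(x)
}

#' Read residue mappings from TSV
#'
#' See the module header for the dialect.  Rows are grouped by
#' `(pdb_id, chain_id, accession)`; within a group `canonical_pos` must be
#' unique and ascending and `auth_num` must be an integer.
#'
#' @param path TSV file path.
#' @return list of [residue_mapping()] objects sorted by pdb, chain,
#'   accession (empty list for a header-only file).
#' @export
read_residue_mapping <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", sep = "\t",
                          quote = "", check.names = FALSE)
  if (!identical(names(df), MAPPING_COLUMNS))
    format_error(sprintf("%s: expected header %s", path,
                         paste(MAPPING_COLUMNS, collapse = "\t")))
  if (nrow(df) == 0L) return(list())
  bad_auth <- which(!grepl("^-?[0-9]+$", df$auth_num))
  if (length(bad_auth))
    format_error(sprintf("%s: non-integer auth_num at data row %d", path,
                         bad_auth[1L]))
  bad_pos <- which(!grepl("^[0-9]+$", df$canonical_pos))
  if (length(bad_pos))
    format_error(sprintf("%s: non-integer canonical_pos at data row %d", path,
                         bad_pos[1L]))
  df$canonical_pos <- as.integer(df$canonical_pos)
  df$auth_num <- as.integer(df$auth_num)
  df$observed <- as.integer(df$observed)
  df$ins_code[df$ins_code == "."] <- ""
  grp <- paste(df$pdb_id, df$chain_id, df$accession, sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    rows <- df[grp == g, , drop = FALSE]
    dup <- which(duplicated(rows$canonical_pos))
    if (length(dup))
      format_error(sprintf(
        "%s: duplicate canonical_pos %d for %s:%s at data row %d", path,
        rows$canonical_pos[dup[1L]], rows$pdb_id[1L], rows$chain_id[1L],
        which(grp == g)[dup[1L]]))
    out[[length(out) + 1L]] <- residue_mapping(
      rows$pdb_id[1L], rows$chain_id[1L], rows$accession[1L],
      rows[, c("canonical_pos", "auth_num", "ins_code", "observed",
               "res_name")])
  }
  keys <- vapply(out, function(m) paste(m$pdb_id, m$chain_id, m$accession), "")
  out[order(keys)]
}

#' Write residue mappings as TSV (sorted by pdb_id, chain_id, canonical_pos)
#' @param maps list of [residue_mapping()] objects.
#' @param path output path.
#' @export
write_residue_mapping <- function(maps, path) {
  keys <- vapply(maps, function(m) paste(m$pdb_id, m$chain_id, m$accession), "")
  maps <- maps[order(keys)]
  lines <- paste(MAPPING_COLUMNS, collapse = "\t")
  for (m in maps) {
    p <- m$pairs[order(m$pairs$canonical_pos), , drop = FALSE]
    ins <- ifelse(p$ins_code == "", ".", p$ins_code)
    lines <- c(lines, paste(m$pdb_id, m$chain_id, m$accession,
                            p$canonical_pos, p$auth_num, ins, p$observed,
                            p$res_name, sep = "\t"))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

residue_ref <- function(m, row) {
  structure(list(pdb_id = m$pdb_id, chain_id = m$chain_id,
                 auth_num = row$auth_num, ins_code = row$ins_code,
                 observed = row$observed == 1L, res_name = row$res_name),
            class = "residue_ref")
}

#' Structure residues mapped to a canonical position
#'
#' @param maps list of [residue_mapping()] objects.
#' @param accession canonical accession.
#' @param canonical_pos 1-based canonical position.
#' @return list of `residue_ref` objects (possibly empty), ordered by
#'   pdb_id then chain_id; unobserved residues are included with
#'   `observed = FALSE`.
#' @export
canonical_to_structure <- function(maps, accession, canonical_pos) {
  if (canonical_pos < 1) range_error("canonical_pos must be >= 1")
  hits <- list()
  for (m in maps) {
    if (m$accession != accession) next
    i <- match(as.integer(canonical_pos), m$pairs$canonical_pos)
    if (!is.na(i)) hits[[length(hits) + 1L]] <- residue_ref(m, m$pairs[i, ])
  }
  ord <- order(vapply(hits, function(h) paste(h$pdb_id, h$chain_id), ""))
  hits[ord]
}

#' Canonical position of a structure residue
#'
#' @param maps list of [residue_mapping()] objects.
#' @param pdb_id,chain_id,auth_num,ins_code structure residue key
#'   (`ins_code` defaults to blank).
#' @return list with `accession` and `canonical_pos`, or `NULL` when the
#'   residue is not in any mapping.
#' @export
structure_to_canonical <- function(maps, pdb_id, chain_id, auth_num,
                                   ins_code = "") {
  for (m in maps) {
    if (m$pdb_id != pdb_id || m$chain_id != chain_id) next
    i <- which(m$pairs$auth_num == as.integer(auth_num) &
               m$pairs$ins_code == ins_code)
    if (length(i))
      return(list(accession = m$accession,
                  canonical_pos = m$pairs$canonical_pos[i[1L]]))
  }
  NULL
}

# --- stage composition ------------------------------------------------------

# Per-transcript isoform selection + alignment to the canonical sequence,
# cached in an environment keyed by transcript id.  Tries isoform sets in
# accession order and keeps the first with a match.
transcript_selection <- function(t, genome, isoform_sets,
                                 identity_threshold = 0.95, cache = NULL,
                                 alignments = NULL) {
  if (!is.null(cache) && !is.null(cache[[t$id]])) return(cache[[t$id]])
  translated <- suppressWarnings(translate_transcript(t, genome))
  res <- list(translated = translated, accession = NULL, isoform_id = NULL,
              match_kind = "none", aln = NULL)
  if (nzchar(translated)) {
    accs <- sort(vapply(isoform_sets, `[[`, "", "accession"))
    for (acc in accs) {
      iso <- get_isoform_set(isoform_sets, acc)
      sel <- select_isoform(translated, iso, identity_threshold)
      if (sel$match_kind == "none") next
      canon <- canonical_sequence(iso)
      iso_seq <- iso$isoforms$sequence[iso$isoforms$isoform_id == sel$isoform_id]
      aln <- alignments[[sel$isoform_id]] %||%
        (if (identical(iso_seq, canon)) identity_alignment(canon)
         else align_isoform_to_canonical(iso_seq, canon))
      aln$isoform_id <- sel$isoform_id
      aln$accession <- acc
      res <- list(translated = translated, accession = acc,
                  isoform_id = sel$isoform_id, match_kind = sel$match_kind,
                  aln = aln)
      break
    }
  }
  if (!is.null(cache)) cache[[t$id]] <- res
  res
}

#' Map a genomic position to structure residues through every transcript
#'
#' For each transcript whose CDS codons contain the position the pipeline is
#' composed stage by stage: [genomic_to_protein()] on the transcript, isoform
#' selection of the genomic translation ([select_isoform()]), projection onto
#' the canonical sequence ([isoform_to_canonical()]), then
#' [canonical_to_structure()].  A stage returning nothing truncates the
#' entry there with a stated reason; no stage raises.
#'
#' @param contig contig name of the query.
#' @param pos 0-based genomic offset.
#' @param gene_models list of [gene_model()] objects.
#' @param genome list of [contig()] objects.
#' @param isoform_sets list of [isoform_set()] objects.
#' @param maps list of [residue_mapping()] objects.
#' @param alignments optional named list of precomputed alignments keyed by
#'   isoform id.
#' @param identity_threshold passed to [select_isoform()].
#' @param cache optional environment for per-transcript selection caching.
#' @return object of class `genome_to_structure_result`: `query` plus one
#'   entry per transcript on the query contig (ordered by transcript id),
#'   each with `transcript_id`, `stage`, `reason` (`NULL` when complete),
#'   `protein_pos`, `codon_offset`, `isoform_id`, `accession`,
#'   `canonical_pos` and `hits` (list of `residue_ref`, ordered by pdb then
#'   chain).
#' @export
map_genome_to_structure <- function(contig, pos, gene_models, genome,
                                    isoform_sets, maps, alignments = NULL,
                                    identity_threshold = 0.95, cache = NULL) {
  ts <- all_transcripts(gene_models)
  entries <- list()
  for (t in ts) {
    if (t$contig != contig) next
    entry <- list(transcript_id = t$id, stage = NULL, reason = NULL,
                  protein_pos = NULL, codon_offset = NULL, isoform_id = NULL,
                  accession = NULL, canonical_pos = NULL, hits = list())
    pp <- genomic_to_protein(t, pos, genome)
    if (is.null(pp)) {
      entry$stage <- "genomic_to_protein"; entry$reason <- "non-coding"
      entries[[length(entries) + 1L]] <- entry
      next
    }
    entry$protein_pos <- pp$protein_pos
    entry$codon_offset <- pp$codon_offset
    sel <- transcript_selection(t, genome, isoform_sets, identity_threshold,
                                cache, alignments)
    if (is.null(sel$accession)) {
      entry$stage <- "select_isoform"; entry$reason <- "no matching isoform"
      entries[[length(entries) + 1L]] <- entry
      next
    }
    entry$isoform_id <- sel$isoform_id
    entry$accession <- sel$accession
    cpos <- if (pp$protein_pos > sel$aln$iso_len) NULL
            else isoform_to_canonical(sel$aln, pp$protein_pos)
    if (is.null(cpos)) {
      entry$stage <- "isoform_to_canonical"; entry$reason <- "not in canonical"
      entries[[length(entries) + 1L]] <- entry
      next
    }
    entry$canonical_pos <- cpos
    entry$hits <- canonical_to_structure(maps, sel$accession, cpos)
    entry$stage <- "complete"
    if (length(entry$hits) == 0L) entry$reason <- "no structure"
    entries[[length(entries) + 1L]] <- entry
  }
  structure(list(query = list(contig = contig, pos = as.integer(pos)),
                 entries = entries),
            class = "genome_to_structure_result")
}

#' Map a structure residue back to genomic codons
#'
#' [structure_to_canonical()], then for every transcript whose selected
#' isoform belongs to the mapped accession: [canonical_to_isoform()] and
#' [protein_to_codon()].  Transcripts in which the canonical residue is
#' deleted are reported with reason `"not in isoform"`.
#'
#' @inheritParams map_genome_to_structure
#' @param pdb_id,chain_id,auth_num,ins_code structure residue key.
#' @return object of class `structure_to_genome_result` with `query`,
#'   `accession`, `canonical_pos` (both `NULL` when the residue is
#'   unmapped) and `entries` (per transcript: `transcript_id`, `reason`
#'   or a `codon_locus` under `codon`).
#' @export
map_structure_to_genome <- function(pdb_id, chain_id, auth_num, ins_code = "",
                                    gene_models, genome, isoform_sets, maps,
                                    alignments = NULL,
                                    identity_threshold = 0.95, cache = NULL) {
  query <- list(pdb_id = pdb_id, chain_id = chain_id,
                auth_num = as.integer(auth_num), ins_code = ins_code)
  sc <- structure_to_canonical(maps, pdb_id, chain_id, auth_num, ins_code)
  if (is.null(sc))
    return(structure(list(query = query, accession = NULL,
                          canonical_pos = NULL, entries = list()),
                     class = "structure_to_genome_result"))
  entries <- list()
  for (t in all_transcripts(gene_models)) {
    sel <- transcript_selection(t, genome, isoform_sets, identity_threshold,
                                cache, alignments)
    if (is.null(sel$accession) || sel$accession != sc$accession) next
    ipos <- if (sc$canonical_pos > sel$aln$canon_len) NULL
            else canonical_to_isoform(sel$aln, sc$canonical_pos)
    if (is.null(ipos)) {
      entries[[length(entries) + 1L]] <- list(transcript_id = t$id,
                                              reason = "not in isoform",
                                              codon = NULL)
      next
    }
    if (ipos > protein_length(t, genome)) {
      entries[[length(entries) + 1L]] <- list(transcript_id = t$id,
                                              reason = "not in translation",
                                              codon = NULL)
      next
    }
    cl <- protein_to_codon(t, ipos, genome)
    entries[[length(entries) + 1L]] <- list(transcript_id = t$id,
                                            reason = NULL, codon = cl)
  }
  structure(list(query = query, accession = sc$accession,
                 canonical_pos = sc$canonical_pos, entries = entries),
            class = "structure_to_genome_result")
}
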