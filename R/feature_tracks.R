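# Provenance-tagged annotation tracks on the canonical sequence, JSON
# serialization, sequence-mismatch detection, and BED export of structure
# coverage onto the genome.
#
# A Feature is a 1-based inclusive range [start, end] on the canonical
# sequence with a controlled-vocabulary type, a label and an open attribute
# set.  A FeatureTrack carries provenance, which drives the default colour
# hint: UniProt-derived data is green, PDB-derived data blue.

FEATURE_TYPES <- c("exon", "variant", "pdb_coverage", "mismatch",
                   "modification", "domain", "user")
PROVENANCES <- c(UniProt = "green", PDB = "blue", computed = "gray",
                 user = "orange")

#' Construct a feature
#'
#' @param start,end 1-based inclusive positions on the canonical sequence.
#' @param type one of `r paste(FEATURE_TYPES, collapse = ", ")`.
#' @param label display label.
#' @param attributes named list of open key/value annotations.
#' @return object of class `feature`.
#' @export
feature <- function(start, end, type, label = "", attributes = list()) {
  if (!(type %in% FEATURE_TYPES))
    param_error(sprintf("unknown feature type '%s'", type))
  if (!(start >= 1 && start <= end))
    param_error(sprintf("invalid feature range [%s,%s]", start, end))
  structure(list(start = as.integer(start), end = as.integer(end),
                 type = type, label = label, attributes = attributes),
            class = "feature")
}

#' Construct a feature track
#'
#' @param name track name.
#' @param provenance one of `UniProt`, `PDB`, `computed`, `user`; drives the
#'   default `color_hint` (UniProt = green, PDB = blue).
#' @param features list of [feature()] objects (sorted by start).
#' @param color_hint optional colour override.
#' @return object of class `feature_track`.
#' @export
feature_track <- function(name, provenance, features = list(),
                          color_hint = NULL) {
  if (!(provenance %in% names(PROVENANCES)))
    param_error(sprintf("unknown provenance '%s'", provenance))
  starts <- vapply(features, `[[`, 1L, "start")
  features <- features[order(starts)]
  structure(list(name = name, provenance = provenance,
                 color_hint = color_hint %||% unname(PROVENANCES[provenance]),
                 features = features),
            class = "feature_track")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track '%s' (%s/%s): %d feature(s)>\n",
              x$name, x$provenance, x$color_hint, length(x$features)))
  invisible(x)
}

#' Build the exon-structure track on the canonical sequence
#'
#' One feature per coding exon, spanning the canonical positions of the
#' residues whose codons *start* in that exon (junction codons are assigned
#' to the exon containing codon base 1 in transcription order).  Exons whose
#' residues are absent from the canonical sequence (isoform-specific) yield
#' no feature.  Features are labelled `exon1..exonN` by the transcription-
#' order index of the coding exon within this transcript.
#'
#' @param t a [transcript()].
#' @param genome list of [contig()] objects.
#' @param iso the [isoform_set()] the transcript translation belongs to.
#' @param aln optional precomputed alignment of the selected isoform to the
#'   canonical sequence; computed when `NULL`.
#' @param identity_threshold passed to [select_isoform()].
#' @return a `feature_track` with provenance `computed`.
#' @export
build_exon_track <- function(t, genome, iso, aln = NULL,
                             identity_threshold = 0.95) {
  sel <- transcript_selection(t, genome, list(iso), identity_threshold)
  if (is.null(sel$accession))
    return(feature_track(paste0("exons ", t$id), "computed"))
  if (!is.null(aln)) sel$aln <- aln
  plen <- protein_length(t, genome)
  ord <- cds_base_order(t)
  # exon index (transcription order) of each codon's first base
  ex <- t$exons
  exon_of <- function(off) which(ex$start <= off & off < ex$end)[1L]
  n_ex <- nrow(ex)
  tx_index <- function(i) if (t$strand == "+") i else n_ex - i + 1L
  codon_exon <- vapply(seq_len(plen), function(r) {
    first_base <- ord[t$phase0 + 3L * (r - 1L) + 1L]
    tx_index(exon_of(first_base))
  }, 0L)
  feats <- list()
  coding_exons <- sort(unique(codon_exon))
  for (k in seq_along(coding_exons)) {
    residues <- which(codon_exon == coding_exons[k])
    cpos <- unlist(lapply(residues, function(r)
      if (r > sel$aln$iso_len) NULL else isoform_to_canonical(sel$aln, r)))
    if (length(cpos) == 0L) next
    feats[[length(feats) + 1L]] <- feature(
      min(cpos), max(cpos), "exon", sprintf("exon%d", k),
      attributes = list(transcript_id = t$id,
                        exon_index = coding_exons[k]))
  }
  feature_track(paste0("exons ", t$id), "computed", feats)
}

#' Read a variant TSV (columns contig, pos, ref, alt; 1-based positions)
#' @param path TSV path.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", sep = "\t",
                          quote = "")
  if (!all(c("contig", "pos", "ref", "alt") %in% names(df)))
    format_error(sprintf("%s: expected columns contig, pos, ref, alt", path))
  if (nrow(df) && any(!grepl("^[0-9]+$", df$pos)))
    format_error(sprintf("%s: non-integer variant position", path))
  df$pos <- as.integer(df$pos)
  df[, c("contig", "pos", "ref", "alt")]
}

#' Parse variant strings of the form `contig:pos:ref:alt` (1-based)
#' @param x character vector.
#' @return data.frame with columns `contig`, `pos`, `ref`, `alt`.
#' @export
parse_variant_strings <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  bad <- vapply(parts, function(p)
    length(p) != 4L || !grepl("^[0-9]+$", p[2L]) ||
      !all(toupper(c(p[3L], p[4L])) %in% DNA_ALPHABET), TRUE)
  if (any(bad))
    format_error(sprintf("malformed variant string(s): %s",
                         paste(x[bad], collapse = ", ")))
  data.frame(contig = vapply(parts, `[[`, "", 1L),
             pos = as.integer(vapply(parts, `[[`, "", 2L)),
             ref = toupper(vapply(parts, `[[`, "", 3L)),
             alt = toupper(vapply(parts, `[[`, "", 4L)))
}

#' Build the variation track for one transcript
#'
#' Each SNV falling in a codon of the transcript becomes a length-1 feature
#' at its canonical position, labelled with the predicted amino-acid change
#' (e.g. `"E3Q"`, reference residue, canonical position, alternate residue)
#' obtained by substituting the alternate base into the codon and
#' re-translating.  Variants whose reference base does not match the genome,
#' and non-coding variants, are skipped with a warning.
#'
#' @param variants data.frame with columns `contig`, `pos` (1-based),
#'   `ref`, `alt`.
#' @inheritParams build_exon_track
#' @return a `feature_track` with provenance `computed`; feature attributes
#'   carry the consequence (`missense`, `synonymous`, `stop_gained`) and the
#'   genomic change.
#' @export
build_variant_track <- function(variants, t, genome, iso, aln = NULL,
                                identity_threshold = 0.95) {
  sel <- transcript_selection(t, genome, list(iso), identity_threshold)
  track_name <- paste0("variants ", t$id)
  if (is.null(sel$accession)) return(feature_track(track_name, "computed"))
  if (!is.null(aln)) sel$aln <- aln
  ctg <- get_contig(genome, t$contig)
  feats <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (v$contig != t$contig) next
    off <- v$pos - 1L
    if (off < 0L || off >= ctg$length) {
      warning(sprintf("variant %s:%d out of contig range; skipped",
                      v$contig, v$pos), call. = FALSE)
      next
    }
    if (contig_bases(ctg, off) != toupper(v$ref)) {
      warning(sprintf("variant %s:%d ref '%s' does not match genome; skipped",
                      v$contig, v$pos, v$ref), call. = FALSE)
      next
    }
    pp <- genomic_to_protein(t, off, genome)
    if (is.null(pp)) {
      warning(sprintf("variant %s:%d is non-coding for %s; skipped",
                      v$contig, v$pos, t$id), call. = FALSE)
      next
    }
    cl <- protein_to_codon(t, pp$protein_pos, genome)
    alt_base <- toupper(v$alt)
    if (t$strand == "-") alt_base <- complement_base(alt_base)
    alt_codon <- cl$codon
    substr(alt_codon, pp$codon_offset + 1L, pp$codon_offset + 1L) <- alt_base
    alt_aa <- translate_codon(alt_codon)
    cpos <- if (pp$protein_pos > sel$aln$iso_len) NULL
            else isoform_to_canonical(sel$aln, pp$protein_pos)
    if (is.null(cpos)) {
      warning(sprintf("variant %s:%d has no canonical position; skipped",
                      v$contig, v$pos), call. = FALSE)
      next
    }
    consequence <- if (alt_aa == "*") "stop_gained"
                   else if (alt_aa == cl$amino_acid) "synonymous"
                   else "missense"
    feats[[length(feats) + 1L]] <- feature(
      cpos, cpos, "variant",
      label = paste0(cl$amino_acid, cpos, alt_aa),
      attributes = list(consequence = consequence,
                        genomic = sprintf("%s:%d:%s>%s", v$contig, v$pos,
                                          toupper(v$ref), toupper(v$alt)),
                        transcript_id = t$id))
  }
  feature_track(track_name, "computed", feats)
}

#' Build the structure-coverage track for an accession
#'
#' Per `(pdb_id, chain_id)`: maximal runs of consecutive canonical positions
#' present in the mapping become features; each feature records the fraction
#' of observed residues within the run.
#'
#' @param maps list of [residue_mapping()] objects.
#' @param accession canonical accession.
#' @return a `feature_track` with provenance `PDB`.
#' @export
build_coverage_track <- function(maps, accession) {
  feats <- list()
  for (m in maps) {
    if (m$accession != accession) next
    pos <- sort(m$pairs$canonical_pos)
    runs <- split(pos, cumsum(c(1L, diff(pos) != 1L)))
    for (r in runs) {
      rows <- m$pairs[m$pairs$canonical_pos %in% r, ]
      feats[[length(feats) + 1L]] <- feature(
        min(r), max(r), "pdb_coverage",
        label = paste0(m$pdb_id, ":", m$chain_id),
        attributes = list(pdb_id = m$pdb_id, chain_id = m$chain_id,
                          observed_fraction = sum(rows$observed) / nrow(rows)))
    }
  }
  feature_track(paste0("structure coverage ", accession), "PDB", feats)
}

#' Detect sequence mismatches between a structure and the canonical sequence
#'
#' Positions where the mapped structure residue (`res_name`) differs from
#' the canonical sequence are grouped into maximal runs of consecutive
#' mismatching canonical positions.  A run touching either end of the mapped
#' range is classified `terminal_extension` (expression-tag heuristic); any
#' other run is a `substitution` (engineered mutation, conflict, ...).
#'
#' @param map a [residue_mapping()].
#' @param canon_seq canonical protein sequence.
#' @return a `feature_track` with provenance `PDB`.
#' @export
detect_mismatches <- function(map, canon_seq) {
  p <- map$pairs[order(map$pairs$canonical_pos), ]
  canon_len <- nchar(canon_seq)
  in_range <- p$canonical_pos <= canon_len
  p <- p[in_range, , drop = FALSE]
  track_name <- sprintf("mismatches %s:%s", map$pdb_id, map$chain_id)
  if (nrow(p) == 0L) return(feature_track(track_name, "PDB"))
  expected <- substring(canon_seq, p$canonical_pos, p$canonical_pos)
  got <- res_name_to_one(p$res_name)
  mism <- p$canonical_pos[got != expected]
  if (length(mism) == 0L) return(feature_track(track_name, "PDB"))
  lo <- min(p$canonical_pos); hi <- max(p$canonical_pos)
  runs <- split(mism, cumsum(c(1L, diff(mism) != 1L)))
  feats <- lapply(runs, function(r) {
    cls <- if (min(r) == lo || max(r) == hi) "terminal_extension"
           else "substitution"
    feature(min(r), max(r), "mismatch",
            label = sprintf("%s:%s %s", map$pdb_id, map$chain_id, cls),
            attributes = list(class = cls, pdb_id = map$pdb_id,
                              chain_id = map$chain_id))
  })
  feature_track(track_name, "PDB", unname(feats))
}

#' Read user protein-space features (TSV: accession, start, end, type, label)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_user_features <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  df <- utils::read.delim(path, colClasses = "character", sep = "\t",
                          quote = "")
  need <- c("accession", "start", "end", "type", "label")
  if (!all(need %in% names(df)))
    format_error(sprintf("%s: expected columns %s", path,
                         paste(need, collapse = ", ")))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df[, need]
}

#' Build a user track from a user-feature table
#' @param user_features data.frame from [read_user_features()].
#' @param accession accession to select.
#' @return a `feature_track` with provenance `user`.
#' @export
build_user_track <- function(user_features, accession) {
  sub <- user_features[user_features$accession == accession, , drop = FALSE]
  feats <- lapply(seq_len(nrow(sub)), function(i)
    feature(sub$start[i], sub$end[i],
            if (sub$type[i] %in% FEATURE_TYPES) sub$type[i] else "user",
            sub$label[i], attributes = list(source_type = sub$type[i])))
  feature_track(paste0("user ", accession), "user", feats)
}

# --- JSON serialization -----------------------------------------------------

feature_to_list <- function(f) {
  attrs <- f$attributes
  attrs <- attrs[order(names(attrs))]
  list(attributes = attrs, end = f$end, label = f$label, start = f$start,
       type = f$type)
}

track_to_list <- function(tr) {
  list(color_hint = tr$color_hint,
       features = lapply(tr$features, feature_to_list),
       name = tr$name, provenance = tr$provenance)
}

#' Serialize feature tracks to the track JSON document
#'
#' Document schema (shipped at
#' `system.file("extdata/track-schema.json", package = "structmapr")`):
#' `{accession, length, tracks:[{name, provenance, color_hint,
#' features:[{start, end, type, label, attributes}]}]}`.  All object keys
#' are emitted in sorted order and the byte output is deterministic for a
#' fixed input.
#'
#' @param tracks list of `feature_track` objects.
#' @param accession canonical accession.
#' @param canon_len canonical sequence length; every feature must lie in
#'   `[1, canon_len]`.
#' @return single JSON string (no trailing newline).
#' @export
tracks_to_json <- function(tracks, accession, canon_len) {
  for (tr in tracks)
    for (f in tr$features)
      if (f$end > canon_len)
        param_error(sprintf(
          "feature [%d,%d] in track '%s' exceeds canonical length %d",
          f$start, f$end, tr$name, canon_len))
  doc <- list(accession = accession, length = as.integer(canon_len),
              tracks = lapply(tracks, track_to_list))
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                null = "null"))
}

#' Parse a track JSON document (inverse of [tracks_to_json()])
#' @param json JSON string.
#' @return list with `accession`, `length` and `tracks` (list of
#'   `feature_track`).
#' @export
parse_tracks_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  tracks <- lapply(doc$tracks, function(tr) {
    feats <- lapply(tr$features, function(f)
      feature(f$start, f$end, f$type, f$label,
              attributes = lapply(f$attributes, identity)))
    feature_track(tr$name, tr$provenance, feats, color_hint = tr$color_hint)
  })
  list(accession = doc$accession, length = as.integer(doc$length),
       tracks = tracks)
}

#' Validate a track JSON document against the shipped schema
#'
#' A small structural validator driven by the JSON-Schema document shipped
#' under `extdata/track-schema.json` (checks types, required keys, enums and
#' array item schemas; not a complete JSON-Schema implementation).
#'
#' @param json JSON string.
#' @param schema_path path to the schema (defaults to the shipped one).
#' @return `TRUE` invisibly; raises a format error on violation.
#' @export
validate_track_json <- function(json,
                                schema_path = system.file(
                                  "extdata/track-schema.json",
                                  package = "structmapr")) {
  schema <- jsonlite::fromJSON(schema_path, simplifyVector = FALSE)
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  check_node(doc, schema, "$")
  invisible(TRUE)
}

check_node <- function(node, schema, where) {
  ty <- schema$type
  if (!is.null(ty)) {
    ok <- switch(ty,
      object = is.list(node) && (length(node) == 0L || !is.null(names(node))),
      array = is.list(node) && is.null(names(node)),
      string = is.character(node) && length(node) == 1L,
      integer = is.numeric(node) && length(node) == 1L &&
        node == floor(node),
      number = is.numeric(node) && length(node) == 1L,
      boolean = is.logical(node) && length(node) == 1L,
      TRUE)
    if (!ok) format_error(sprintf("%s: expected %s", where, ty))
  }
  if (!is.null(schema$enum) &&
      !(node %in% unlist(schema$enum)))
    format_error(sprintf("%s: value '%s' not in enum", where, node))
  if (!is.null(schema$required))
    for (k in unlist(schema$required))
      if (!(k %in% names(node)))
        format_error(sprintf("%s: missing required key '%s'", where, k))
  if (!is.null(schema$properties))
    for (k in names(schema$properties))
      if (k %in% names(node))
        check_node(node[[k]], schema$properties[[k]],
                   paste0(where, ".", k))
  if (!is.null(schema$items))
    for (i in seq_along(node))
      check_node(node[[i]], schema$items, sprintf("%s[%d]", where, i))
  invisible(TRUE)
}

# --- BED export -------------------------------------------------------------

#' Export structure coverage of a transcript as BED intervals
#'
#' Genomic bases covered by codons of structure-mapped residues, merged
#' where adjacent, as BED6 records (0-based half-open).  The record name is
#' `pdb_id:chain_id`; minus-strand transcripts produce ascending-coordinate
#' records with strand `"-"`.
#'
#' @param t a [transcript()].
#' @param map a [residue_mapping()] against the canonical accession.
#' @param genome list of [contig()] objects.
#' @param iso the [isoform_set()] of the mapped accession.
#' @param aln optional precomputed isoform-to-canonical alignment.
#' @param identity_threshold passed to [select_isoform()].
#' @return data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, sorted by `chrom` then `start` (zero rows when
#'   nothing maps).
#' @export
export_coverage_bed <- function(t, map, genome, iso, aln = NULL,
                                identity_threshold = 0.95) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = integer(0), strand = character(0))
  sel <- transcript_selection(t, genome, list(iso), identity_threshold)
  if (is.null(sel$accession) || sel$accession != map$accession) return(empty)
  if (!is.null(aln)) sel$aln <- aln
  plen <- protein_length(t, genome)
  offs <- integer(0)
  for (cpos in map$pairs$canonical_pos) {
    ipos <- if (cpos > sel$aln$canon_len) NULL
            else canonical_to_isoform(sel$aln, cpos)
    if (is.null(ipos) || ipos > plen) next
    offs <- c(offs, protein_to_codon(t, ipos, genome)$base_positions)
  }
  if (length(offs) == 0L) return(empty)
  offs <- sort(unique(offs))
  brk <- cumsum(c(1L, diff(offs) != 1L))
  starts <- tapply(offs, brk, min)
  ends <- tapply(offs, brk, max) + 1L
  df <- data.frame(chrom = t$contig, start = as.integer(starts),
                   end = as.integer(ends),
                   name = paste0(map$pdb_id, ":", map$chain_id),
                   score = 0L, strand = t$strand)
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write BED records (tab-separated, no header, deterministic bytes)
#' @param bed data.frame from [export_coverage_bed()].
#' @param path output path.
#' @export
write_bed <- function(bed, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(bed))
    writeLines(paste(bed$chrom, bed$start, bed$end, bed$name, bed$score,
                     bed$strand, sep = "\t"), con, sep = "\n")
  invisible(path)
}
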