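# Splice-isoform handling: pick the isoform matching a genomic translation,
# align any isoform to the canonical sequence, and project positions through
# that alignment.
#
# Scoring (match +2, mismatch -1, gap open -10, gap extend -0.5; a gap of
# length k costs open + k*extend) is deliberately simple: isoforms of one
# accession are near-identical segment rearrangements, so a substitution
# matrix adds nothing.  Traceback ties are broken diagonal > gap-in-canonical
# > gap-in-isoform so outputs are bit-reproducible.

#' Construct an isoform set
#'
#' @param accession accession identifier.
#' @param isoforms data.frame with columns `isoform_id`, `sequence`,
#'   `is_canonical` (exactly one `TRUE`).
#' @return object of class `isoform_set`.
#' @export
isoform_set <- function(accession, isoforms) {
  if (sum(isoforms$is_canonical) != 1L)
    format_error(sprintf("accession %s: exactly one canonical isoform required",
                         accession))
  if (anyDuplicated(isoforms$isoform_id))
    format_error(sprintf("accession %s: duplicate isoform ids", accession))
  if (any(!nzchar(isoforms$sequence)))
    format_error(sprintf("accession %s: empty isoform sequence", accession))
  bad <- setdiff(unique(unlist(strsplit(isoforms$sequence, ""))), AA_ALPHABET)
  if (length(bad))
    format_error(sprintf("accession %s: illegal residue character(s): %s",
                         accession, paste(bad, collapse = ", ")))
  rownames(isoforms) <- NULL
  structure(list(accession = accession, isoforms = isoforms),
            class = "isoform_set")
}

#' Canonical sequence of an isoform set
#' @param iso an [isoform_set()].
#' @export
canonical_sequence <- function(iso) {
  iso$isoforms$sequence[iso$isoforms$is_canonical][1L]
}

#' Read protein isoform FASTA
#'
#' Header dialect: `>ACCESSION-N |canonical` marks the canonical isoform of
#' `ACCESSION`; `>ACCESSION-N` marks an alternative isoform.
#'
#' @param path FASTA file path.
#' @return list of [isoform_set()] objects, sorted by accession.
#' @export
read_isoforms <- function(path) {
  if (!file.exists(path)) format_error(sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) format_error(
                    sprintf("cannot parse FASTA %s: %s", path, conditionMessage(e))))
  if (length(set) == 0L) format_error(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  canonical <- grepl("\\|canonical", headers)
  accession <- sub("-[0-9]+$", "", ids)
  df <- data.frame(isoform_id = ids, accession = accession,
                   sequence = toupper(as.character(set)),
                   is_canonical = canonical, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  lapply(sort(unique(df$accession)), function(acc) {
    sub <- df[df$accession == acc, c("isoform_id", "sequence", "is_canonical")]
    isoform_set(acc, sub)
  })
}

#' Write protein isoform FASTA (see [read_isoforms()] for the header dialect)
#' @param isoform_sets list of [isoform_set()] objects.
#' @param path output path.
#' @export
write_isoforms <- function(isoform_sets, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (iso in isoform_sets) {
    for (i in seq_len(nrow(iso$isoforms))) {
      hdr <- paste0(">", iso$isoforms$isoform_id[i],
                    if (iso$isoforms$is_canonical[i]) " |canonical" else "")
      writeLines(hdr, con, sep = "\n")
      s <- iso$isoforms$sequence[i]
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con,
                 sep = "\n")
    }
  }
  invisible(path)
}

#' Find an isoform set by accession
#' @keywords internal
get_isoform_set <- function(isoform_sets, accession) {
  for (iso in isoform_sets) if (iso$accession == accession) return(iso)
  lookup_error(sprintf("unknown accession '%s'", accession))
}

#' Globally align an isoform to the canonical sequence
#'
#' Needleman--Wunsch/Gotoh global alignment with identity scoring and affine
#' gaps.  Traceback ties are broken deterministically: diagonal first, then
#' gap-in-canonical (isoform residue aligned to nothing), then
#' gap-in-isoform.  The result is expressed as ungapped aligned blocks
#' (mismatches stay inside blocks).
#'
#' @param iso_seq,canon_seq protein strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring parameters; a gap of
#'   length k costs `gap_open + k * gap_extend`.
#' @return object of class `isoform_alignment` with `blocks` (data.frame
#'   `iso_start`, `canon_start`, `length`, 1-based), `score`, `identity`
#'   (matches / alignment columns), `iso_len`, `canon_len`.
#' @export
align_isoform_to_canonical <- function(iso_seq, canon_seq, match = 2,
                                       mismatch = -1, gap_open = -10,
                                       gap_extend = -0.5) {
  if (!nzchar(iso_seq) || !nzchar(canon_seq))
    param_error("sequences must be non-empty")
  a <- chars(iso_seq); b <- chars(canon_seq)
  n <- length(a); m <- length(b)
  NEG <- -1e18
  # state matrices, (n+1) x (m+1); row i = isoform prefix, col j = canonical
  # prefix.  M ends in diagonal; X ends with gap in canonical (consumes
  # isoform, vertical); Y ends with gap in isoform (consumes canonical).
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1L, 1L] <- 0
  if (n >= 1L) X[2:(n + 1L), 1L] <- gap_open + gap_extend * (1:n)
  if (m >= 1L) Y[1L, 2:(m + 1L)] <- gap_open + gap_extend * (1:m)
  for (i in 2:(n + 1L)) {
    sub <- ifelse(a[i - 1L] == b, match, mismatch)  # vector over j-1
    for (j in 2:(m + 1L)) {
      M[i, j] <- sub[j - 1L] + max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                                   Y[i - 1L, j - 1L])
      X[i, j] <- max(M[i - 1L, j] + gap_open + gap_extend,
                     X[i - 1L, j] + gap_extend,
                     Y[i - 1L, j] + gap_open + gap_extend)
      Y[i, j] <- max(M[i, j - 1L] + gap_open + gap_extend,
                     Y[i, j - 1L] + gap_extend,
                     X[i, j - 1L] + gap_open + gap_extend)
    }
  }
  eps <- 1e-9
  pick_state <- function(i, j) {
    # tie order: M (diagonal) > X (gap-in-canonical) > Y (gap-in-isoform)
    best <- max(M[i, j], X[i, j], Y[i, j])
    if (M[i, j] >= best - eps) "M" else if (X[i, j] >= best - eps) "X" else "Y"
  }
  score <- max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
  # traceback
  i <- n + 1L; j <- m + 1L
  state <- pick_state(i, j)
  moves <- character(n + m)
  k <- 0L
  while (i > 1L || j > 1L) {
    k <- k + 1L
    if (state == "M") {
      moves[k] <- "D"
      prev <- c(M = M[i - 1L, j - 1L], X = X[i - 1L, j - 1L],
                Y = Y[i - 1L, j - 1L])
      i <- i - 1L; j <- j - 1L
      need <- M[i + 1L, j + 1L] - ifelse(a[i] == b[j], match, mismatch)
      state <- names(prev)[which(prev >= need - eps)][1L]
      if (i == 1L && j == 1L) break
    } else if (state == "X") {
      moves[k] <- "I"                      # consume isoform
      from_open <- X[i, j] - gap_open - gap_extend
      from_ext <- X[i, j] - gap_extend
      i <- i - 1L
      state <- if (M[i, j] >= from_open - eps) "M"
               else if (X[i, j] >= from_ext - eps) "X" else "Y"
      if (i == 1L && j == 1L) break
    } else {
      moves[k] <- "C"                      # consume canonical
      from_open <- Y[i, j] - gap_open - gap_extend
      from_ext <- Y[i, j] - gap_extend
      j <- j - 1L
      state <- if (M[i, j] >= from_open - eps) "M"
               else if (Y[i, j] >= from_ext - eps) "Y" else "X"
      if (i == 1L && j == 1L) break
    }
  }
  moves <- rev(moves[seq_len(k)])
  # walk moves to collect ungapped blocks and identity
  blocks <- list()
  ip <- 0L; jp <- 0L
  bi <- NA_integer_; bj <- NA_integer_; blen <- 0L
  matches <- 0L
  flush <- function() {
    if (blen > 0L)
      blocks[[length(blocks) + 1L]] <<- c(iso_start = bi, canon_start = bj,
                                          length = blen)
    blen <<- 0L
  }
  for (mv in moves) {
    if (mv == "D") {
      ip <- ip + 1L; jp <- jp + 1L
      if (blen == 0L) { bi <- ip; bj <- jp }
      blen <- blen + 1L
      if (a[ip] == b[jp]) matches <- matches + 1L
    } else if (mv == "I") { flush(); ip <- ip + 1L }
    else { flush(); jp <- jp + 1L }
  }
  flush()
  blocks <- if (length(blocks)) as.data.frame(do.call(rbind, blocks))
            else data.frame(iso_start = integer(0), canon_start = integer(0),
                            length = integer(0))
  structure(list(isoform_id = NA_character_, accession = NA_character_,
                 blocks = blocks, score = score,
                 identity = matches / length(moves),
                 iso_len = n, canon_len = m),
            class = "isoform_alignment")
}

#' @export
print.isoform_alignment <- function(x, ...) {
  cat(sprintf("<isoform_alignment %s -> %s: %d block(s), score %.1f, identity %.3f>\n",
              x$isoform_id, x$accession, nrow(x$blocks), x$score, x$identity))
  invisible(x)
}

# identity alignment of a sequence to itself (cheap common case)
identity_alignment <- function(seq, match = 2) {
  n <- nchar(seq)
  structure(list(isoform_id = NA_character_, accession = NA_character_,
                 blocks = data.frame(iso_start = 1L, canon_start = 1L,
                                     length = n),
                 score = match * n, identity = 1, iso_len = n, canon_len = n),
            class = "isoform_alignment")
}

#' Select the isoform matching a genomic translation
#'
#' Exact sequence equality wins (ties: canonical isoform first, then the
#' lexicographically smallest id).  Otherwise the isoform with the highest
#' global-alignment identity is accepted when its identity reaches
#' `identity_threshold`; below the threshold nothing is selected.
#'
#' @param translated protein string (a transcript translation).
#' @param iso an [isoform_set()].
#' @param identity_threshold minimum identity for a non-exact match
#'   (default 0.95).
#' @return list with `isoform_id` (`""` when no match), `match_kind`
#'   (`"exact"`, `"best_alignment"` or `"none"`) and `identity`.
#' @export
select_isoform <- function(translated, iso, identity_threshold = 0.95) {
  if (!nzchar(translated)) param_error("translated sequence must be non-empty")
  df <- iso$isoforms
  # deterministic candidate order: canonical first, then id
  ord <- order(!df$is_canonical, df$isoform_id)
  df <- df[ord, , drop = FALSE]
  hit <- which(df$sequence == translated)
  if (length(hit))
    return(list(isoform_id = df$isoform_id[hit[1L]], match_kind = "exact",
                identity = 1))
  idents <- vapply(df$sequence, function(s)
    align_isoform_to_canonical(translated, s)$identity, 0, USE.NAMES = FALSE)
  best <- which.max(idents)   # first max in canonical-then-id order
  if (idents[best] >= identity_threshold)
    list(isoform_id = df$isoform_id[best], match_kind = "best_alignment",
         identity = idents[best])
  else
    list(isoform_id = "", match_kind = "none", identity = max(idents))
}

block_lookup <- function(blocks, pos, from, to) {
  for (i in seq_len(nrow(blocks))) {
    s <- blocks[[from]][i]
    if (pos >= s && pos < s + blocks$length[i])
      return(blocks[[to]][i] + (pos - s))
  }
  NULL
}

#' Project an isoform position onto the canonical sequence
#'
#' @param aln an [align_isoform_to_canonical()] result.
#' @param pos 1-based isoform position.
#' @return 1-based canonical position, or `NULL` when `pos` falls in a gap
#'   (isoform-specific residue).
#' @export
isoform_to_canonical <- function(aln, pos) {
  if (!(pos >= 1 && pos <= aln$iso_len))
    range_error(sprintf("isoform position %s out of range 1..%d",
                        format(pos), aln$iso_len))
  block_lookup(aln$blocks, as.integer(pos), "iso_start", "canon_start")
}

#' Project a canonical position onto an isoform
#'
#' @param aln an [align_isoform_to_canonical()] result.
#' @param pos 1-based canonical position.
#' @return 1-based isoform position, or `NULL` when the canonical residue is
#'   absent from the isoform.
#' @export
canonical_to_isoform <- function(aln, pos) {
  if (!(pos >= 1 && pos <= aln$canon_len))
    range_error(sprintf("canonical position %s out of range 1..%d",
                        format(pos), aln$canon_len))
  block_lookup(aln$blocks, as.integer(pos), "canon_start", "iso_start")
}
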