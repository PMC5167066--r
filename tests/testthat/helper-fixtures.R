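# Shared test helpers: cached fixture bundles and independent oracles.

`%||%` <- function(a, b) if (is.null(a)) b else a

.fixture_cache <- new.env(parent = emptyenv())

fixed_bundle <- function() {
  if (is.null(.fixture_cache$fixed))
    .fixture_cache$fixed <- make_fixed_fixtures()
  .fixture_cache$fixed
}

random_bundle_42 <- function() {
  if (is.null(.fixture_cache$r42))
    .fixture_cache$r42 <- make_random_fixtures(42, 100)
  .fixture_cache$r42
}

fixed_transcripts <- function() all_transcripts(fixed_bundle()$gene_models)

# --- independent alignment oracles -----------------------------------------

# Memoized top-down recursion over (i, j, previous-move) — same scoring
# definition as the production aligner (a gap of length k costs
# open + k*extend; switching gap type re-opens) but a structurally
# different formulation.  Returns the optimal global score.
aln_score_oracle <- function(a, b, match = 2, mismatch = -1,
                             gap_open = -10, gap_extend = -0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    key <- paste(i, j, state)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, ifelse(av[i] == bv[j], match, mismatch) +
                    rec(i + 1, j + 1, "D"))
    if (i <= n)
      best <- max(best, gap_extend + (if (state != "A") gap_open else 0) +
                    rec(i + 1, j, "A"))
    if (j <= m)
      best <- max(best, gap_extend + (if (state != "B") gap_open else 0) +
                    rec(i, j + 1, "B"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "S")
}

# Exhaustive enumeration of every global alignment (all monotone move
# sequences) for tiny inputs; scores each alignment from its gap runs.
enum_align_score <- function(a, b, match = 2, mismatch = -1,
                             gap_open = -10, gap_extend = -0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  walk <- function(i, j, prev, score) {
    if (i > n && j > m) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= n && j <= m)
      walk(i + 1, j + 1, "D",
           score + ifelse(av[i] == bv[j], match, mismatch))
    if (i <= n)
      walk(i + 1, j, "A",
           score + gap_extend + if (prev != "A") gap_open else 0)
    if (j <= m)
      walk(i, j + 1, "B",
           score + gap_extend + if (prev != "B") gap_open else 0)
  }
  walk(1, 1, "S", 0)
  best
}

random_protein <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# expected canonical position for fixed-fixture transcripts, by construction
fixed_canonical_pos <- function(transcript_id, protein_pos) {
  switch(transcript_id,
         T1 = protein_pos,
         T2 = protein_pos,
         T3 = if (protein_pos <= 4) protein_pos else protein_pos + 4L,
         T4 = if (protein_pos <= 11) protein_pos
              else if (protein_pos <= 13) NULL else protein_pos - 2L)
}

fixed_accession <- function(transcript_id) {
  switch(transcript_id, T1 = "ACC1", T3 = "ACC1", T4 = "ACC1", T2 = "ACC2")
}
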