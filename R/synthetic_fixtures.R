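# Deterministic synthetic fixtures: genomes, gene models, isoform sets,
# residue mappings and variants with known ground truth, so every pipeline
# stage is testable without downloading real annotation.
#
# The fixed bundle is hand-specified (not seeded) so its values are stable
# identifiers; the random generator stress-tests invariants.  Ground truth
# is produced by an independent per-base walk over the genome
# (per_base_ground_truth), not by the interval-arithmetic mapper under test.

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"]

# overwrite ctg_chars[start0+1 .. ] with the characters of `seq`
splice_in <- function(ctg_chars, start0, seq) {
  s <- chars(seq)
  ctg_chars[(start0 + 1L):(start0 + length(s))] <- s
  ctg_chars
}

revcomp <- function(seq) paste(rev(complement_base(chars(seq))), collapse = "")

#' Per-base ground-truth genome-to-protein table (independent oracle)
#'
#' Builds, by a one-pass per-base walk structurally independent of
#' [cds_base_order()] arithmetic, the exhaustive table of coding bases:
#' for every transcript, a membership vector over its contig is marked base
#' by base from the CDS rows, ordered by strand, leader bases dropped,
#' bases grouped into consecutive triplets and the trailing stop codon
#' (translated directly from the genome) excluded.
#'
#' @param genome list of [contig()] objects.
#' @param gene_models list of [gene_model()] objects.
#' @return data.frame with columns `contig`, `offset` (0-based),
#'   `transcript_id`, `protein_pos`, `codon_offset`.
#' @export
per_base_ground_truth <- function(genome, gene_models) {
  out <- list()
  for (gm in gene_models) for (t in gm$transcripts) {
    ctg <- get_contig(genome, t$contig)
    member <- rep(FALSE, ctg$length)
    for (i in seq_len(nrow(t$cds)))
      for (p in seq.int(t$cds$start[i], t$cds$end[i] - 1L))
        member[p + 1L] <- TRUE
    walk <- which(member) - 1L
    if (t$strand == "-") walk <- rev(walk)
    if (t$phase0 > 0L) walk <- walk[-seq_len(t$phase0)]
    n_codon <- length(walk) %/% 3L
    if (n_codon == 0L) next
    walk <- walk[seq_len(3L * n_codon)]
    last_bases <- substring(ctg$sequence, walk[(3L * n_codon - 2L):(3L * n_codon)] + 1L,
                            walk[(3L * n_codon - 2L):(3L * n_codon)] + 1L)
    if (t$strand == "-") last_bases <- complement_base(last_bases)
    n_res <- if (translate_codon(paste(last_bases, collapse = "")) == "*")
      n_codon - 1L else n_codon
    if (n_res == 0L) next
    idx <- seq_len(3L * n_res)
    out[[length(out) + 1L]] <- data.frame(
      contig = t$contig, offset = walk[idx], transcript_id = t$id,
      protein_pos = (idx - 1L) %/% 3L + 1L,
      codon_offset = (idx - 1L) %% 3L)
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), offset = integer(0),
                      transcript_id = character(0), protein_pos = integer(0),
                      codon_offset = integer(0)))
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

residue_truth_table <- function(maps) {
  if (length(maps) == 0L)
    return(data.frame(accession = character(0), canonical_pos = integer(0),
                      pdb_id = character(0), chain_id = character(0),
                      auth_num = integer(0), ins_code = character(0),
                      observed = integer(0)))
  df <- do.call(rbind, lapply(maps, function(m)
    data.frame(accession = m$accession, canonical_pos = m$pairs$canonical_pos,
               pdb_id = m$pdb_id, chain_id = m$chain_id,
               auth_num = m$pairs$auth_num, ins_code = m$pairs$ins_code,
               observed = m$pairs$observed)))
  rownames(df) <- NULL
  df
}

new_fixture_bundle <- function(genome, gene_models, isoform_sets, maps,
                               variants, user_features) {
  structure(list(
    genome = genome, gene_models = gene_models, isoform_sets = isoform_sets,
    maps = maps, variants = variants, user_features = user_features,
    ground_truth = per_base_ground_truth(genome, gene_models),
    residue_truth = residue_truth_table(maps)),
    class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle: %d contig(s), %d gene(s), %d accession(s), %d mapping group(s), %d coding base(s)>\n",
              length(x$genome), length(x$gene_models), length(x$isoform_sets),
              length(x$maps), nrow(x$ground_truth)))
  invisible(x)
}

#' The hand-specified fixed fixture bundle
#'
#' One 400 bp contig `chrT` carrying:
#' * `T1` (`GENE1`, `+` strand, CDS `[100,131) U [200,229)`, phase 0): a
#'   clean 19-residue protein whose codon 11 spans the exon junction and
#'   whose stop codon occupies CDS bases 58--60;
#' * `T3` (`GENE1`): skips CDS bases 12--23 of `T1` (codons 5--8), so its
#'   translation equals the canonical sequence minus residues 5--8;
#' * `T4` (`GENE1`): retains a 6 bp cassette `[150,156)`, so its
#'   translation equals the canonical sequence with two residues inserted
#'   after position 11;
#' * `T2` (`GENE2`, `-` strand, CDS `[300,330)`): a 9-residue protein.
#'
#' Isoform sets: `ACC1` with canonical `ACC1-1` = translation of `T1`,
#' `ACC1-2` = canonical minus residues 5--8, `ACC1-3` = canonical with two
#' inserted residues; `ACC2` with canonical `ACC2-1` = translation of `T2`.
#'
#' Residue mappings: `MAP1` = `1XYZ:A` vs `ACC1`, canonical 3--17 at author
#' numbers 101--115 with canonical 12--13 unobserved; `MAP2` = `2ABC:B` vs
#' `ACC1`, canonical 5--14, including an insertion-code residue (auth 107,
#' ins `A`) and a `res_name` conflict (`ALA`) at canonical 10.
#'
#' Variants: a missense SNV in codon 3 of `T1`, a synonymous SNV in codon 4
#' and an intronic SNV.
#'
#' Regeneration is byte-identical (no randomness is involved).
#'
#' @return object of class `fixture_bundle` with components `genome`,
#'   `gene_models`, `isoform_sets`, `maps`, `variants`, `user_features`,
#'   `ground_truth` (per-base oracle table) and `residue_truth`.
#' @export
make_fixed_fixtures <- function() {
  # CDS of T1, codon per residue of "MDEFHIKLNPQRSVWYACG" plus TAA
  cds1 <- paste0("ATG", "GAT", "GAA", "TTT", "CAT", "ATT", "AAA", "CTG",
                 "AAT", "CCG", "CAA", "CGT", "AGC", "GTG", "TGG", "TAT",
                 "GCT", "TGC", "GGT", "TAA")
  stopifnot(nchar(cds1) == 60L)
  g <- rep(c("A", "C", "G", "T"), length.out = 400L)
  g <- splice_in(g, 100L, substr(cds1, 1L, 31L))    # exon-1 coding part
  g <- splice_in(g, 200L, substr(cds1, 32L, 60L))   # exon-2 coding part
  g <- splice_in(g, 150L, "AAACTA")                 # T4 cassette
  # T2 (minus strand): forward strand holds revcomp of "MVHLTPEEK" + stop
  g <- splice_in(g, 300L, "TTATTTTTCTTCCGGAGTCAGATGCACCAT")
  genome <- list(contig("chrT", paste(g, collapse = "")))

  iv <- function(s, e) data.frame(start = s, end = e)
  t1 <- transcript("T1", "GENE1", "Gene-One", "chrT", "+",
                   exons = iv(c(90L, 195L), c(140L, 240L)),
                   cds = iv(c(100L, 200L), c(131L, 229L)), phase0 = 0L)
  t3 <- transcript("T3", "GENE1", "Gene-One", "chrT", "+",
                   exons = iv(c(90L, 124L, 195L), c(112L, 140L, 240L)),
                   cds = iv(c(100L, 124L, 200L), c(112L, 131L, 229L)),
                   phase0 = 0L)
  t4 <- transcript("T4", "GENE1", "Gene-One", "chrT", "+",
                   exons = iv(c(90L, 150L, 195L), c(140L, 156L, 240L)),
                   cds = iv(c(100L, 150L, 200L), c(131L, 156L, 229L)),
                   phase0 = 0L)
  t2 <- transcript("T2", "GENE2", "Gene-Two", "chrT", "-",
                   exons = iv(290L, 340L), cds = iv(300L, 330L), phase0 = 0L)
  gene_models <- list(gene_model("GENE1", "Gene-One", list(t1, t3, t4)),
                      gene_model("GENE2", "Gene-Two", list(t2)))

  canon1 <- "MDEFHIKLNPQRSVWYACG"
  iso2 <- paste0(substr(canon1, 1L, 4L), substr(canon1, 9L, 19L))
  iso3 <- paste0(substr(canon1, 1L, 11L), "TK", substr(canon1, 12L, 19L))
  isoform_sets <- list(
    isoform_set("ACC1", data.frame(
      isoform_id = c("ACC1-1", "ACC1-2", "ACC1-3"),
      sequence = c(canon1, iso2, iso3),
      is_canonical = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)),
    isoform_set("ACC2", data.frame(
      isoform_id = "ACC2-1", sequence = "MVHLTPEEK", is_canonical = TRUE,
      stringsAsFactors = FALSE)))

  canon_chars <- chars(canon1)
  map1 <- residue_mapping("1XYZ", "A", "ACC1", data.frame(
    canonical_pos = 3:17, auth_num = 101:115, ins_code = "",
    observed = ifelse(3:17 %in% c(12L, 13L), 0L, 1L),
    res_name = unname(AA_1TO3[canon_chars[3:17]]),
    stringsAsFactors = FALSE))
  map2_pos <- 5:14
  map2_res <- unname(AA_1TO3[canon_chars[map2_pos]])
  map2_res[map2_pos == 10L] <- "ALA"   # engineered conflict at canonical 10
  map2 <- residue_mapping("2ABC", "B", "ACC1", data.frame(
    canonical_pos = map2_pos,
    auth_num = c(105L, 106L, 107L, 107L, 108L, 109L, 110L, 111L, 112L, 113L),
    ins_code = c("", "", "", "A", "", "", "", "", "", ""),
    observed = 1L, res_name = map2_res, stringsAsFactors = FALSE))
  maps <- list(map1, map2)

  variants <- data.frame(
    contig = "chrT", pos = c(107L, 112L, 161L),
    ref = c("G", "T", "A"), alt = c("C", "C", "G"),
    stringsAsFactors = FALSE)
  user_features <- data.frame(
    accession = "ACC1", start = 2L, end = 9L, type = "domain",
    label = "toy-domain", stringsAsFactors = FALSE)

  new_fixture_bundle(genome, gene_models, isoform_sets, maps, variants,
                     user_features)
}

#' Seeded random fixture bundles
#'
#' Generates `n_genes` genes, one per contig, with 1--8 exons, random phase,
#' both strands, clean translations (ATG start, no internal stop, trailing
#' stop codon); per gene a canonical isoform equal to the translation and,
#' with probability 0.5, an exon-skipped-style alternative isoform (an
#' internal run of 2--4 residues deleted); with probability 0.7 a residue
#' mapping over a random subrange with a random unobserved run and an
#' occasional insertion-code residue.  All randomness flows from `seed`;
#' the same seed reproduces the same bundle byte-for-byte.  The calling
#' session's RNG state is preserved.
#'
#' @param seed integer seed.
#' @param n_genes number of genes (>= 1).
#' @param exon_count_range length-2 integer range of exon counts (within
#'   1--8).
#' @param strand_mix probability of the minus strand.
#' @return a `fixture_bundle` (see [make_fixed_fixtures()]).
#' @export
make_random_fixtures <- function(seed, n_genes = 10L,
                                 exon_count_range = c(1L, 8L),
                                 strand_mix = 0.5) {
  if (!(is.numeric(n_genes) && n_genes >= 1L))
    param_error("n_genes must be >= 1")
  if (length(exon_count_range) != 2L ||
      exon_count_range[1L] < 1L || exon_count_range[2L] > 8L ||
      exon_count_range[1L] > exon_count_range[2L])
    param_error("exon_count_range must be an increasing range within 1..8")
  if (!(strand_mix >= 0 && strand_mix <= 1))
    param_error("strand_mix must be a probability")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)

  genome <- list(); gene_models <- list(); isoform_sets <- list()
  maps <- list()
  iv <- function(s, e) data.frame(start = s, end = e)
  for (i in seq_len(n_genes)) {
    ctg_name <- sprintf("rchr%03d", i)
    L <- sample(10:30, 1L)                 # residues
    phase0 <- sample(0:2, 1L)
    k <- sample(exon_count_range[1L]:exon_count_range[2L], 1L)
    strand <- if (stats::runif(1L) < strand_mix) "-" else "+"
    codons <- c("ATG", sample(SENSE_CODONS, L - 1L, replace = TRUE),
                sample(STOP_CODONS, 1L))
    leader <- paste(sample(DNA_ALPHABET[1:4], phase0, replace = TRUE),
                    collapse = "")
    cds_seq <- paste0(leader, paste(codons, collapse = ""))
    cds_len <- nchar(cds_seq)
    # split the CDS into k positive chunks (transcription order)
    cuts <- if (k > 1L) sort(sample(seq_len(cds_len - 1L), k - 1L)) else integer(0)
    chunk_lens <- diff(c(0L, cuts, cds_len))
    chunks <- substring(cds_seq, c(1L, cuts + 1L), c(cuts, cds_len))
    introns <- if (k > 1L) sample(8:30, k - 1L, replace = TRUE) else integer(0)
    utr5 <- sample(3:12, 1L); utr3 <- sample(3:12, 1L)
    # ascending genomic CDS intervals; for '-' transcription chunks are laid
    # out right-to-left
    asc_lens <- if (strand == "+") chunk_lens else rev(chunk_lens)
    starts <- integer(k); ends <- integer(k)
    cursor <- 30L
    for (j in seq_len(k)) {
      starts[j] <- cursor
      ends[j] <- cursor + asc_lens[j]
      cursor <- ends[j] + if (j < k) introns[j] else 0L
    }
    ctg_len <- ends[k] + 30L
    seq_chars <- sample(DNA_ALPHABET[1:4], ctg_len, replace = TRUE)
    for (j in seq_len(k)) {
      chunk_idx <- if (strand == "+") j else k - j + 1L
      content <- if (strand == "+") chunks[chunk_idx] else revcomp(chunks[chunk_idx])
      seq_chars <- splice_in(seq_chars, starts[j], content)
    }
    genome[[i]] <- contig(ctg_name, paste(seq_chars, collapse = ""))
    exon_start <- starts; exon_end <- ends
    if (strand == "+") {
      exon_start[1L] <- exon_start[1L] - utr5
      exon_end[k] <- exon_end[k] + utr3
    } else {
      exon_start[1L] <- exon_start[1L] - utr3
      exon_end[k] <- exon_end[k] + utr5
    }
    tid <- sprintf("RT%03d", i)
    gid <- sprintf("RG%03d", i)
    t <- transcript(tid, gid, gid, ctg_name, strand,
                    exons = iv(exon_start, exon_end),
                    cds = iv(starts, ends), phase0 = phase0)
    gene_models[[i]] <- gene_model(gid, gid, list(t))
    canon <- paste(translate_codon(codons[seq_len(L)]), collapse = "")
    acc <- sprintf("RACC%03d", i)
    iso_df <- data.frame(isoform_id = paste0(acc, "-1"), sequence = canon,
                         is_canonical = TRUE, stringsAsFactors = FALSE)
    if (stats::runif(1L) < 0.5 && L >= 12L) {
      del_start <- sample(3:(L - 6L), 1L)
      del_len <- sample(2:4, 1L)
      alt <- paste0(substr(canon, 1L, del_start - 1L),
                    substr(canon, del_start + del_len, L))
      if (alt != canon)
        iso_df <- rbind(iso_df, data.frame(
          isoform_id = paste0(acc, "-2"), sequence = alt,
          is_canonical = FALSE, stringsAsFactors = FALSE))
    }
    isoform_sets[[i]] <- isoform_set(acc, iso_df)
    if (stats::runif(1L) < 0.7) {
      s <- sample(seq_len(max(1L, L - 6L)), 1L)
      e <- min(L, s + sample(5:15, 1L))
      n <- e - s + 1L
      auth <- sample(50:500, 1L) + 0:(n - 1L)
      ins <- rep("", n)
      if (n >= 3L && stats::runif(1L) < 0.3) {
        j <- sample(2:n, 1L)
        auth[j:n] <- auth[j:n] - 1L
        ins[j] <- "A"
      }
      observed <- rep(1L, n)
      if (n >= 4L && stats::runif(1L) < 0.5) {
        us <- sample(seq_len(n - 1L), 1L)
        ue <- min(n, us + sample(1:3, 1L))
        observed[us:ue] <- 0L
      }
      maps[[length(maps) + 1L]] <- residue_mapping(
        sprintf("%04X", 4096L + i), "A", acc, data.frame(
          canonical_pos = s:e, auth_num = auth, ins_code = ins,
          observed = observed,
          res_name = unname(AA_1TO3[chars(canon)[s:e]]),
          stringsAsFactors = FALSE))
    }
  }
  variants <- data.frame(contig = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         stringsAsFactors = FALSE)
  user_features <- data.frame(accession = character(0), start = integer(0),
                              end = integer(0), type = character(0),
                              label = character(0), stringsAsFactors = FALSE)
  new_fixture_bundle(genome, gene_models, isoform_sets, maps, variants,
                     user_features)
}

#' Write a fixture bundle to a directory in the standard formats
#'
#' Emits `genome.fa`, `genes.gff3`, `isoforms.fa`, `mapping.tsv`,
#' `variants.tsv`, `user_features.tsv`, `ground_truth.tsv` and a
#' `config.txt` pointing at them.  All outputs are deterministic
#' byte-for-byte.
#'
#' @param bundle a `fixture_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2L) != 0L)
    usage_error(sprintf("cannot write to directory %s", dir))
  write_genome(bundle$genome, file.path(dir, "genome.fa"))
  write_gene_models(bundle$gene_models, file.path(dir, "genes.gff3"))
  write_isoforms(bundle$isoform_sets, file.path(dir, "isoforms.fa"))
  write_residue_mapping(bundle$maps, file.path(dir, "mapping.tsv"))
  write_tsv <- function(df, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    lines <- paste(names(df), collapse = "\t")
    if (nrow(df))
      lines <- c(lines, do.call(paste, c(unname(as.list(df)), sep = "\t")))
    writeLines(lines, con, sep = "\n")
  }
  write_tsv(bundle$variants, file.path(dir, "variants.tsv"))
  write_tsv(bundle$user_features, file.path(dir, "user_features.tsv"))
  write_tsv(bundle$ground_truth, file.path(dir, "ground_truth.tsv"))
  # paths relative to the config file itself, so the bundle is byte-identical
  # wherever it is written (read_config resolves them)
  cfg <- c("genome=genome.fa", "gff3=genes.gff3", "isoforms=isoforms.fa",
           "mapping=mapping.tsv", "variants=variants.tsv",
           "features=user_features.tsv")
  con <- file(file.path(dir, "config.txt"), open = "wb")
  writeLines(cfg, con, sep = "\n")
  close(con)
  invisible(dir)
}
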