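# Residue-level structure mapping and pipeline composition.

test_that("read_residue_mapping parses the TSV dialect and enforces invariants", {
  b <- fixed_bundle()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_residue_mapping(b$maps, tsv)
  back <- read_residue_mapping(tsv)
  expect_identical(back, b$maps)        # two chains -> two mapping groups
  expect_length(back, 2L)
  m1 <- back[[1]]
  expect_equal(nrow(m1$pairs), 15L)
  expect_equal(sum(m1$pairs$observed), 13L)

  hdr <- paste(c("pdb_id", "chain_id", "accession", "canonical_pos",
                 "auth_num", "ins_code", "observed", "res_name"),
               collapse = "\t")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(hdr, empty)
  expect_identical(read_residue_mapping(empty), list())

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr,
               "1ABC\tA\tP1\t3\t10\t.\t1\tALA",
               "1ABC\tA\tP1\t3\t11\t.\t1\tGLY"), dup)
  expect_error(read_residue_mapping(dup), "duplicate canonical_pos",
               class = "structmapr_format_error")

  badnum <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(hdr, "1ABC\tA\tP1\t3\tx\t.\t1\tALA"), badnum)
  expect_error(read_residue_mapping(badnum), "non-integer auth_num",
               class = "structmapr_format_error")
})

test_that("canonical_to_structure and structure_to_canonical are inverse", {
  b <- fixed_bundle()
  hits <- canonical_to_structure(b$maps, "ACC1", 3L)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$pdb_id, "1XYZ")
  expect_equal(hits[[1]]$auth_num, 101L)
  expect_true(hits[[1]]$observed)
  # unobserved residues are included but flagged
  h12 <- canonical_to_structure(b$maps, "ACC1", 12L)
  expect_equal(vapply(h12, `[[`, "", "pdb_id"), c("1XYZ", "2ABC"))
  expect_false(h12[[1]]$observed)
  expect_identical(canonical_to_structure(b$maps, "ACC1", 1L), list())

  expect_equal(structure_to_canonical(b$maps, "1XYZ", "A", 101L),
               list(accession = "ACC1", canonical_pos = 3L))
  expect_null(structure_to_canonical(b$maps, "1XYZ", "A", 999L))
  # insertion code selects a distinct residue
  expect_equal(structure_to_canonical(b$maps, "2ABC", "B", 107L)$canonical_pos,
               7L)
  expect_equal(
    structure_to_canonical(b$maps, "2ABC", "B", 107L, "A")$canonical_pos, 8L)

  # mutual inverse over every fixture pair
  for (m in b$maps) for (i in seq_len(nrow(m$pairs))) {
    p <- m$pairs[i, ]
    sc <- structure_to_canonical(b$maps, m$pdb_id, m$chain_id, p$auth_num,
                                 p$ins_code)
    expect_equal(sc$canonical_pos, p$canonical_pos)
    back <- canonical_to_structure(b$maps, m$accession, p$canonical_pos)
    keys <- vapply(back, function(h)
      paste(h$pdb_id, h$chain_id, h$auth_num, h$ins_code), "")
    expect_true(paste(m$pdb_id, m$chain_id, p$auth_num, p$ins_code) %in% keys)
  }
})

test_that("map_genome_to_structure composes stages with stated reasons", {
  b <- fixed_bundle()
  cache <- new.env()
  r <- map_genome_to_structure("chrT", 106L, b$gene_models, b$genome,
                               b$isoform_sets, b$maps, cache = cache)
  e <- r$entries[[which(vapply(r$entries, `[[`, "", "transcript_id") == "T1")]]
  expect_equal(e$stage, "complete")
  expect_equal(e$isoform_id, "ACC1-1")
  expect_equal(e$canonical_pos, 3L)
  expect_equal(e$hits[[1]]$auth_num, 101L)

  r2 <- map_genome_to_structure("chrT", 150L, b$gene_models, b$genome,
                                b$isoform_sets, b$maps, cache = cache)
  e2 <- r2$entries[[which(vapply(r2$entries, `[[`, "", "transcript_id") == "T1")]]
  expect_equal(e2$stage, "genomic_to_protein")
  expect_equal(e2$reason, "non-coding")

  # T4 cassette codon: isoform position 12 has no canonical residue
  r3 <- map_genome_to_structure("chrT", 152L, b$gene_models, b$genome,
                                b$isoform_sets, b$maps, cache = cache)
  e3 <- r3$entries[[which(vapply(r3$entries, `[[`, "", "transcript_id") == "T4")]]
  expect_equal(e3$stage, "isoform_to_canonical")
  expect_equal(e3$reason, "not in canonical")
  expect_equal(e3$isoform_id, "ACC1-3")

  # entries ordered by transcript id
  expect_equal(vapply(r$entries, `[[`, "", "transcript_id"),
               c("T1", "T2", "T3", "T4"))
})

test_that("map_structure_to_genome inverts the pipeline", {
  b <- fixed_bundle()
  cache <- new.env()
  r <- map_structure_to_genome("1XYZ", "A", 101L, "", b$gene_models,
                               b$genome, b$isoform_sets, b$maps,
                               cache = cache)
  expect_equal(r$accession, "ACC1")
  expect_equal(r$canonical_pos, 3L)
  e <- r$entries[[which(vapply(r$entries, `[[`, "", "transcript_id") == "T1")]]
  expect_equal(e$codon$base_positions, c(106L, 107L, 108L))

  # unmapped residue -> empty result
  r2 <- map_structure_to_genome("1XYZ", "A", 999L, "", b$gene_models,
                                b$genome, b$isoform_sets, b$maps,
                                cache = cache)
  expect_null(r2$accession)
  expect_length(r2$entries, 0L)

  # canonical residue 6 is deleted in T3's isoform
  r3 <- map_structure_to_genome("2ABC", "B", 106L, "", b$gene_models,
                                b$genome, b$isoform_sets, b$maps,
                                cache = cache)
  e3 <- r3$entries[[which(vapply(r3$entries, `[[`, "", "transcript_id") == "T3")]]
  expect_equal(e3$reason, "not in isoform")
  expect_null(e3$codon)
})

test_that("full round-trip: every structure hit maps back to its query base", {
  b <- fixed_bundle()
  cache <- new.env()
  for (pos in 0:399) {
    r <- map_genome_to_structure("chrT", pos, b$gene_models, b$genome,
                                 b$isoform_sets, b$maps, cache = cache)
    for (e in r$entries) {
      if (length(e$hits) == 0L) next
      for (h in e$hits) {
        back <- map_structure_to_genome(h$pdb_id, h$chain_id, h$auth_num,
                                        h$ins_code, b$gene_models, b$genome,
                                        b$isoform_sets, b$maps,
                                        cache = cache)
        be <- back$entries[[which(vapply(back$entries, `[[`, "",
                                         "transcript_id") == e$transcript_id)]]
        expect_true(pos %in% be$codon$base_positions)
      }
    }
  }
})
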