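# Annotation tracks, mismatch detection, JSON serialization, BED export.

test_that("build_exon_track assigns junction codons to the first-base exon", {
  b <- fixed_bundle()
  ts <- fixed_transcripts()
  iso1 <- b$isoform_sets[[1]]
  et <- build_exon_track(ts$T1, b$genome, iso1)
  expect_equal(vapply(et$features, `[[`, "", "label"), c("exon1", "exon2"))
  # codon 11 starts on the last base of exon 1 -> residue 11 belongs to exon 1
  expect_equal(et$features[[1]]$start, 1L)
  expect_equal(et$features[[1]]$end, 11L)
  expect_equal(et$features[[2]]$start, 12L)
  expect_equal(et$features[[2]]$end, 19L)

  # exon-skipped transcript: canonical positions shift through the alignment
  et3 <- build_exon_track(ts$T3, b$genome, iso1)
  spans <- t(vapply(et3$features, function(f) c(f$start, f$end), c(0L, 0L)))
  expect_equal(unname(spans), rbind(c(1L, 4L), c(9L, 11L), c(12L, 19L)))

  # single coding exon -> one feature [1, protein length]
  et2 <- build_exon_track(ts$T2, b$genome, b$isoform_sets[[2]])
  expect_length(et2$features, 1L)
  expect_equal(c(et2$features[[1]]$start, et2$features[[1]]$end), c(1L, 9L))
})

test_that("build_variant_track labels amino-acid changes and consequences", {
  b <- fixed_bundle()
  ts <- fixed_transcripts()
  iso1 <- b$isoform_sets[[1]]
  expect_warning(
    vt <- build_variant_track(b$variants, ts$T1, b$genome, iso1),
    "non-coding")                          # the intronic SNV warns
  expect_length(vt$features, 2L)
  f1 <- vt$features[[1]]
  expect_equal(f1$label, "E3Q")            # G>C in codon 3 base 1
  expect_equal(c(f1$start, f1$end), c(3L, 3L))
  expect_equal(f1$attributes$consequence, "missense")
  f2 <- vt$features[[2]]
  expect_equal(f2$attributes$consequence, "synonymous")
  expect_equal(f2$start, 4L)

  # label invariant: re-translating the mutated codon reproduces the label
  for (f in vt$features) {
    v <- b$variants[match(f$attributes$genomic,
                          sprintf("%s:%d:%s>%s", b$variants$contig,
                                  b$variants$pos, b$variants$ref,
                                  b$variants$alt)), ]
    pp <- genomic_to_protein(ts$T1, v$pos - 1L, b$genome)
    cl <- protein_to_codon(ts$T1, pp$protein_pos, b$genome)
    mut <- cl$codon
    substr(mut, pp$codon_offset + 1L, pp$codon_offset + 1L) <- v$alt
    expect_equal(substr(f$label, nchar(f$label), nchar(f$label)),
                 structmapr:::translate_codon(mut))
  }

  # ref mismatch is skipped with a warning
  badref <- data.frame(contig = "chrT", pos = 107L, ref = "T", alt = "C")
  expect_warning(
    vtb <- build_variant_track(badref, ts$T1, b$genome, iso1),
    "does not match")
  expect_length(vtb$features, 0L)

  # malformed variant strings raise a format error
  expect_error(parse_variant_strings("chrT:xx:G:C"),
               class = "structmapr_format_error")
  pv <- parse_variant_strings("chrT:107:G:C")
  expect_equal(pv$pos, 107L)
})

test_that("build_coverage_track emits runs with observed fractions", {
  b <- fixed_bundle()
  ct <- build_coverage_track(b$maps, "ACC1")
  expect_length(ct$features, 2L)
  f1 <- ct$features[[1]]
  expect_equal(c(f1$start, f1$end), c(3L, 17L))
  expect_equal(f1$attributes$observed_fraction, 13 / 15)
  expect_equal(ct$provenance, "PDB")
  expect_equal(ct$color_hint, "blue")
  expect_length(build_coverage_track(list(), "ACC1")$features, 0L)

  # a hole splits the run
  m <- residue_mapping("3DEF", "A", "ACC1", data.frame(
    canonical_pos = c(3:7, 9:17), auth_num = c(3:7, 9:17) + 100L,
    ins_code = "", observed = 1L, res_name = "ALA"))
  ct2 <- build_coverage_track(list(m), "ACC1")
  spans <- t(vapply(ct2$features, function(f) c(f$start, f$end), c(0L, 0L)))
  expect_equal(unname(spans), rbind(c(3L, 7L), c(9L, 17L)))
})

test_that("detect_mismatches classifies substitutions and terminal runs", {
  b <- fixed_bundle()
  canon <- canonical_sequence(b$isoform_sets[[1]])
  mt <- detect_mismatches(b$maps[[2]], canon)
  expect_length(mt$features, 1L)
  expect_equal(c(mt$features[[1]]$start, mt$features[[1]]$end), c(10L, 10L))
  expect_equal(mt$features[[1]]$attributes$class, "substitution")

  # identical over its range -> empty track
  expect_length(detect_mismatches(b$maps[[1]], canon)$features, 0L)

  # three mismatches at the start of the mapped range -> terminal_extension
  p <- b$maps[[1]]$pairs
  p$res_name[1:3] <- "TRP"   # canonical 3..5 are E,F,H
  m <- residue_mapping("1XYZ", "A", "ACC1", p)
  mt2 <- detect_mismatches(m, canon)
  expect_length(mt2$features, 1L)
  expect_equal(c(mt2$features[[1]]$start, mt2$features[[1]]$end), c(3L, 5L))
  expect_equal(mt2$features[[1]]$attributes$class, "terminal_extension")
})

test_that("track JSON is schema-valid, stable and round-trips", {
  b <- fixed_bundle()
  ts <- fixed_transcripts()
  iso1 <- b$isoform_sets[[1]]
  tracks <- list(build_exon_track(ts$T1, b$genome, iso1),
                 build_coverage_track(b$maps, "ACC1"),
                 detect_mismatches(b$maps[[2]],
                                   canonical_sequence(iso1)),
                 build_user_track(b$user_features, "ACC1"))
  j <- tracks_to_json(tracks, "ACC1", 19L)
  expect_true(validate_track_json(j))
  # byte-identical across two builds
  tracks_b <- list(build_exon_track(ts$T1, b$genome, iso1),
                   build_coverage_track(b$maps, "ACC1"),
                   detect_mismatches(b$maps[[2]],
                                     canonical_sequence(iso1)),
                   build_user_track(b$user_features, "ACC1"))
  expect_identical(tracks_to_json(tracks_b, "ACC1", 19L), j)
  # parse -> serialize is the identity on documents
  expect_identical(tracks_to_json(parse_tracks_json(j)$tracks, "ACC1", 19L), j)
  # empty document
  j0 <- tracks_to_json(list(), "ACC1", 19L)
  expect_match(j0, "\"tracks\":\\[\\]")
  expect_true(validate_track_json(j0))
  # features outside [1, canonical length] are rejected
  badf <- feature_track("bad", "user", list(feature(18, 25, "user")))
  expect_error(tracks_to_json(list(badf), "ACC1", 19L),
               class = "structmapr_param_error")
  # schema violations are caught
  expect_error(validate_track_json("{\"accession\":\"A\",\"length\":5}"),
               class = "structmapr_format_error")
})

test_that("every feature of built tracks lies within the canonical range", {
  b <- fixed_bundle()
  res <- structure(list(genome = b$genome, gene_models = b$gene_models,
                        isoform_sets = b$isoform_sets, maps = b$maps,
                        variants = b$variants,
                        user_features = b$user_features,
                        identity_threshold = 0.95,
                        cache = new.env()), class = "resources")
  for (acc in c("ACC1", "ACC2")) {
    canon_len <- nchar(canonical_sequence(
      structmapr:::get_isoform_set(b$isoform_sets, acc)))
    for (tr in suppressWarnings(build_all_tracks(res, acc)))
      for (f in tr$features) {
        expect_gte(f$start, 1L)
        expect_lte(f$end, canon_len)
        expect_lte(f$start, f$end)
      }
  }
})

test_that("BED export equals the brute-force codon union and merges runs", {
  b <- fixed_bundle()
  ts <- fixed_transcripts()
  iso1 <- b$isoform_sets[[1]]
  bed <- export_coverage_bed(ts$T1, b$maps[[1]], b$genome, iso1)
  expect_equal(nrow(bed), 2L)      # split at the intron
  bed_bases <- unlist(mapply(seq.int, bed$start, bed$end - 1L,
                             SIMPLIFY = FALSE))
  brute <- sort(unique(unlist(lapply(b$maps[[1]]$pairs$canonical_pos,
    function(cp) protein_to_codon(ts$T1, cp, b$genome)$base_positions))))
  expect_identical(sort(as.integer(bed_bases)), as.integer(brute))
  expect_true(all(bed$start < bed$end))

  # minus-strand transcript yields ascending-coordinate records
  m2 <- residue_mapping("9GLB", "A", "ACC2", data.frame(
    canonical_pos = 2:5, auth_num = 12:15, ins_code = "", observed = 1L,
    res_name = unname(structmapr:::AA_1TO3[
      strsplit("VHLT", "")[[1]]])))
  bedm <- export_coverage_bed(ts$T2, m2, b$genome, b$isoform_sets[[2]])
  expect_true(all(bedm$start < bedm$end))
  expect_true(all(bedm$strand == "-"))
  # residues 2..5 in transcription order cover offsets [315, 327) forward
  expect_equal(bedm$start, 315L)
  expect_equal(bedm$end, 327L)

  # empty mapping -> no records
  empty <- export_coverage_bed(ts$T1, m2, b$genome, iso1)
  expect_equal(nrow(empty), 0L)
})
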