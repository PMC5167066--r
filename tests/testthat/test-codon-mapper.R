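# Codon arithmetic: CDS enumeration, genome<->protein mapping, translation.

test_that("cds_base_order enumerates CDS bases in transcription order", {
  ts <- fixed_transcripts()
  o1 <- cds_base_order(ts$T1)
  expect_length(o1, 60L)
  expect_equal(o1[1:3], c(100L, 101L, 102L))
  expect_equal(o1[31:33], c(130L, 200L, 201L))   # exon junction
  expect_equal(o1[60], 228L)

  o2 <- cds_base_order(ts$T2)
  expect_length(o2, 30L)
  expect_equal(o2[1:3], c(329L, 328L, 327L))     # minus strand: descending
})

test_that("phase leader bases are excluded from codon numbering", {
  b <- fixed_bundle()
  iv <- function(s, e) data.frame(start = s, end = e)
  # T1 CDS extended one base left, phase0 = 1: same codons, one leader base
  tp <- transcript("TP", "GENE1", "Gene-One", "chrT", "+",
                   exons = iv(c(90L, 195L), c(140L, 240L)),
                   cds = iv(c(99L, 200L), c(131L, 229L)), phase0 = 1L)
  expect_null(genomic_to_protein(tp, 99L, b$genome))    # leader base
  pp <- genomic_to_protein(tp, 100L, b$genome)
  expect_equal(pp$protein_pos, 1L)
  expect_equal(pp$codon_offset, 0L)
  expect_equal(protein_to_codon(tp, 1L, b$genome)$codon, "ATG")
  expect_equal(translate_transcript(tp, b$genome),
               translate_transcript(fixed_transcripts()$T1, b$genome))
})

test_that("genomic_to_protein handles coding, junction, intron and stop", {
  b <- fixed_bundle()
  t1 <- fixed_transcripts()$T1
  p <- genomic_to_protein(t1, 100L, b$genome)
  expect_equal(p$protein_pos, 1L)
  expect_equal(p$codon_offset, 0L)
  # base 31 of the CDS: codon 11 starts on the last base of exon 1
  p130 <- genomic_to_protein(t1, 130L, b$genome)
  expect_equal(p130$protein_pos, 11L)
  expect_equal(p130$codon_offset, 0L)
  expect_null(genomic_to_protein(t1, 150L, b$genome))   # intronic
  expect_null(genomic_to_protein(t1, 226L, b$genome))   # stop codon base
  expect_null(genomic_to_protein(t1, 228L, b$genome))
  expect_null(genomic_to_protein(t1, 95L, b$genome))    # UTR
})

test_that("protein_to_codon returns transcription-order loci", {
  b <- fixed_bundle()
  ts <- fixed_transcripts()
  cl <- protein_to_codon(ts$T1, 11L, b$genome)
  expect_equal(cl$base_positions, c(130L, 200L, 201L))  # spans the junction
  expect_equal(cl$codon, "CAA")
  expect_equal(cl$amino_acid, "Q")
  expect_equal(protein_to_codon(ts$T1, 1L, b$genome)$base_positions,
               c(100L, 101L, 102L))
  cl2 <- protein_to_codon(ts$T2, 1L, b$genome)
  expect_equal(cl2$base_positions, c(329L, 328L, 327L))
  expect_equal(cl2$codon, "ATG")                        # reverse-complemented
  expect_error(protein_to_codon(ts$T1, 20L, b$genome),
               class = "structmapr_range_error")
  expect_error(protein_to_codon(ts$T1, 0L, b$genome),
               class = "structmapr_range_error")
})

test_that("translate_transcript applies the standard code and edge rules", {
  b <- fixed_bundle()
  ts <- fixed_transcripts()
  expect_equal(translate_transcript(ts$T1, b$genome), "MDEFHIKLNPQRSVWYACG")
  expect_equal(nchar(translate_transcript(ts$T1, b$genome)), 19L)
  expect_equal(translate_transcript(ts$T2, b$genome), "MVHLTPEEK")

  iv <- function(s, e) data.frame(start = s, end = e)
  # minimal CDS "ATGTAA" -> "M"
  g <- list(contig("c", "ATGTAAGG"))
  tm <- transcript("tm", "g", "g", "c", "+", iv(0, 8), iv(0, 6))
  expect_equal(translate_transcript(tm, g), "M")
  # codon with N -> X
  gx <- list(contig("c", "ATGANATAA"))
  tx <- transcript("tx", "g", "g", "c", "+", iv(0, 9), iv(0, 9))
  expect_equal(translate_transcript(tx, gx), "MX")
  # internal stop truncates with a warning
  gs <- list(contig("c", "ATGTAAGGGTAA"))
  tsp <- transcript("tsp", "g", "g", "c", "+", iv(0, 12), iv(0, 12))
  expect_warning(p <- translate_transcript(tsp, gs), "internal stop")
  expect_equal(p, "M")
})

test_that("round-trip holds exhaustively on the fixed contig", {
  b <- fixed_bundle()
  for (t in fixed_transcripts()) {
    for (pos in 0:399) {
      pp <- genomic_to_protein(t, pos, b$genome)
      if (!is.null(pp)) {
        cl <- protein_to_codon(t, pp$protein_pos, b$genome)
        expect_identical(cl$base_positions[pp$codon_offset + 1L],
                         as.integer(pos))
      }
    }
    # conservation: mapped genomic positions == 3 * protein length
    n_mapped <- sum(!vapply(0:399, function(p)
      is.null(genomic_to_protein(t, p, b$genome)), TRUE))
    expect_equal(n_mapped, 3L * protein_length(t, b$genome))
  }
})

test_that("strand symmetry: mirroring the contig preserves protein answers", {
  b <- fixed_bundle()
  L <- b$genome[[1]]$length
  mirrored <- list(contig("chrT", paste(
    rev(strsplit(chartr("ACGT", "TGCA", b$genome[[1]]$sequence), "")[[1]]),
    collapse = "")))
  for (t in fixed_transcripts()) {
    tm <- transcript(t$id, t$gene_id, t$gene_name, t$contig,
                     if (t$strand == "+") "-" else "+",
                     exons = data.frame(start = L - t$exons$end,
                                        end = L - t$exons$start),
                     cds = data.frame(start = L - t$cds$end,
                                      end = L - t$cds$start),
                     phase0 = t$phase0)
    expect_equal(translate_transcript(tm, mirrored),
                 translate_transcript(t, b$genome), label = t$id)
    for (pos in 0:(L - 1L)) {
      a <- genomic_to_protein(t, pos, b$genome)
      m <- genomic_to_protein(tm, L - 1L - pos, mirrored)
      expect_identical(is.null(a), is.null(m))
      if (!is.null(a)) {
        expect_identical(a$protein_pos, m$protein_pos)
        expect_identical(a$codon_offset, m$codon_offset)
      }
    }
  }
})
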