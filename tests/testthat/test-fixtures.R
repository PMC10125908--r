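th <- thresholds()

test_that("toy genes are reproducible, well-formed and strand-consistent", {
  a <- make_toy_gene(n_exons = 3, seed = 1)
  b <- make_toy_gene(n_exons = 3, seed = 1)
  expect_identical(a$genome$contigs, b$genome$contigs)
  expect_identical(a$transcript, b$transcript)

  one <- make_toy_gene(n_exons = 1, exon_lengths = 200L, seed = 2)
  expect_equal(nrow(native_splice_sites(one$transcript)), 0L)

  expect_error(make_toy_gene(n_exons = 3, exon_lengths = c(10L, 10L, 10L)),
               "infeasible|>=")
})

test_that("generated reference CDS starts ATG, ends at a stop, no internal stop", {
  for (strand in c("+", "-")) {
    gt <- make_toy_gene(n_exons = 4, seed = 13, strand = strand)
    t <- gt$transcript
    alt <- apply_calls(t, classify(rec_for(t, t$exons[1, "start"] + 35L), t, th),
                       gt$genome)
    cds_len <- splicefx:::cds_genomic_length(t)
    cds <- substr(alt$ref_mrna, alt$ref_cds_offset, alt$ref_cds_offset + cds_len - 1L)
    expect_equal(substr(cds, 1, 3), "ATG")
    # independent oracle: Biostrings translation of the full CDS
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
    expect_equal(substring(aa, nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))

    # GT/AG at every intron boundary, read on the transcript strand
    ns <- native_splice_sites(t)
    s <- splicefx:::strand_sign(t$strand)
    for (i in unique(ns$intron)) {
      don <- ns$pos[ns$kind == "donor" & ns$intron == i]
      acc <- ns$pos[ns$kind == "acceptor" & ns$intron == i]
      first2 <- seq_at(gt$genome, t$contig, min(don + s, don + 2L * s),
                       max(don + s, don + 2L * s))
      last2 <- seq_at(gt$genome, t$contig, min(acc - s, acc - 2L * s),
                      max(acc - s, acc - 2L * s))
      if (t$strand == "-") {
        first2 <- splicefx:::revcomp(first2)
        last2 <- splicefx:::revcomp(last2)
      }
      expect_equal(first2, "GT")
      expect_equal(last2, "AG")
    }
  }
})

test_that("forged truths honour thresholds and the pseudoexon size gate", {
  neg <- forge_case("negative", seed = 4)
  r <- neg$record
  expect_true(all(c(r$ds_ag, r$ds_al, r$ds_dg, r$ds_dl) < th$noise_floor))
  expect_equal(neg$truth$types, "no_impact")

  big <- forge_case("pseudoexonization", list(size = 600L), seed = 4)
  expect_equal(big$truth$types, "no_impact")
  expect_equal(classify(big$record, big$transcript, th)$type, "no_impact")

  ok <- forge_case("pseudoexonization", list(size = 101L), seed = 4)
  expect_equal(ok$truth$types, "pseudoexonization")
  expect_equal(ok$truth$inserted_bp, 101L)
  expect_equal(ok$truth$frame, "frameshift")
})

test_that("corpus generation is deterministic and negatives yield no calls", {
  c1 <- build_corpus(seed = 7, n_per_type = 2)
  c2 <- build_corpus(seed = 7, n_per_type = 2)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$cases[[1]]$genome$contigs, c2$cases[[1]]$genome$contigs)

  for (cs in c1$cases[c1$labels$category == "negative"]) {
    expect_equal(classify(cs$record, cs$transcript, th)$type, "no_impact")
  }

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture_files(c1, d1)
  p2 <- write_fixture_files(c2, d2)
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), info = k)
  }
})

test_that("fixture files round-trip through every reader without warnings", {
  corpus <- build_corpus(seed = 9, n_per_type = 1)
  dir <- withr::local_tempdir()
  paths <- write_fixture_files(corpus, dir)
  expect_no_warning(rec <- parse_spliceai_vcf(paths["vcf"]))
  expect_no_warning(tbl <- read_gene_transcript_table(paths["genes"]))
  expect_no_warning(models <- load_transcripts(paths["gtf"], tbl))
  genome <- read_genome_fasta(paths["fasta"])
  expect_equal(nrow(rec), length(corpus$cases))
  for (cs in corpus$cases) {
    m <- models[[cs$transcript$gene_symbol]]
    expect_identical(m$exons, cs$transcript$exons)
    expect_equal(m$cds_start, cs$transcript$cds_start)
    expect_equal(m$cds_end, cs$transcript$cds_end)
    expect_equal(genome$contigs[[cs$transcript$contig]],
                 cs$genome$contigs[[cs$transcript$contig]])
  }
})
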