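th <- thresholds()

test_that("apply_calls edits segments and keeps length bookkeeping consistent", {
  gt <- make_toy_gene(n_exons = 3, exon_lengths = c(120L, 164L, 150L),
                      intron_lengths = c(500L, 600L), seed = 8)
  t <- gt$transcript

  # identity
  noimp <- classify(rec_for(t, t$exons[2, "start"] + 5L), t, th)
  alt0 <- apply_calls(t, noimp, gt$genome)
  expect_equal(unname(alt0$segments), unname(cbind(t$exons[, "start"], t$exons[, "end"])))
  expect_equal(alt0$delta_len, 0L)

  # skip the 164-bp exon
  ns <- native_splice_sites(t)
  rskip <- rec_for(t, t$exons[2, "start"] + 80L,
                   al = c(0.9, ns$pos[ns$kind == "acceptor" & ns$intron == 1L]),
                   dl = c(0.8, ns$pos[ns$kind == "donor" & ns$intron == 2L]))
  alt1 <- apply_calls(t, classify(rskip, t, th), gt$genome)
  expect_equal(alt1$delta_len, -164L)
  expect_equal(nrow(alt1$segments), 2L)

  # 101-bp pseudoexon in intron 2: one extra segment, two extra junctions
  iv <- splicefx:::intron_interval(t, 2L)
  rpe <- rec_for(t, iv[1] + 60L, ag = c(0.3, iv[1] + 20L), dg = c(0.25, iv[1] + 120L))
  alt2 <- apply_calls(t, classify(rpe, t, th), gt$genome)
  expect_equal(alt2$delta_len, 101L)
  expect_equal(nrow(alt2$segments), nrow(alt0$segments) + 1L)
  expect_equal(length(alt2$junctions), length(alt0$junctions) + 1L)

  # referencing an absent feature is a consistency error
  bad <- classify(rskip, t, th)
  bad$from <- 9L; bad$to <- 9L
  expect_error(apply_calls(t, bad, gt$genome), "outside the transcript")
})

test_that("altered-transcript length change equals inserted minus deleted", {
  corpus <- build_corpus(seed = 17, n_per_type = 2)
  for (cs in corpus$cases) {
    calls <- classify(cs$record, cs$transcript, th)
    alt <- apply_calls(cs$transcript, calls, cs$genome)
    expect_equal(alt$delta_len, sum(calls$inserted_bp) - sum(calls$deleted_bp),
                 info = cs$case_id)
  }
})

test_that("frame effect is plain mod-3 arithmetic", {
  expect_equal(frame_effect(0L), "in_frame")
  expect_equal(frame_effect(-119L), "frameshift")
  expect_equal(frame_effect(101L), "frameshift")
  d <- -1000:1000
  expect_equal(frame_effect(d), ifelse(d %% 3 == 0, "in_frame", "frameshift"))
})

test_that("translation follows the standard code with N->X and stop handling", {
  p <- translate_cds("ATGGCTTAA")
  expect_equal(as.character(p), "MA")
  expect_true(attr(p, "terminated"))

  p2 <- translate_cds("ATGAANGGG")
  expect_equal(as.character(p2), "MXG")

  p3 <- translate_cds("ATGTT")   # trailing incomplete codon dropped
  expect_equal(as.character(p3), "M")
  expect_true(attr(p3, "incomplete_tail"))

  expect_error(translate_cds(""), "empty")
})

test_that("frameshifted translation diverges exactly where an independent oracle says", {
  set.seed(5)
  codons <- c("ATG", sample(splicefx:::NONSTOP_CODONS, 40, replace = TRUE), "TAA")
  cds <- paste(codons, collapse = "")
  shifted <- paste0(substr(cds, 1, 60), substring(cds, 62))  # delete nt 61

  mine <- as.character(translate_cds(shifted))
  # oracle: Biostrings translation of the frame-trimmed sequence
  n3 <- nchar(shifted) - nchar(shifted) %% 3
  oracle <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(shifted, 1, n3))
  ))
  oracle <- sub("\\*.*$", "", oracle)
  expect_equal(mine, oracle)
  # divergence begins at the first affected codon (codon 21)
  wt <- as.character(translate_cds(cds))
  expect_equal(substr(mine, 1, 20), substr(wt, 1, 20))
})

test_that("bracket notation renders substitutions, deletions and frameshifts", {
  expect_equal(as.character(format_notation("MABC", "MABC")), ".")

  # in-frame deletion of codons 10-12, no missense: residues 7-9, blank
  # brackets, residues 13-15
  wt <- "MAKLSTRWHEDCVIPQGYFN"
  mut <- paste0(substr(wt, 1, 9), substring(wt, 13))
  nt <- format_notation(wt, mut)
  expect_equal(as.character(nt), paste0("RWH", "[]", "VIP"))
  expect_equal(attr(nt, "first_affected_codon"), 10L)

  # frameshift introducing 5 novel residues then a stop
  mut2 <- paste0(substr(wt, 1, 9), "LQRST")
  nt2 <- format_notation(wt, mut2, frameshift = TRUE)
  expect_equal(as.character(nt2), "RWH[LQRST*]")

  # frameshift that never reaches a stop: no '*' inside the bracket
  nt3 <- format_notation(wt, mut2, frameshift = TRUE, terminated = FALSE)
  expect_equal(as.character(nt3), "RWH[LQRST]")

  # in-frame missense: bracket closes at re-synchronization
  mut4 <- paste0(substr(wt, 1, 9), "GG", substring(wt, 12))
  nt4 <- format_notation(wt, mut4)
  expect_equal(as.character(nt4), "RWH[GG]")
})

test_that("the 50-nt rule separates NMD from truncation", {
  expect_true(nmd_predict(800L, c(300L, 1000L)))          # 200 nt upstream
  expect_false(nmd_predict(960L, c(300L, 1000L)))         # within 50 nt
  expect_false(nmd_predict(950L, c(300L, 1000L)))         # exactly 50: no NMD
  expect_true(nmd_predict(949L, c(300L, 1000L)))
  expect_false(nmd_predict(1200L, c(300L, 1000L)))        # PTC in last exon
  expect_false(nmd_predict(10L, integer(0)))              # single-exon transcript
})

test_that("protein effects are suppressed when a call disrupts the start codon", {
  gt <- make_toy_gene(n_exons = 3, exon_lengths = c(120L, 164L, 150L),
                      intron_lengths = c(500L, 600L), seed = 8, utr5_len = 21L)
  t <- gt$transcript
  # donor-side cryptic site 5 bp into exon 1 trims away the start codon
  gpos <- t$exons[1, "start"] + 5L
  r <- rec_for(t, t$exons[1, "start"] + 40L, dg = c(0.4, gpos))
  calls <- classify(r, t, th)
  expect_equal(calls$type, "partial_exon_deletion")
  pe <- predict_protein_effect(t, calls, gt$genome, th)
  expect_true(is.na(pe$notation))
  expect_match(pe$protein_note, "start codon disrupted")
})

test_that("notation round-trips as an edit script over the forged corpus", {
  corpus <- build_corpus(seed = 23, n_per_type = 2)
  n_checked <- 0L
  for (cs in corpus$cases) {
    calls <- classify(cs$record, cs$transcript, th)
    pe <- predict_protein_effect(cs$transcript, calls, cs$genome, th)
    if (cs$truth$notation_class == "none") {
      expect_equal(pe$notation, ".")
      next
    }
    expect_false(is.na(pe$notation))
    if (cs$truth$notation_class == "blank_brackets") {
      expect_match(pe$notation, "\\[\\]")
    }
    if (pe$notation == ".") next  # silent at protein level (e.g. UTR-only edit)
    pp <- protein_pair(cs$transcript, calls, cs$genome)
    expect_notation_roundtrip(pp$wt, pp$mut, pe$notation, pe$first_affected_codon)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 10L)
})

test_that("a codon-aligned clean exon skip serializes as blank brackets", {
  cs <- forge_case("exon_skipping", list(inframe_clean = TRUE), seed = 3)
  calls <- classify(cs$record, cs$transcript, th)
  pe <- predict_protein_effect(cs$transcript, calls, cs$genome, th)
  expect_equal(pe$frame, "in_frame")
  expect_match(pe$notation, "^[A-Z]{1,3}\\[\\][A-Z]{1,3}$")
  pp <- protein_pair(cs$transcript, calls, cs$genome)
  expect_notation_roundtrip(pp$wt, pp$mut, pe$notation, pe$first_affected_codon)
})

test_that("nmd flag on frameshifting pseudoexons matches direct arithmetic", {
  cs <- forge_case("pseudoexonization", list(size = 101L), seed = 42)
  calls <- classify(cs$record, cs$transcript, th)
  pe <- predict_protein_effect(cs$transcript, calls, cs$genome, th)
  expect_equal(pe$frame, "frameshift")
  alt <- apply_calls(cs$transcript, calls, cs$genome)
  if (!is.na(pe$ptc_codon)) {
    ptc_nt <- alt$cds_offset + 3L * (pe$ptc_codon - 1L)
    expect_equal(pe$nmd_predicted,
                 (max(alt$junctions) - ptc_nt) > th$nmd_distance)
    expect_equal(pe$truncated, !pe$nmd_predicted)
  }
})
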