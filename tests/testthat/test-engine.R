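th <- thresholds()

test_that("signals are localized to features and matched to native sites", {
  t <- tx3("+")
  r <- rec_for(t, 450L, dl = c(0.5, 200L), dg = c(0.3, 450L))
  sig <- localize_signals(r, t, th)
  expect_equal(nrow(sig), 4L)
  dl <- sig[sig$kind == "donor_loss", ]
  expect_equal(dl$native_match_intron, 1L)
  dg <- sig[sig$kind == "donor_gain", ]
  expect_equal(dg$locus, "intron")
  expect_equal(dg$locus_index, 2L)

  r0 <- rec_for(t, 450L)
  expect_true(all(localize_signals(r0, t, th)$inert))
})

# intron 2 of this transcript is 401..1200 (800 bp), roomy enough for
# pseudoexon candidates of any tested size
tx_long_intron <- function() {
  transcript_model("G", "T1", "chr1", "+",
                   cbind(c(101L, 301L, 1201L), c(200L, 400L, 1300L)),
                   cds_start = 121L, cds_end = 1280L)
}

test_that("pseudoexon calls need a paired in-order gain within the size range", {
  t <- tx_long_intron()
  # acceptor gain 501, donor gain 601: 101 bases inclusive
  r <- rec_for(t, 550L, ag = c(0.30, 501L), dg = c(0.25, 601L))
  calls <- classify(r, t, th)
  expect_equal(calls$type, "pseudoexonization")
  expect_equal(calls$inserted_bp, 101L)
  expect_equal(calls$deleted_bp, 0L)

  # 600 bases apart: outside 25-500, no call at all
  r600 <- rec_for(t, 550L, ag = c(0.30, 501L), dg = c(0.25, 1100L))
  c600 <- classify(r600, t, th)
  expect_equal(c600$type, "no_impact")
  expect_match(attr(c600, "notes"), "outside", all = FALSE)

  # acceptor gain below the 0.05 gain threshold: pair does not form
  rlow <- rec_for(t, 550L, ag = c(0.04, 501L), dg = c(0.25, 601L))
  expect_equal(nrow(detect_pseudoexon(rlow, t, th)), 0L)

  # crossed order (donor 5' of acceptor) is not a pseudoexon
  rx <- rec_for(t, 550L, ag = c(0.30, 601L), dg = c(0.25, 501L))
  expect_equal(nrow(detect_pseudoexon(rx, t, th)), 0L)
})

test_that("exon skipping requires both native-site losses of one exon", {
  gt <- make_toy_gene(n_exons = 3, exon_lengths = c(120L, 164L, 150L),
                      intron_lengths = c(500L, 500L), seed = 2)
  t <- gt$transcript
  ns <- native_splice_sites(t)
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == 1L]
  don <- ns$pos[ns$kind == "donor" & ns$intron == 2L]
  vpos <- t$exons[2, "start"] + 80L
  r <- rec_for(t, vpos, al = c(0.9, acc), dl = c(0.8, don))
  calls <- classify(r, t, th)
  expect_equal(calls$type, "exon_skipping")
  expect_equal(calls$deleted_bp, 164L)

  # one loss below threshold: no skipping
  rlow <- rec_for(t, vpos, al = c(0.9, acc), dl = c(0.1, don))
  expect_equal(nrow(detect_exon_skipping(rlow, t, th)), 0L)
})

test_that("multi-exon skipping sums the skipped exon lengths", {
  gt <- make_toy_gene(n_exons = 7,
                      exon_lengths = c(100L, 100L, 100L, 100L, 90L, 120L, 100L),
                      intron_lengths = rep(400L, 6), seed = 2)
  t <- gt$transcript
  ns <- native_splice_sites(t)
  acc5 <- ns$pos[ns$kind == "acceptor" & ns$intron == 4L]  # acceptor of exon 5
  don6 <- ns$pos[ns$kind == "donor" & ns$intron == 6L]     # donor of exon 6
  iv <- splicefx:::intron_interval(t, 5L)
  vpos <- iv[1] + 200L
  r <- rec_for(t, vpos, al = c(0.9, acc5), dl = c(0.8, don6))
  calls <- classify(r, t, th)
  expect_equal(calls$type, "multi_exon_skipping")
  expect_equal(calls$deleted_bp, 90L + 120L)
  expect_equal(c(calls$from, calls$to), c(5L, 6L))

  # below-threshold donor loss: nothing fires
  rlow <- rec_for(t, vpos, al = c(0.9, acc5), dl = c(0.1, don6))
  expect_equal(nrow(detect_multi_exon_skipping(rlow, t, th)), 0L)

  # crossed losses (acceptor of exon 4, donor of exon 2): unresolved, no call
  acc4 <- ns$pos[ns$kind == "acceptor" & ns$intron == 3L]
  don2 <- ns$pos[ns$kind == "donor" & ns$intron == 2L]
  iv2 <- splicefx:::intron_interval(t, 3L)
  rx <- rec_for(t, iv2[1] + 100L, al = c(0.9, acc4), dl = c(0.8, don2))
  cx <- classify(rx, t, th)
  expect_equal(cx$type, "no_impact")
  expect_match(attr(cx, "notes"), "crossed", all = FALSE)
})

test_that("whole intron retention keeps the full intron between paired losses", {
  gt <- make_toy_gene(n_exons = 3, exon_lengths = c(120L, 150L, 150L),
                      intron_lengths = c(500L, 1000L), seed = 4)
  t <- gt$transcript
  ns <- native_splice_sites(t)
  don <- ns$pos[ns$kind == "donor" & ns$intron == 2L]
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == 2L]
  iv <- splicefx:::intron_interval(t, 2L)
  vpos <- iv[1] + 500L
  r <- rec_for(t, vpos, dl = c(0.5, don), al = c(0.4, acc))
  calls <- classify(r, t, th)
  expect_equal(calls$type, "whole_intron_retention")
  expect_equal(calls$inserted_bp, 1000L)

  # a lone strong donor loss falls through to an unresolved note
  rl <- rec_for(t, vpos, dl = c(0.5, don), al = c(0.1, acc))
  cl <- classify(rl, t, th)
  expect_equal(cl$type, "no_impact")
  expect_match(attr(cl, "notes"), "lone donor_loss", all = FALSE)
})

test_that("partial intron retention measures from the native splice site", {
  t <- tx3("+")
  # donor gain 88 bases into intron 2 (native donor at 400)
  r <- rec_for(t, 430L, dg = c(0.62, 488L))
  calls <- classify(r, t, th)
  expect_equal(calls$type, "partial_intron_retention")
  expect_equal(calls$inserted_bp, 88L)

  # acceptor gain 30 bases before the native acceptor (501), score 0.07
  r2 <- rec_for(t, 450L, ag = c(0.07, 471L))
  c2 <- classify(r2, t, th)
  expect_equal(c2$type, "partial_intron_retention")
  expect_equal(c2$inserted_bp, 30L)

  # a matching native-site loss is recorded as support, not required
  r3 <- rec_for(t, 430L, dg = c(0.62, 488L), dl = c(0.3, 400L))
  c3 <- classify(r3, t, th)
  expect_equal(c3$type, "partial_intron_retention")
  expect_match(c3$note, "supported")

  # donor gain inside an exon is partial exon deletion, not retention
  r4 <- rec_for(t, 380L, dg = c(0.62, 390L))
  expect_equal(nrow(detect_partial_intron_retention(r4, t, th)), 0L)
  expect_equal(classify(r4, t, th)$type, "partial_exon_deletion")
})

test_that("partial exon deletion sizes come from the annotated native site", {
  # exon 2 = 401..600 (200 bp), native donor at 600
  t <- transcript_model("G", "T1", "chr1", "+",
                        cbind(c(101L, 401L, 701L), c(250L, 600L, 850L)),
                        cds_start = 121L, cds_end = 820L)
  # cryptic donor 119 bases upstream of the native donor; a strong donor loss
  # sits 6 bp away from the native site (as a shifted predicted position
  # would) and must NOT be used as the size anchor
  r <- rec_for(t, 500L, dg = c(0.55, 600L - 119L), dl = c(0.9, 600L - 6L))
  calls <- classify(r, t, th)
  ped <- calls[calls$type == "partial_exon_deletion", ]
  expect_equal(nrow(ped), 1L)
  expect_equal(ped$deleted_bp, 119L)
  expect_false(identical(ped$deleted_bp, 125L))

  # gain exactly at the native site: degenerate, suppressed
  r0 <- rec_for(t, 500L, dg = c(0.55, 600L))
  expect_equal(nrow(detect_partial_exon_deletion(r0, t, th)), 0L)

  # below the gain threshold: no call
  rlow <- rec_for(t, 500L, dg = c(0.03, 481L))
  expect_equal(classify(rlow, t, th)$type, "no_impact")
})

test_that("classify composes allowed combinations and returns no_impact otherwise", {
  gt <- make_toy_gene(n_exons = 3, exon_lengths = c(120L, 164L, 150L),
                      intron_lengths = c(500L, 500L), seed = 2)
  t <- gt$transcript
  ns <- native_splice_sites(t)
  r0 <- rec_for(t, t$exons[2, "start"] + 5L)
  expect_equal(classify(r0, t, th)$type, "no_impact")

  # losses flanking exon 2 plus a donor gain in intron 1
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == 1L]
  don <- ns$pos[ns$kind == "donor" & ns$intron == 2L]
  don1 <- ns$pos[ns$kind == "donor" & ns$intron == 1L]
  r <- rec_for(t, t$exons[2, "start"] + 80L,
               al = c(0.9, acc), dl = c(0.8, don), dg = c(0.4, don1 + 88L))
  calls <- classify(r, t, th)
  expect_setequal(calls$type, c("exon_skipping", "partial_intron_retention"))
  expect_equal(sum(calls$deleted_bp), 164L)
  expect_equal(sum(calls$inserted_bp), 88L)
})

test_that("indistinguishable call pairs resolve by driving score, tie to retention", {
  t <- tx3("+")
  # acceptor gain inside exon 2 (deletion candidate) vs donor gain in intron
  # 2 (retention candidate)
  ped_gain <- c(0.30, 330L)   # 29 bp into exon 2 from acceptor 301
  pir_gain <- c(0.20, 450L)   # 50 bp into intron 2 from donor 400
  r <- rec_for(t, 380L, ag = ped_gain, dg = pir_gain)
  calls <- classify(r, t, th)
  expect_equal(calls$type, "partial_exon_deletion")
  expect_match(attr(calls, "notes"), "indistinguishable", all = FALSE)

  r2 <- rec_for(t, 380L, ag = c(0.20, 330L), dg = c(0.30, 450L))
  expect_equal(classify(r2, t, th)$type, "partial_intron_retention")

  r3 <- rec_for(t, 380L, ag = c(0.30, 330L), dg = c(0.30, 450L))
  expect_equal(classify(r3, t, th)$type, "partial_intron_retention")  # tie-break
})

test_that("calling thresholds are inclusive at the boundary", {
  t <- tx3("+")
  # gain threshold 0.05: 0.05 fires, 0.04 does not
  fires <- function(score) classify(rec_for(t, 430L, dg = c(score, 488L)), t, th)$type
  expect_equal(fires(0.05), "partial_intron_retention")
  expect_equal(fires(0.06), "partial_intron_retention")
  expect_equal(fires(0.04), "no_impact")

  gt <- make_toy_gene(n_exons = 3, exon_lengths = c(120L, 164L, 150L),
                      intron_lengths = c(500L, 500L), seed = 2)
  t2 <- gt$transcript
  ns <- native_splice_sites(t2)
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == 1L]
  don <- ns$pos[ns$kind == "donor" & ns$intron == 2L]
  skip_at <- function(s) {
    classify(rec_for(t2, t2$exons[2, "start"] + 80L,
                     al = c(s, acc), dl = c(s, don)), t2, th)$type
  }
  expect_equal(skip_at(0.20), "exon_skipping")
  expect_equal(skip_at(0.21), "exon_skipping")
  expect_equal(skip_at(0.19), "no_impact")
})

test_that("strand mirroring leaves call types and sizes unchanged", {
  for (ty in c("pseudoexonization", "partial_intron_retention",
               "partial_exon_deletion", "exon_skipping",
               "multi_exon_skipping", "whole_intron_retention")) {
    for (sd in 1:3) {
      cp <- forge_case(ty, list(strand = "+"), seed = sd)
      cm <- forge_case(ty, list(strand = "-"), seed = sd)
      kp <- classify(cp$record, cp$transcript, th)
      km <- classify(cm$record, cm$transcript, th)
      expect_equal(sort(kp$type), sort(km$type), info = paste(ty, sd))
      expect_equal(sum(kp$inserted_bp), sum(km$inserted_bp), info = paste(ty, sd))
      expect_equal(sum(kp$deleted_bp), sum(km$deleted_bp), info = paste(ty, sd))
    }
  }
})

test_that("random signal sets never violate structural call constraints", {
  gt <- make_toy_gene(n_exons = 5, seed = 31)
  t <- gt$transcript
  span <- c(t$exons[1, "start"] - 200L, t$exons[5, "end"] + 200L)
  set.seed(99)
  for (i in 1:800) {
    vpos <- sample(span[1]:span[2], 1)
    r <- spliceai_record(
      variant(t$contig, vpos, "A", "C"), t$gene_symbol,
      ds_ag = runif(1), ds_al = runif(1), ds_dg = runif(1), ds_dl = runif(1),
      dp_ag = sample(-4999:4999, 1), dp_al = sample(-4999:4999, 1),
      dp_dg = sample(-4999:4999, 1), dp_dl = sample(-4999:4999, 1)
    )
    calls <- classify(r, t, th)
    types <- calls$type
    for (pair in splicefx:::FORBIDDEN_PAIRS) {
      expect_false(all(pair %in% types))
    }
    if ("no_impact" %in% types) expect_equal(length(types), 1L)
    pe <- calls[calls$type == "pseudoexonization", ]
    if (nrow(pe)) expect_true(all(pe$inserted_bp >= 25L & pe$inserted_bp <= 500L))
  }
})
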