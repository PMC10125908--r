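# Shared hand-built fixtures and oracles.

# 3-exon plus/minus strand transcript with round coordinates; CDS 121-580.
tx3 <- function(strand = "+") {
  transcript_model("G", "T1", "chr1", strand,
                   cbind(c(101L, 301L, 501L), c(200L, 400L, 600L)),
                   cds_start = 121L, cds_end = 580L)
}

# Forge a record by genomic target positions: each signal is c(score, target).
rec_for <- function(t, vpos, ref = "A", alt = "G",
                    ag = NULL, al = NULL, dg = NULL, dl = NULL) {
  f <- function(x) {
    if (is.null(x)) list(score = 0, dp = 0L)
    else list(score = x[[1]], dp = as.integer(x[[2]] - vpos))
  }
  ag <- f(ag); al <- f(al); dg <- f(dg); dl <- f(dl)
  spliceai_record(variant(t$contig, vpos, ref, alt), t$gene_symbol,
                  ds_ag = ag$score, ds_al = al$score, ds_dg = dg$score, ds_dl = dl$score,
                  dp_ag = ag$dp, dp_al = al$dp, dp_dg = dg$dp, dp_dl = dl$dp)
}

parse_notation <- function(s) {
  m <- regmatches(s, regexec("^([A-Z]*)\\[([A-Z]*)(\\*?)\\]([A-Z]*)$", s))[[1]]
  if (length(m) == 0) return(NULL)
  list(anchor = m[2], novel = m[3], stopped = m[4] == "*", trail = m[5])
}

# wild-type and mutant proteins via the package's own transcript rebuild
protein_pair <- function(t, calls, genome) {
  alt <- apply_calls(t, calls, genome)
  list(
    wt = as.character(translate_cds(substring(alt$ref_mrna, alt$ref_cds_offset))),
    mut = as.character(translate_cds(substring(alt$mrna, alt$cds_offset)))
  )
}

# The notation, read as an edit script anchored at first_affected_codon,
# must reproduce the mutant protein from the wild type.
expect_notation_roundtrip <- function(wt, mut, notation, first_affected_codon) {
  nt <- parse_notation(notation)
  expect_false(is.null(nt), info = paste("unparseable notation:", notation))
  p <- first_affected_codon - 1L
  prefix <- substr(wt, 1L, p)
  expect_identical(substr(mut, 1L, p), prefix)
  expect_identical(nt$anchor, substr(wt, max(1L, p - 2L), p))
  if (nt$novel == "" && !nt$stopped) {
    # pure in-frame deletion: mutant = prefix + a wild-type suffix
    s <- nchar(mut) - p
    expect_identical(substring(mut, p + 1L), substring(wt, nchar(wt) - s + 1L))
    expect_identical(nt$trail, substr(wt, nchar(wt) - s + 1L,
                                      min(nchar(wt), nchar(wt) - s + 3L)))
  } else if (nt$stopped && nchar(nt$trail) == 0 &&
             identical(paste0(prefix, nt$novel), mut)) {
    # premature stop: mutant ends right after the novel residues
    expect_identical(paste0(prefix, nt$novel), mut)
  } else {
    # in-frame missense: prefix + novel + re-synchronized wild-type tail
    expect_identical(substr(mut, p + 1L, p + nchar(nt$novel)), nt$novel)
    tail_len <- nchar(mut) - p - nchar(nt$novel)
    if (tail_len > 0) {
      expect_identical(substring(mut, p + nchar(nt$novel) + 1L),
                       substring(wt, nchar(wt) - tail_len + 1L))
    }
  }
}
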