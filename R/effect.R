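revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Map genomic position -> 1-based mRNA coordinate over a segment matrix
# (genomic order) for the given strand; NA when not in any segment.
map_g2m <- function(segs, strand, gpos) {
  lens <- segs[, "end"] - segs[, "start"] + 1L
  if (strand == "+") {
    off <- c(0L, cumsum(lens))[seq_len(nrow(segs))]
    row <- which(gpos >= segs[, "start"] & gpos <= segs[, "end"])
    if (length(row) != 1) return(NA_integer_)
    off[row] + (gpos - segs[row, "start"]) + 1L
  } else {
    ord <- rev(seq_len(nrow(segs)))
    off <- c(0L, cumsum(lens[ord]))[seq_len(nrow(segs))]
    row <- which(gpos >= segs[, "start"] & gpos <= segs[, "end"])
    if (length(row) != 1) return(NA_integer_)
    k <- which(ord == row)
    off[k] + (segs[row, "end"] - gpos) + 1L
  }
}

segments_mrna <- function(genome, contig, segs, strand) {
  parts <- vapply(seq_len(nrow(segs)),
                  function(i) seq_at(genome, contig, segs[i, "start"], segs[i, "end"]),
                  character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") revcomp(s) else s
}

junctions_of <- function(segs, strand) {
  lens <- segs[, "end"] - segs[, "start"] + 1L
  if (strand == "-") lens <- rev(lens)
  if (length(lens) < 2) return(integer(0))
  cumsum(lens)[-length(lens)]
}

#' Apply aberration calls to a transcript
#'
#' Edits the exon segment list according to each call (pseudoexonization
#' inserts a segment, skipping removes exons, whole intron retention merges
#' the flanking exons across the intron, partial retention extends an exon
#' boundary into the intron, partial deletion trims an exon at the cryptic
#' site) and rebuilds the mature mRNA.
#'
#' @param t A [transcript_model()].
#' @param calls An `sfx_calls` tibble from [classify()] (or a compatible
#'   tibble).
#' @param genome A [genome_ref()] covering `t$contig`.
#' @return A list of class `sfx_altered`: `segments` (genomic-order matrix),
#'   `mrna` (spliced sequence, transcript strand), `junctions` (mRNA
#'   coordinates after which an exon-exon junction lies), `delta_len`
#'   (signed bp change vs the reference mRNA), `cds_offset` (mRNA coordinate
#'   of the first coding base, `NA` if lost), plus the reference equivalents
#'   `ref_mrna`, `ref_junctions`, `ref_cds_offset`.
#' @export
apply_calls <- function(t, calls, genome) {
  stopifnot(inherits(t, "transcript_model"), inherits(genome, "genome_ref"))
  calls <- as.data.frame(calls)
  n <- n_exons(t)
  segs <- cbind(start = t$exons[, "start"], end = t$exons[, "end"])
  keep <- rep(TRUE, n)
  inserts <- NULL
  plus <- t$strand == "+"

  for (ci in seq_len(nrow(calls))) {
    cl <- calls[ci, ]
    if (cl$type == "no_impact") next
    if (cl$feature == "exon" && (cl$from < 1 || cl$to > n)) {
      stop("apply_calls: call references exon outside the transcript", call. = FALSE)
    }
    if (cl$feature == "intron" && (cl$from < 1 || cl$to > n - 1)) {
      stop("apply_calls: call references intron outside the transcript", call. = FALSE)
    }
    switch(cl$type,
      pseudoexonization = {
        inserts <- rbind(inserts, c(start = cl$g1, end = cl$g2))
      },
      exon_skipping = ,
      multi_exon_skipping = {
        for (e in cl$from:cl$to) keep[genomic_exon_row(t, e)] <- FALSE
      },
      whole_intron_retention = {
        r1 <- genomic_exon_row(t, cl$from)
        r2 <- genomic_exon_row(t, cl$from + 1L)
        lo <- min(r1, r2); hi <- max(r1, r2)
        segs[lo, "end"] <- segs[hi, "end"]
        keep[hi] <- FALSE
      },
      partial_intron_retention = {
        if (cl$side == "donor") {
          row <- genomic_exon_row(t, cl$from)          # upstream exon extends
          if (plus) segs[row, "end"] <- cl$g1 else segs[row, "start"] <- cl$g1
        } else {
          row <- genomic_exon_row(t, cl$from + 1L)     # downstream exon extends
          if (plus) segs[row, "start"] <- cl$g1 else segs[row, "end"] <- cl$g1
        }
      },
      partial_exon_deletion = {
        row <- genomic_exon_row(t, cl$from)
        if (cl$side == "acceptor") {
          if (plus) segs[row, "start"] <- cl$g1 else segs[row, "end"] <- cl$g1
        } else {
          if (plus) segs[row, "end"] <- cl$g1 else segs[row, "start"] <- cl$g1
        }
      },
      stop("apply_calls: unknown call type '", cl$type, "'", call. = FALSE)
    )
  }

  segs <- segs[keep, , drop = FALSE]
  if (!is.null(inserts)) segs <- rbind(segs, inserts)
  segs <- segs[order(segs[, "start"]), , drop = FALSE]
  if (nrow(segs) == 0) stop("apply_calls: all segments removed", call. = FALSE)
  if (nrow(segs) > 1 && any(segs[-1, "start"] <= segs[-nrow(segs), "end"])) {
    stop("apply_calls: resulting segments overlap", call. = FALSE)
  }

  ref_segs <- cbind(start = t$exons[, "start"], end = t$exons[, "end"])
  mrna <- segments_mrna(genome, t$contig, segs, t$strand)
  ref_mrna <- segments_mrna(genome, t$contig, ref_segs, t$strand)

  cds_first <- if (!has_cds(t)) NA_integer_ else if (plus) t$cds_start else t$cds_end
  structure(
    list(
      segments = segs,
      mrna = mrna,
      junctions = junctions_of(segs, t$strand),
      delta_len = nchar(mrna) - nchar(ref_mrna),
      cds_offset = if (is.na(cds_first)) NA_integer_ else map_g2m(segs, t$strand, cds_first),
      ref_mrna = ref_mrna,
      ref_junctions = junctions_of(ref_segs, t$strand),
      ref_cds_offset = if (is.na(cds_first)) NA_integer_ else map_g2m(ref_segs, t$strand, cds_first)
    ),
    class = "sfx_altered"
  )
}

#' Reading-frame effect of a net length change
#'
#' @param delta_len Signed bp change of the mature transcript.
#' @return `"in_frame"` when `delta_len` is a multiple of 3, else
#'   `"frameshift"`.
#' @export
frame_effect <- function(delta_len) {
  ifelse(delta_len %% 3L == 0L, "in_frame", "frameshift")
}

#' Translate a coding sequence
#'
#' Standard genetic code, starting at the first base of `cds_sequence` and
#' stopping at (and consuming) the first stop codon. Codons containing `N`
#' translate to `X`. A trailing incomplete codon is ignored and flagged.
#'
#' @param cds_sequence Nucleotide string beginning at the start codon.
#' @return The amino-acid string, with attributes `terminated` (a stop codon
#'   was reached) and `incomplete_tail` (1-2 trailing bases were dropped).
#' @export
translate_cds <- function(cds_sequence) {
  s <- toupper(cds_sequence)
  if (nchar(s) == 0) stop("translate_cds: empty sequence", call. = FALSE)
  n_cod <- nchar(s) %/% 3L
  incomplete <- nchar(s) %% 3L != 0L
  if (n_cod == 0) {
    out <- ""
    attr(out, "terminated") <- FALSE
    attr(out, "incomplete_tail") <- TRUE
    return(out)
  }
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  terminated <- length(stop_at) > 0
  if (terminated) aa <- aa[seq_len(stop_at[1] - 1L)]
  out <- paste(aa, collapse = "")
  attr(out, "terminated") <- terminated
  attr(out, "incomplete_tail") <- incomplete && !terminated
  out
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(a, "")[[1]][1:n]
  bv <- strsplit(b, "")[[1]][1:n]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

common_suffix_len <- function(a, b, max_len) {
  n <- min(nchar(a), nchar(b), max_len)
  if (n <= 0) return(0L)
  av <- rev(strsplit(a, "")[[1]])[1:n]
  bv <- rev(strsplit(b, "")[[1]])[1:n]
  d <- which(av != bv)
  if (length(d) == 0) n else d[1] - 1L
}

#' Bracketed amino-acid change notation
#'
#' Serializes the difference between the wild-type and altered protein: up
#' to three wild-type residues preceding the first changed residue, then the
#' novel residues inside square brackets. For frameshifts (and premature
#' stops) the bracket runs to the new stop, printed as `*` inside the
#' brackets. For in-frame events the bracket closes where the altered
#' sequence re-synchronizes with the wild type; a pure in-frame deletion
#' with no missense change serializes as blank brackets flanked by three
#' wild-type residues on each side. Deleted residues are never shown.
#' Identical proteins give `"."`.
#'
#' @param wt_protein,mut_protein Amino-acid strings from the same start
#'   codon (no stop characters).
#' @param frameshift Is the altered protein out of frame at the divergence
#'   point?
#' @param premature_stop Did the altered protein terminate before the native
#'   stop (PTC)?
#' @param terminated Did translation of the altered protein reach any stop
#'   codon?
#' @param first_affected_codon Optional override of the divergence codon
#'   index (1-based); computed from the longest common prefix by default.
#' @return The notation string, with attribute `first_affected_codon`.
#' @export
format_notation <- function(wt_protein, mut_protein, frameshift = FALSE,
                            premature_stop = frameshift, terminated = TRUE,
                            first_affected_codon = NULL) {
  wt <- as.character(wt_protein)
  mut <- as.character(mut_protein)
  if (identical(wt, mut)) {
    out <- "."
    attr(out, "first_affected_codon") <- NA_integer_
    return(out)
  }
  p <- if (is.null(first_affected_codon)) common_prefix_len(wt, mut)
       else as.integer(first_affected_codon) - 1L
  anchor <- substr(wt, max(1L, p - 2L), p)
  if (frameshift || premature_stop) {
    novel <- substring(mut, p + 1L)
    out <- paste0(anchor, "[", novel, if (terminated) "*", "]")
  } else {
    s <- common_suffix_len(wt, mut, max_len = min(nchar(wt), nchar(mut)) - p)
    novel <- substr(mut, p + 1L, nchar(mut) - s)
    if (nchar(novel) == 0) {
      trail <- substr(wt, nchar(wt) - s + 1L, min(nchar(wt), nchar(wt) - s + 3L))
      out <- paste0(anchor, "[]", trail)
    } else {
      out <- paste0(anchor, "[", novel, "]")
    }
  }
  attr(out, "first_affected_codon") <- p + 1L
  out
}

#' Nonsense-mediated decay prediction (50-nt rule)
#'
#' A premature termination codon is predicted to trigger NMD when it lies
#' more than `nmd_distance` nucleotides upstream of the last exon-exon
#' junction of the altered transcript; a PTC in the last exon, or within
#' `nmd_distance` nt of the final junction, predicts a truncated protein
#' instead.
#'
#' @param ptc_nt_pos 1-based mRNA coordinate of the first base of the stop
#'   codon.
#' @param junction_offsets mRNA coordinates after which each exon-exon
#'   junction lies (see [apply_calls()]).
#' @param nmd_distance Boundary distance in nt (default 50).
#' @return Logical flag.
#' @export
nmd_predict <- function(ptc_nt_pos, junction_offsets, nmd_distance = 50L) {
  if (length(junction_offsets) == 0) return(FALSE)
  (max(junction_offsets) - ptc_nt_pos) > nmd_distance
}

codon_genomic_positions <- function(t, mrna_from, n_nt = 3L) {
  ref_segs <- cbind(start = t$exons[, "start"], end = t$exons[, "end"])
  vapply(seq_len(n_nt) - 1L, function(k) map_m2g(ref_segs, t$strand, mrna_from + k), integer(1))
}

# Inverse of map_g2m.
map_m2g <- function(segs, strand, mpos) {
  lens <- segs[, "end"] - segs[, "start"] + 1L
  ord <- if (strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  off <- 0L
  for (row in ord) {
    if (mpos <= off + lens[row]) {
      within <- mpos - off
      return(if (strand == "+") segs[row, "start"] + within - 1L
             else segs[row, "end"] - within + 1L)
    }
    off <- off + lens[row]
  }
  NA_integer_
}

#' Protein-level consequence of aberration calls
#'
#' Rebuilds the altered transcript, translates the altered coding sequence,
#' and reports the reading-frame effect, the bracketed change notation, the
#' premature-termination status and the NMD flag. Prediction is suppressed
#' (with a note) when the transcript has no CDS or when a call disrupts the
#' annotated start or stop codon.
#'
#' @param t A [transcript_model()].
#' @param calls Calls tibble from [classify()].
#' @param genome A [genome_ref()].
#' @param th [thresholds()] (supplies `nmd_distance`).
#' @return A one-row tibble: `frame`, `delta_len`, `notation`,
#'   `first_affected_codon`, `ptc_codon`, `nmd_predicted`, `truncated`,
#'   `protein_note`.
#' @export
predict_protein_effect <- function(t, calls, genome, th = thresholds()) {
  effectless <- all(calls$type == "no_impact")
  alt <- apply_calls(t, calls, genome)
  base <- tibble::tibble(
    frame = if (effectless) "none" else frame_effect(alt$delta_len),
    delta_len = alt$delta_len,
    notation = ".",
    first_affected_codon = NA_integer_,
    ptc_codon = NA_integer_,
    nmd_predicted = FALSE,
    truncated = FALSE,
    protein_note = NA_character_
  )
  if (!has_cds(t)) {
    base$notation <- NA_character_
    base$protein_note <- "no CDS: protein prediction disabled"
    return(base)
  }
  if (effectless) return(base)

  # start / stop codon integrity in the altered transcript
  start_g <- codon_genomic_positions(t, t_cds_offset(t), 3L)
  stop_g <- codon_genomic_positions(t, t_cds_offset(t) + cds_genomic_length(t) - 3L, 3L)
  m_start <- vapply(start_g, function(g) map_g2m(alt$segments, t$strand, g), integer(1))
  m_stop <- vapply(stop_g, function(g) map_g2m(alt$segments, t$strand, g), integer(1))
  if (any(is.na(m_start)) || any(diff(m_start) != 1L)) {
    base$notation <- NA_character_
    base$protein_note <- "start codon disrupted: protein prediction suppressed"
    return(base)
  }
  if (any(is.na(m_stop)) || any(diff(m_stop) != 1L)) {
    base$notation <- NA_character_
    base$protein_note <- "stop codon disrupted: protein prediction suppressed"
    return(base)
  }

  wt <- translate_cds(substring(alt$ref_mrna, alt$ref_cds_offset))
  mut <- translate_cds(substring(alt$mrna, alt$cds_offset))
  terminated <- isTRUE(attr(mut, "terminated"))
  mut_stop_nt <- alt$cds_offset + 3L * nchar(mut)      # first nt of the stop codon
  premature <- terminated && mut_stop_nt < m_stop[1]

  fshift <- alt$delta_len %% 3L != 0L
  base$notation <- as.character(
    nt <- format_notation(as.character(wt), as.character(mut),
                          frameshift = fshift, premature_stop = premature,
                          terminated = terminated)
  )
  base$first_affected_codon <- attr(nt, "first_affected_codon")
  if (premature) {
    base$ptc_codon <- nchar(mut) + 1L
    base$nmd_predicted <- nmd_predict(mut_stop_nt, alt$junctions, th$nmd_distance)
    base$truncated <- !base$nmd_predicted
  }
  if (!terminated) base$protein_note <- "no stop codon found in altered transcript"
  base
}

# mRNA coordinate (reference transcript) of the first coding base.
t_cds_offset <- function(t) {
  segs <- cbind(start = t$exons[, "start"], end = t$exons[, "end"])
  cds_first <- if (t$strand == "+") t$cds_start else t$cds_end
  map_g2m(segs, t$strand, cds_first)
}
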