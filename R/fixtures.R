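# Seeded evaluation that never disturbs the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

NONSTOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                          names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])

stamp <- function(s, at, what) {
  substr(s, at, at + nchar(what) - 1L) <- what
  s
}

#' Generate a toy gene: random genome plus a consistent transcript model
#'
#' Builds a random ACGT contig containing one multi-exon gene with GT/AG
#' dinucleotides at every intron boundary, an ATG at the CDS start, a stop
#' codon at the CDS end, and no in-frame internal stop in the reference
#' coding sequence. Deterministic for a given seed. Minus-strand genes are
#' generated on the plus strand and then mirrored (reverse-complemented
#' contig, remapped coordinates), so both strands exercise identical
#' geometry.
#'
#' @param n_exons Number of exons (>= 1).
#' @param exon_len_range,intron_len_range Inclusive bp ranges to draw
#'   feature lengths from. Fixed lengths can be forced by passing
#'   `exon_lengths` / `intron_lengths`.
#' @param exon_lengths,intron_lengths Optional explicit length vectors
#'   (override the ranges).
#' @param utr5_len 5' UTR length inside exon 1 (transcript orientation).
#' @param flank Plain genomic flank on each side of the gene.
#' @param strand `"+"` or `"-"`.
#' @param contig,gene,tx Names used in the emitted model.
#' @param seed Optional integer seed.
#' @return A list with elements `genome` ([genome_ref()]) and `transcript`
#'   ([transcript_model()]).
#' @export
make_toy_gene <- function(n_exons = 3, exon_len_range = c(90, 210),
                          intron_len_range = c(300, 1200),
                          exon_lengths = NULL, intron_lengths = NULL,
                          utr5_len = 21L, flank = 300L, strand = "+",
                          contig = "chrT", gene = "GENE1", tx = "NM_000001.1",
                          seed = NULL) {
  with_seed(seed, {
    n_exons <- as.integer(n_exons)
    if (n_exons < 1) stop("make_toy_gene: n_exons must be >= 1", call. = FALSE)
    if (is.null(exon_lengths)) {
      if (any(exon_len_range < 30)) stop("make_toy_gene: exons must be >= 30 bp", call. = FALSE)
      exon_lengths <- sample(exon_len_range[1]:exon_len_range[2], n_exons, replace = TRUE)
    }
    if (is.null(intron_lengths)) {
      if (n_exons > 1 && any(intron_len_range < 20)) {
        stop("make_toy_gene: introns must be >= 20 bp", call. = FALSE)
      }
      intron_lengths <- if (n_exons > 1) {
        sample(intron_len_range[1]:intron_len_range[2], n_exons - 1L, replace = TRUE)
      } else integer(0)
    }
    exon_lengths <- as.integer(exon_lengths)
    intron_lengths <- as.integer(intron_lengths)
    stopifnot(length(exon_lengths) == n_exons, length(intron_lengths) == n_exons - 1L)
    if (any(exon_lengths < 30) || (n_exons > 1 && any(intron_lengths < 20))) {
      stop("make_toy_gene: infeasible feature lengths", call. = FALSE)
    }

    total_exonic <- sum(exon_lengths)
    utr5_len <- as.integer(utr5_len)
    if (utr5_len < 0 || utr5_len > exon_lengths[1] - 30L) {
      stop("make_toy_gene: utr5_len incompatible with exon 1", call. = FALSE)
    }
    # choose a 3' UTR so the CDS is a whole number of codons and the stop
    # codon sits fully inside the last exon
    utr3_len <- 15L + (total_exonic - utr5_len - 15L) %% 3L
    cds_len <- total_exonic - utr5_len - utr3_len
    if (cds_len < 30L || utr3_len > exon_lengths[n_exons] - 30L) {
      stop("make_toy_gene: geometry leaves no room for a CDS", call. = FALSE)
    }

    # genomic layout on the plus strand
    starts <- integer(n_exons); ends <- integer(n_exons)
    cursor <- flank + 1L
    for (e in seq_len(n_exons)) {
      starts[e] <- cursor
      ends[e] <- cursor + exon_lengths[e] - 1L
      cursor <- ends[e] + 1L + (if (e < n_exons) intron_lengths[e] else 0L)
    }
    glen <- ends[n_exons] + flank
    seq <- random_dna(glen)

    # splice dinucleotides
    for (e in seq_len(n_exons - 1L)) {
      seq <- stamp(seq, ends[e] + 1L, "GT")
      seq <- stamp(seq, starts[e + 1L] - 2L, "AG")
    }

    # write the CDS: ATG + non-stop codons + TAA, laid across exons
    codons <- c("ATG", sample(NONSTOP_CODONS, cds_len %/% 3L - 2L, replace = TRUE), "TAA")
    cds_seq <- paste(codons, collapse = "")
    exonic_pos <- unlist(lapply(seq_len(n_exons), function(e) starts[e]:ends[e]))
    cds_pos <- exonic_pos[(utr5_len + 1L):(utr5_len + cds_len)]
    cds_chars <- strsplit(cds_seq, "")[[1]]
    seq_chars <- strsplit(seq, "")[[1]]
    seq_chars[cds_pos] <- cds_chars
    seq <- paste(seq_chars, collapse = "")

    t <- transcript_model(gene, tx, contig, "+", cbind(starts, ends),
                          cds_start = cds_pos[1], cds_end = cds_pos[cds_len])
    g <- genome_ref(stats::setNames(list(seq), contig))
    out <- list(genome = g, transcript = t)
    if (strand == "-") out <- mirror_gene(out)
    out
  })
}

# Reverse-complement the contig and remap all transcript coordinates, turning
# a plus-strand gene into the equivalent minus-strand gene.
mirror_gene <- function(gt) {
  t <- gt$transcript
  seq <- gt$genome$contigs[[t$contig]]
  L <- nchar(seq)
  mp <- function(p) L - p + 1L
  exons <- cbind(start = mp(t$exons[, "end"]), end = mp(t$exons[, "start"]))
  t2 <- transcript_model(t$gene_symbol, t$transcript_id, t$contig,
                         if (t$strand == "+") "-" else "+", exons,
                         cds_start = if (has_cds(t)) mp(t$cds_end) else NA_integer_,
                         cds_end = if (has_cds(t)) mp(t$cds_start) else NA_integer_)
  g2 <- genome_ref(stats::setNames(list(revcomp(seq)), t$contig))
  list(genome = g2, transcript = t2)
}

FORGE_TYPES <- c(
  "pseudoexonization", "partial_intron_retention", "partial_exon_deletion",
  "exon_skipping", "multi_exon_skipping", "whole_intron_retention",
  "combination", "window_limited", "negative"
)

round2 <- function(x) round(x, 2)

# Draw an active score comfortably above a threshold, on the 2-decimal grid
# that SpliceAI VCFs print.
active_score <- function(threshold) round2(stats::runif(1, min(threshold + 0.05, 0.9), 0.98))

noise_score <- function() round2(stats::runif(1, 0, 0.01))

#' Forge a fixture case with by-construction ground truth
#'
#' Builds a toy gene and places SpliceAI delta scores/positions so that
#' exactly the requested aberration (or no call) is the ground truth. The
#' truth is derived from the generation parameters, never from the calling
#' engine.
#'
#' @param aberration_type One of `"pseudoexonization"`,
#'   `"partial_intron_retention"`, `"partial_exon_deletion"`,
#'   `"exon_skipping"`, `"multi_exon_skipping"`,
#'   `"whole_intron_retention"`, `"combination"` (exon skipping plus partial
#'   intron retention), `"window_limited"` (a lone native-site loss whose
#'   partner site is beyond the analysis window) or `"negative"`.
#' @param params Optional list of type-specific overrides: `size` (bp, for
#'   pseudoexon/partial types), `side` (`"donor"`/`"acceptor"`), `exon` /
#'   `exons` / `intron` (transcript-orientation indices), `strand`,
#'   `inframe_clean` (exon skipping aligned to codon boundaries, for
#'   blank-bracket notation), and naming overrides `contig`/`gene`/`tx`.
#' @param seed Optional integer seed (recorded in the case).
#' @param th [thresholds()] the truth should be valid under.
#' @return A list of class `sfx_case`: `genome`, `transcript`, `record`,
#'   `truth` (list: `types`, `inserted_bp`, `deleted_bp`, `delta_len`,
#'   `frame`, `notation_class`, `spliceogenic`), `seed`.
#' @export
forge_case <- function(aberration_type, params = list(), seed = NULL, th = thresholds()) {
  aberration_type <- match.arg(aberration_type, FORGE_TYPES)
  with_seed(seed, {
    p <- params
    strand <- p$strand %||% "+"
    nm <- list(contig = p$contig %||% "chrT", gene = p$gene %||% "GENE1",
               tx = p$tx %||% "NM_000001.1")

    case <- switch(aberration_type,
      pseudoexonization = forge_pseudoexon(p, strand, nm, th),
      partial_intron_retention = forge_pir(p, strand, nm, th),
      partial_exon_deletion = forge_ped(p, strand, nm, th),
      exon_skipping = forge_skip(p, strand, nm, th),
      multi_exon_skipping = forge_multi_skip(p, strand, nm, th),
      whole_intron_retention = forge_wir(p, strand, nm, th),
      combination = forge_combination(p, strand, nm, th),
      window_limited = forge_window_limited(p, strand, nm, th),
      negative = forge_negative(p, strand, nm, th)
    )
    case$seed <- seed
    case$category <- aberration_type
    class(case) <- "sfx_case"
    case
  })
}

# helper: default gene for forging (5 exons, roomy introns)
forge_gene <- function(p, strand, nm, n_exons = 5,
                       exon_lengths = NULL, intron_lengths = NULL) {
  make_toy_gene(
    n_exons = n_exons,
    exon_len_range = p$exon_len_range %||% c(90, 210),
    intron_len_range = p$intron_len_range %||% c(600, 1400),
    exon_lengths = exon_lengths, intron_lengths = intron_lengths,
    strand = strand, contig = nm$contig, gene = nm$gene, tx = nm$tx
  )
}

# Pick a variant position and return a forged record with the four signals;
# positions are genomic, dp is genome-forward (target - variant position).
forge_record <- function(gt, vpos, ag = NULL, al = NULL, dg = NULL, dl = NULL) {
  g <- gt$genome; t <- gt$transcript
  ref <- seq_at(g, t$contig, vpos, vpos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  sig <- function(x, fallback_dp) {
    if (is.null(x)) list(score = noise_score(), dp = fallback_dp) else x
  }
  # inert signals get an arbitrary in-window dp
  ag <- sig(ag, sample(-50:50, 1)); al <- sig(al, sample(-50:50, 1))
  dg <- sig(dg, sample(-50:50, 1)); dl <- sig(dl, sample(-50:50, 1))
  spliceai_record(
    variant(t$contig, vpos, ref, alt), t$gene_symbol,
    ds_ag = ag$score, ds_al = al$score, ds_dg = dg$score, ds_dl = dl$score,
    dp_ag = ag$dp, dp_al = al$dp, dp_dg = dg$dp, dp_dl = dl$dp
  )
}

at <- function(score, target_pos, vpos) list(score = score, dp = target_pos - vpos)

truth_of <- function(types, inserted, deleted, notation_class = "changed") {
  delta <- sum(inserted) - sum(deleted)
  spliceo <- !identical(types, "no_impact")
  list(
    types = sort(types), inserted_bp = as.integer(sum(inserted)),
    deleted_bp = as.integer(sum(deleted)), delta_len = as.integer(delta),
    frame = if (!spliceo) "none" else if (delta %% 3 == 0) "in_frame" else "frameshift",
    notation_class = if (!spliceo) "none" else notation_class,
    spliceogenic = spliceo
  )
}

forge_pseudoexon <- function(p, strand, nm, th) {
  size <- as.integer(p$size %||% sample(th$pseudoexon_min_bp:min(th$pseudoexon_max_bp, 400L), 1))
  gt <- forge_gene(p, strand, nm, intron_lengths = p$intron_lengths %||%
                     pmax(rep(700L, 4), size + 80L))
  t <- gt$transcript
  i <- as.integer(p$intron %||% 2L)
  iv <- intron_interval(t, i)            # genomic order
  s <- strand_sign(t$strand)
  # acceptor 5' of donor in transcript orientation, >= 20 bp off the boundaries
  if (t$strand == "+") { a <- iv[1] + 20L; d <- a + size - 1L } else { a <- iv[2] - 20L; d <- a - size + 1L }
  stopifnot(d >= iv[1] + 2L, d <= iv[2] - 2L, a >= iv[1] + 2L, a <= iv[2] - 2L)
  vpos <- a + s * (size %/% 2L)
  sc_a <- p$score_ag %||% active_score(th$gain_call_threshold)
  sc_d <- p$score_dg %||% active_score(th$gain_call_threshold)
  rec <- forge_record(gt, vpos, ag = at(sc_a, a, vpos), dg = at(sc_d, d, vpos))
  in_range <- size >= th$pseudoexon_min_bp && size <= th$pseudoexon_max_bp
  called <- in_range && sc_a >= th$gain_call_threshold && sc_d >= th$gain_call_threshold
  truth <- if (called) truth_of("pseudoexonization", size, 0L) else truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

forge_pir <- function(p, strand, nm, th) {
  size <- as.integer(p$size %||% sample(20:300, 1))
  gt <- forge_gene(p, strand, nm, intron_lengths = pmax(rep(700L, 4), size + 80L))
  t <- gt$transcript
  i <- as.integer(p$intron %||% 2L)
  side <- p$side %||% sample(c("donor", "acceptor"), 1)
  ns <- native_splice_sites(t)
  s <- strand_sign(t$strand)
  anchor <- ns$pos[ns$kind == side & ns$intron == i]
  gpos <- if (side == "donor") anchor + s * size else anchor - s * size
  vpos <- gpos - s * min(size - 1L, 10L)
  sc <- p$score %||% active_score(th$gain_call_threshold)
  rec <- if (side == "donor") {
    forge_record(gt, vpos, dg = at(sc, gpos, vpos))
  } else {
    forge_record(gt, vpos, ag = at(sc, gpos, vpos))
  }
  called <- sc >= th$gain_call_threshold
  truth <- if (called) truth_of("partial_intron_retention", size, 0L)
           else truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

forge_ped <- function(p, strand, nm, th) {
  gt <- forge_gene(p, strand, nm, exon_lengths = p$exon_lengths %||% rep(180L, 5))
  t <- gt$transcript
  e <- as.integer(p$exon %||% 3L)
  elen <- exon_lengths(t)[genomic_exon_row(t, e)]
  size <- as.integer(p$size %||% sample(10:(elen - 10L), 1))
  stopifnot(size >= 1, size <= elen - 2L)
  side <- p$side %||% sample(c("donor", "acceptor"), 1)
  ns <- native_splice_sites(t)
  s <- strand_sign(t$strand)
  # exon e: native acceptor closes intron e-1, native donor opens intron e
  gpos <- if (side == "acceptor") {
    ns$pos[ns$kind == "acceptor" & ns$intron == e - 1L] + s * size
  } else {
    ns$pos[ns$kind == "donor" & ns$intron == e] - s * size
  }
  vpos <- gpos + s * min(5L, elen - size - 1L) * (if (side == "acceptor") 1L else -1L)
  sc <- p$score %||% active_score(th$gain_call_threshold)
  rec <- if (side == "acceptor") {
    forge_record(gt, vpos, ag = at(sc, gpos, vpos))
  } else {
    forge_record(gt, vpos, dg = at(sc, gpos, vpos))
  }
  called <- sc >= th$gain_call_threshold
  truth <- if (called) truth_of("partial_exon_deletion", 0L, size)
           else truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

skip_geometry <- function(p, strand, nm, inframe_clean = FALSE) {
  if (inframe_clean) {
    # exon 3 length divisible by 3 and preceded by a codon-aligned CDS chunk:
    # utr5 21, exon1 120 (99 coding), exon2 150, exon3 153 -> all aligned
    forge_gene(p, strand, nm, exon_lengths = c(120L, 150L, 153L, 150L, 120L))
  } else {
    forge_gene(p, strand, nm)
  }
}

forge_skip <- function(p, strand, nm, th) {
  inframe_clean <- isTRUE(p$inframe_clean)
  gt <- skip_geometry(p, strand, nm, inframe_clean)
  t <- gt$transcript
  e <- as.integer(p$exon %||% 3L)
  ns <- native_splice_sites(t)
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == e - 1L]
  don <- ns$pos[ns$kind == "donor" & ns$intron == e]
  row <- genomic_exon_row(t, e)
  vpos <- t$exons[row, "start"] + exon_lengths(t)[row] %/% 2L
  sc_a <- p$score_al %||% active_score(th$loss_call_threshold)
  sc_d <- p$score_dl %||% active_score(th$loss_call_threshold)
  rec <- forge_record(gt, vpos, al = at(sc_a, acc, vpos), dl = at(sc_d, don, vpos))
  called <- sc_a >= th$loss_call_threshold && sc_d >= th$loss_call_threshold
  elen <- exon_lengths(t)[row]
  truth <- if (called) {
    truth_of("exon_skipping", 0L, elen,
             notation_class = if (inframe_clean) "blank_brackets" else "changed")
  } else truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

forge_multi_skip <- function(p, strand, nm, th) {
  gt <- forge_gene(p, strand, nm, intron_lengths = rep(500L, 4))
  t <- gt$transcript
  ee <- as.integer(p$exons %||% c(3L, 4L))
  e1 <- ee[1]; e2 <- ee[2]
  ns <- native_splice_sites(t)
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == e1 - 1L]
  don <- ns$pos[ns$kind == "donor" & ns$intron == e2]
  iv <- intron_interval(t, e1)          # variant in the intron between e1 and e1+1
  vpos <- iv[1] + (iv[2] - iv[1]) %/% 2L
  stopifnot(abs(acc - vpos) <= DP_WINDOW, abs(don - vpos) <= DP_WINDOW)
  sc_a <- p$score_al %||% active_score(th$loss_call_threshold)
  sc_d <- p$score_dl %||% active_score(th$loss_call_threshold)
  rec <- forge_record(gt, vpos, al = at(sc_a, acc, vpos), dl = at(sc_d, don, vpos))
  called <- sc_a >= th$loss_call_threshold && sc_d >= th$loss_call_threshold
  rows <- vapply(e1:e2, function(e) genomic_exon_row(t, e), integer(1))
  truth <- if (called) truth_of("multi_exon_skipping", 0L, sum(exon_lengths(t)[rows]))
           else truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

forge_wir <- function(p, strand, nm, th) {
  gt <- forge_gene(p, strand, nm)
  t <- gt$transcript
  i <- as.integer(p$intron %||% 2L)
  ns <- native_splice_sites(t)
  don <- ns$pos[ns$kind == "donor" & ns$intron == i]
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == i]
  iv <- intron_interval(t, i)
  vpos <- iv[1] + (iv[2] - iv[1]) %/% 2L
  sc_a <- p$score_al %||% active_score(th$loss_call_threshold)
  sc_d <- p$score_dl %||% active_score(th$loss_call_threshold)
  rec <- forge_record(gt, vpos, al = at(sc_a, acc, vpos), dl = at(sc_d, don, vpos))
  called <- sc_a >= th$loss_call_threshold && sc_d >= th$loss_call_threshold
  truth <- if (called) truth_of("whole_intron_retention", intron_length(t, i), 0L)
           else truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

# exon skipping of exon e plus a donor-side partial retention of intron 1:
# losses flank exon e, the donor gain extends exon 1 into its intron, so the
# two aberrations touch distinct features and compose cleanly.
forge_combination <- function(p, strand, nm, th) {
  gt <- forge_gene(p, strand, nm, intron_lengths = rep(800L, 4))
  t <- gt$transcript
  e <- as.integer(p$exon %||% 3L)
  size <- as.integer(p$size %||% sample(30:200, 1))
  ns <- native_splice_sites(t)
  s <- strand_sign(t$strand)
  acc <- ns$pos[ns$kind == "acceptor" & ns$intron == e - 1L]
  don <- ns$pos[ns$kind == "donor" & ns$intron == e]
  gpos <- ns$pos[ns$kind == "donor" & ns$intron == 1L] + s * size  # cryptic donor in intron 1
  row <- genomic_exon_row(t, e)
  vpos <- t$exons[row, "start"] + exon_lengths(t)[row] %/% 2L
  rec <- forge_record(
    gt, vpos,
    al = at(active_score(th$loss_call_threshold), acc, vpos),
    dl = at(active_score(th$loss_call_threshold), don, vpos),
    dg = at(active_score(th$gain_call_threshold), gpos, vpos)
  )
  elen <- exon_lengths(t)[row]
  truth <- truth_of(c("exon_skipping", "partial_intron_retention"), size, elen)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

# A strong donor loss at the native donor of a >10 kb intron: the partner
# acceptor lies beyond the analysis window, so no aberration is callable and
# the record is flagged unresolved/window-limited.
forge_window_limited <- function(p, strand, nm, th) {
  gt <- forge_gene(p, strand, nm, intron_lengths = c(700L, 10500L, 700L, 700L))
  t <- gt$transcript
  ns <- native_splice_sites(t)
  don <- ns$pos[ns$kind == "donor" & ns$intron == 2L]
  s <- strand_sign(t$strand)
  vpos <- don + s * 20L                # deep in the long intron, near its donor
  rec <- forge_record(gt, vpos, dl = at(active_score(th$loss_call_threshold), don, vpos))
  truth <- truth_of("no_impact", 0L, 0L)
  truth$window_limited_note <- TRUE
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

forge_negative <- function(p, strand, nm, th) {
  gt <- forge_gene(p, strand, nm)
  t <- gt$transcript
  row <- genomic_exon_row(t, 2L)
  vpos <- t$exons[row, "start"] + 10L
  rec <- forge_record(gt, vpos)        # all four scores below the noise floor
  truth <- truth_of("no_impact", 0L, 0L)
  list(genome = gt$genome, transcript = t, record = rec, truth = truth)
}

#' Build a balanced forged-fixture corpus
#'
#' Generates `n_per_type` cases for each category: the six aberration types,
#' a combination case (exon skipping plus partial intron retention), a
#' window-limited case, and negatives. Deterministic for a given seed.
#'
#' @param seed Integer seed.
#' @param n_per_type Cases per category (>= 1).
#' @param strands Strands to alternate across cases.
#' @param th [thresholds()] the truths should be valid under.
#' @return A list of class `sfx_corpus`: `cases` (list of `sfx_case`) and
#'   `labels` (tibble: `case_id`, `category`, `contig`, `pos`, `ref`, `alt`,
#'   `gene`, `transcript`, `truth_types`, `inserted_bp`, `deleted_bp`,
#'   `frame`, `spliceogenic`).
#' @export
build_corpus <- function(seed = 1L, n_per_type = 5L, strands = c("+", "-"),
                         th = thresholds()) {
  stopifnot(n_per_type >= 1)
  with_seed(seed, {
    cases <- list()
    k <- 0L
    for (type in FORGE_TYPES) {
      for (j in seq_len(n_per_type)) {
        k <- k + 1L
        params <- list(
          strand = strands[(j - 1L) %% length(strands) + 1L],
          contig = sprintf("chrT%03d", k),
          gene = sprintf("G%03d", k),
          tx = sprintf("NM_%06d.1", k)
        )
        case_seed <- sample.int(.Machine$integer.max, 1)
        cases[[k]] <- forge_case(type, params, seed = case_seed, th = th)
        cases[[k]]$case_id <- sprintf("case%03d", k)
      }
    }
    labels <- dplyr::bind_rows(lapply(cases, function(cs) {
      v <- cs$record$variant
      tibble::tibble(
        case_id = cs$case_id, category = cs$category,
        contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
        gene = cs$transcript$gene_symbol, transcript = cs$transcript$transcript_id,
        truth_types = paste(cs$truth$types, collapse = ";"),
        inserted_bp = cs$truth$inserted_bp, deleted_bp = cs$truth$deleted_bp,
        frame = cs$truth$frame, spliceogenic = cs$truth$spliceogenic
      )
    }))
    structure(list(cases = cases, labels = labels, seed = seed), class = "sfx_corpus")
  })
}

#' In-memory views of a corpus
#'
#' Convenience accessors matching what the file readers would return:
#' `corpus_records()` the records tibble, `corpus_transcripts()` the gene ->
#' transcript mapping, `corpus_genome()` a single [genome_ref()] holding all
#' case contigs.
#'
#' @param corpus An `sfx_corpus` from [build_corpus()].
#' @return See description.
#' @export
corpus_records <- function(corpus) {
  stopifnot(inherits(corpus, "sfx_corpus"))
  dplyr::bind_rows(lapply(corpus$cases, function(cs) {
    r <- cs$record; v <- r$variant
    tibble::tibble(
      contig = v$contig, pos = v$pos, ref = v$ref, alt = v$alt,
      gene = r$gene_symbol,
      ds_ag = r$ds_ag, ds_al = r$ds_al, ds_dg = r$ds_dg, ds_dl = r$ds_dl,
      dp_ag = r$dp_ag, dp_al = r$dp_al, dp_dg = r$dp_dg, dp_dl = r$dp_dl
    )
  }))
}

#' @rdname corpus_records
#' @export
corpus_transcripts <- function(corpus) {
  stopifnot(inherits(corpus, "sfx_corpus"))
  stats::setNames(
    lapply(corpus$cases, function(cs) cs$transcript),
    vapply(corpus$cases, function(cs) cs$transcript$gene_symbol, character(1))
  )
}

#' @rdname corpus_records
#' @export
corpus_genome <- function(corpus) {
  stopifnot(inherits(corpus, "sfx_corpus"))
  genome_ref(unlist(lapply(corpus$cases, function(cs) cs$genome$contigs),
                    recursive = FALSE))
}

#' Write a corpus as the file set the annotator consumes
#'
#' Emits `genome.fa`, `annotation.gtf`, `genes.tsv`, `variants.vcf` (with
#' SpliceAI INFO annotations) and `labels.tsv` into `dir`. The files
#' round-trip through [parse_spliceai_vcf()], [read_gene_transcript_table()],
#' [load_transcripts()] and [read_genome_fasta()].
#'
#' @param corpus An `sfx_corpus` from [build_corpus()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the five file paths, invisibly.
#' @export
write_fixture_files <- function(corpus, dir) {
  stopifnot(inherits(corpus, "sfx_corpus"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fasta = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    genes = file.path(dir, "genes.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    labels = file.path(dir, "labels.tsv")
  )

  contigs <- unlist(lapply(corpus$cases, function(cs) cs$genome$contigs), recursive = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unlist(contigs)), paths["fasta"])

  gtf_lines <- unlist(lapply(corpus$cases, function(cs) gtf_lines_for(cs$transcript)))
  writeLines(gtf_lines, paths["gtf"])

  readr::write_tsv(
    tibble::tibble(
      gene = vapply(corpus$cases, function(cs) cs$transcript$gene_symbol, character(1)),
      transcript = vapply(corpus$cases, function(cs) cs$transcript$transcript_id, character(1))
    ),
    paths["genes"], col_names = FALSE, progress = FALSE
  )

  writeLines(vcf_lines_for(corpus), paths["vcf"])
  readr::write_tsv(corpus$labels, paths["labels"], progress = FALSE)
  invisible(paths)
}

gtf_lines_for <- function(t) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   t$gene_symbol, t$transcript_id, t$gene_symbol)
  lines <- character()
  for (i in seq_len(n_exons(t))) {
    lines <- c(lines, paste(t$contig, "splicefx", "exon", t$exons[i, "start"],
                            t$exons[i, "end"], ".", t$strand, ".", attrs, sep = "\t"))
  }
  if (has_cds(t)) {
    # standard GTF: CDS excludes the stop codon, emitted as stop_codon
    stop_g <- sort(codon_genomic_positions(t, t_cds_offset(t) + cds_genomic_length(t) - 3L, 3L))
    cds_lo <- t$cds_start; cds_hi <- t$cds_end
    if (t$strand == "+") cds_hi <- stop_g[1] - 1L else cds_lo <- stop_g[3] + 1L
    for (i in seq_len(n_exons(t))) {
      s <- max(t$exons[i, "start"], cds_lo); e <- min(t$exons[i, "end"], cds_hi)
      if (s <= e) {
        lines <- c(lines, paste(t$contig, "splicefx", "CDS", s, e, ".", t$strand, "0",
                                attrs, sep = "\t"))
      }
    }
    lines <- c(lines, paste(t$contig, "splicefx", "stop_codon", stop_g[1], stop_g[3],
                            ".", t$strand, "0", attrs, sep = "\t"))
  }
  lines
}

vcf_lines_for <- function(corpus) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SpliceAI,Number=.,Type=String,Description="SpliceAIv1.3 variant annotation. These include delta scores (DS) and delta positions (DP) for acceptor gain (AG), acceptor loss (AL), donor gain (DG), and donor loss (DL). Format: ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL">',
    vapply(corpus$cases, function(cs) {
      sprintf("##contig=<ID=%s,length=%d>", cs$record$variant$contig,
              nchar(cs$genome$contigs[[cs$record$variant$contig]]))
    }, character(1)),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- vapply(corpus$cases, function(cs) {
    r <- cs$record; v <- r$variant
    info <- sprintf("SpliceAI=%s|%s|%.2f|%.2f|%.2f|%.2f|%d|%d|%d|%d",
                    v$alt, r$gene_symbol, r$ds_ag, r$ds_al, r$ds_dg, r$ds_dl,
                    r$dp_ag, r$dp_al, r$dp_dg, r$dp_dl)
    paste(v$contig, v$pos, cs$case_id, v$ref, v$alt, ".", "PASS", info, sep = "\t")
  }, character(1))
  c(header, body)
}
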