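ABERRATION_TYPES <- c(
  "pseudoexonization", "partial_intron_retention", "partial_exon_deletion",
  "exon_skipping", "multi_exon_skipping", "whole_intron_retention", "no_impact"
)

# Combinations that a single SpliceAI score set cannot distinguish; when
# detectors collide on one of these, the call with the higher driving score
# is kept (ties go to the loss-driven call).
FORBIDDEN_PAIRS <- list(
  c("exon_skipping", "multi_exon_skipping"),
  c("exon_skipping", "whole_intron_retention"),
  c("partial_exon_deletion", "partial_intron_retention")
)

LOSS_DRIVEN <- c("exon_skipping", "multi_exon_skipping", "whole_intron_retention")

strand_sign <- function(strand) if (strand == "+") 1L else -1L

# Internal fast localization used by all detectors: plain vectors, one entry
# per signal in fixed order AG, AL, DG, DL.
signal_frame <- function(r, t, th) {
  kinds <- c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")
  scores <- c(r$ds_ag, r$ds_al, r$ds_dg, r$ds_dl)
  dps <- c(r$dp_ag, r$dp_al, r$dp_dg, r$dp_dl)
  pos <- vapply(dps, function(dp) resolve_dp(r$variant, dp, t$strand, th$dp_convention),
                integer(1))
  ex <- t$exons
  n <- nrow(ex)
  locus <- character(4)
  locus_idx <- rep(NA_integer_, 4)
  for (k in 1:4) {
    p <- pos[k]
    row <- which(p >= ex[, "start"] & p <= ex[, "end"])
    if (length(row) == 1) {
      locus[k] <- "exon"
      locus_idx[k] <- tx_exon_index(t, row)
    } else if (p > ex[1, "start"] && p < ex[n, "end"]) {
      # between two exons: genomic intron index = count of exon ends < p
      g <- sum(ex[, "end"] < p)
      locus[k] <- "intron"
      locus_idx[k] <- if (t$strand == "+") g else (n - 1L) - g + 1L
    } else {
      locus[k] <- "outside"
    }
  }
  ns <- native_splice_sites(t)
  match_intron <- rep(NA_integer_, 4)
  if (nrow(ns) > 0) {
    don <- ns$pos[ns$kind == "donor"]
    acc <- ns$pos[ns$kind == "acceptor"]
    di <- ns$intron[ns$kind == "donor"]
    ai <- ns$intron[ns$kind == "acceptor"]
    m <- match(pos[4], don)              # donor_loss vs native donors
    if (!is.na(m)) match_intron[4] <- di[m]
    m <- match(pos[2], acc)              # acceptor_loss vs native acceptors
    if (!is.na(m)) match_intron[2] <- ai[m]
  }
  list(
    kind = kinds, score = scores, dp = dps, pos = pos,
    locus = locus, locus_idx = locus_idx,
    native_intron = match_intron, ns = ns,
    inert = scores < th$noise_floor,
    strand = t$strand, sign = strand_sign(t$strand),
    variant_pos = r$variant$pos
  )
}

#' Localize the four SpliceAI signals on a transcript
#'
#' Places each of the four gain/loss signals at its genomic coordinate (via
#' [resolve_dp()]), annotates the containing feature in transcript
#' orientation, and records whether a loss signal coincides with a native
#' splice site. Signals with scores below the noise floor are flagged inert.
#'
#' @param r A [spliceai_record()].
#' @param t A [transcript_model()] for the same gene.
#' @param th [thresholds()].
#' @return A tibble with one row per signal (`acceptor_gain`,
#'   `acceptor_loss`, `donor_gain`, `donor_loss`): `score`, `dp`, `pos`,
#'   `locus` (`"exon"`/`"intron"`/`"outside"`), `locus_index`
#'   (transcript-orientation index), `native_match_intron` (for losses that
#'   sit exactly on a native site) and `inert`.
#' @export
localize_signals <- function(r, t, th = thresholds()) {
  stopifnot(inherits(r, "spliceai_record"), inherits(t, "transcript_model"))
  sf <- signal_frame(r, t, th)
  tibble::tibble(
    kind = sf$kind, score = sf$score, dp = sf$dp, pos = sf$pos,
    locus = sf$locus, locus_index = sf$locus_idx,
    native_match_intron = ifelse(sf$inert, NA_integer_, sf$native_intron),
    inert = sf$inert
  )
}

new_call <- function(type, inserted_bp = 0L, deleted_bp = 0L,
                     feature = NA_character_, from = NA_integer_, to = NA_integer_,
                     window_limited = FALSE, driving_score = NA_real_,
                     driving_kind = NA_character_, note = NA_character_,
                     g1 = NA_integer_, g2 = NA_integer_, side = NA_character_) {
  list(
    type = type, inserted_bp = as.integer(inserted_bp),
    deleted_bp = as.integer(deleted_bp), feature = feature,
    from = as.integer(from), to = as.integer(to),
    window_limited = window_limited, driving_score = driving_score,
    driving_kind = driving_kind, note = note,
    g1 = as.integer(g1), g2 = as.integer(g2), side = side
  )
}

calls_tibble <- function(calls) {
  if (length(calls) == 0) {
    return(tibble::tibble(
      type = character(), inserted_bp = integer(), deleted_bp = integer(),
      feature = character(), from = integer(), to = integer(),
      window_limited = logical(), driving_score = double(),
      driving_kind = character(), note = character(),
      g1 = integer(), g2 = integer(), side = character()
    ))
  }
  dplyr::bind_rows(lapply(calls, tibble::as_tibble))
}

# --- individual detectors -------------------------------------------------
# Each takes the internal signal frame plus transcript/thresholds and
# returns a call (list) or NULL. Exported wrappers accept a record.

.detect_pseudoexon <- function(sf, t, th) {
  ag <- 1L; dg <- 3L
  if (sf$score[ag] < th$gain_call_threshold || sf$score[dg] < th$gain_call_threshold) return(NULL)
  if (sf$locus[ag] != "intron" || sf$locus[dg] != "intron") return(NULL)
  if (sf$locus_idx[ag] != sf$locus_idx[dg]) return(NULL)
  if (sf$sign * (sf$pos[dg] - sf$pos[ag]) <= 0) return(NULL)  # acceptor must be 5' of donor
  size <- abs(sf$pos[dg] - sf$pos[ag]) + 1L
  if (size < th$pseudoexon_min_bp || size > th$pseudoexon_max_bp) {
    return(new_call("no_impact",
                    note = sprintf("paired intronic gains form a %d-bp candidate exon outside [%d,%d]; no call",
                                   size, th$pseudoexon_min_bp, th$pseudoexon_max_bp)))
  }
  new_call("pseudoexonization", inserted_bp = size,
           feature = "intron", from = sf$locus_idx[ag], to = sf$locus_idx[ag],
           driving_score = min(sf$score[ag], sf$score[dg]), driving_kind = "gain",
           g1 = min(sf$pos[ag], sf$pos[dg]), g2 = max(sf$pos[ag], sf$pos[dg]))
}

# Loss geometry: acceptor_loss matched to intron i_a marks the acceptor of
# exon i_a + 1; donor_loss matched to intron i_d marks the donor of exon i_d.
loss_exons <- function(sf, th) {
  al <- 2L; dl <- 4L
  if (sf$score[al] < th$loss_call_threshold || sf$score[dl] < th$loss_call_threshold) return(NULL)
  if (is.na(sf$native_intron[al]) || is.na(sf$native_intron[dl])) return(NULL)
  list(e1 = sf$native_intron[al] + 1L, e2 = sf$native_intron[dl],
       score = min(sf$score[al], sf$score[dl]))
}

.detect_exon_skipping <- function(sf, t, th) {
  le <- loss_exons(sf, th)
  if (is.null(le) || le$e1 != le$e2) return(NULL)
  e <- le$e1
  new_call("exon_skipping",
           deleted_bp = exon_lengths(t)[genomic_exon_row(t, e)],
           feature = "exon", from = e, to = e,
           driving_score = le$score, driving_kind = "loss")
}

.detect_multi_exon_skipping <- function(sf, t, th) {
  le <- loss_exons(sf, th)
  if (is.null(le) || le$e2 <= le$e1) return(NULL)
  rows <- vapply(le$e1:le$e2, function(e) genomic_exon_row(t, e), integer(1))
  new_call("multi_exon_skipping",
           deleted_bp = sum(exon_lengths(t)[rows]),
           feature = "exon", from = le$e1, to = le$e2,
           window_limited = range_window_limited(t, le$e1, le$e2, sf$variant_pos),
           driving_score = le$score, driving_kind = "loss")
}

.detect_whole_intron_retention <- function(sf, t, th) {
  le <- loss_exons(sf, th)
  if (is.null(le) || le$e2 != le$e1 - 1L) return(NULL)
  i <- le$e2  # donor of exon i opens intron i; acceptor of exon i+1 closes it
  iv <- intron_interval(t, i)
  new_call("whole_intron_retention",
           inserted_bp = intron_length(t, i),
           feature = "intron", from = i, to = i,
           window_limited = any(abs(iv - sf$variant_pos) > DP_WINDOW),
           driving_score = le$score, driving_kind = "loss")
}

.detect_partial_intron_retention <- function(sf, t, th, pseudoexon_active = FALSE) {
  out <- list()
  ns <- sf$ns
  for (k in c(3L, 1L)) {  # donor_gain, acceptor_gain
    if (pseudoexon_active) next   # paired gains are a pseudoexon candidate, not retention
    if (sf$score[k] < th$gain_call_threshold || sf$locus[k] != "intron") next
    i <- sf$locus_idx[k]
    if (k == 3L) {
      anchor <- ns$pos[ns$kind == "donor" & ns$intron == i]
      size <- sf$sign * (sf$pos[k] - anchor)
      support <- !sf$inert[4] && identical(sf$native_intron[4], i)
    } else {
      anchor <- ns$pos[ns$kind == "acceptor" & ns$intron == i]
      size <- sf$sign * (anchor - sf$pos[k])
      support <- !sf$inert[2] && identical(sf$native_intron[2], i)
    }
    if (size <= 0) next
    out[[length(out) + 1L]] <- new_call(
      "partial_intron_retention", inserted_bp = size,
      feature = "intron", from = i, to = i,
      driving_score = sf$score[k], driving_kind = "gain",
      note = if (support) "supported by matching native-site loss" else NA_character_,
      g1 = sf$pos[k], side = if (k == 3L) "donor" else "acceptor"
    )
  }
  out
}

.detect_partial_exon_deletion <- function(sf, t, th) {
  out <- list()
  ns <- sf$ns
  n <- n_exons(t)
  for (k in c(1L, 3L)) {  # acceptor_gain, donor_gain
    if (sf$score[k] < th$gain_call_threshold || sf$locus[k] != "exon") next
    e <- sf$locus_idx[k]
    if (k == 1L) {
      if (e < 2L) next  # first transcript exon has no native acceptor
      anchor <- ns$pos[ns$kind == "acceptor" & ns$intron == e - 1L]
      size <- sf$sign * (sf$pos[k] - anchor)
      boundary <- "acceptor"
    } else {
      if (e > n - 1L) next  # last transcript exon has no native donor
      anchor <- ns$pos[ns$kind == "donor" & ns$intron == e]
      size <- sf$sign * (anchor - sf$pos[k])
      boundary <- "donor"
    }
    if (size <= 0) next  # gain at (or beyond) the native site: degenerate, suppressed
    out[[length(out) + 1L]] <- new_call(
      "partial_exon_deletion", deleted_bp = size,
      feature = "exon", from = e, to = e,
      driving_score = sf$score[k], driving_kind = "gain",
      note = paste0(boundary, "-side cryptic site"),
      g1 = sf$pos[k], side = boundary
    )
  }
  out
}

# TRUE when a native boundary of the skipped exon range sits beyond the
# analysis window from the variant (size then rests on annotation alone).
range_window_limited <- function(t, e1, e2, variant_pos) {
  r1 <- genomic_exon_row(t, e1)
  r2 <- genomic_exon_row(t, e2)
  bounds <- c(t$exons[r1, ], t$exons[r2, ])
  any(abs(bounds - variant_pos) > DP_WINDOW)
}

unresolved_notes <- function(sf, t, th, used_loss) {
  notes <- character()
  al <- 2L; dl <- 4L
  strong <- function(k) sf$score[k] >= th$loss_call_threshold
  if (!used_loss && (strong(al) || strong(dl))) {
    if (strong(al) && strong(dl) &&
        !is.na(sf$native_intron[al]) && !is.na(sf$native_intron[dl])) {
      e1 <- sf$native_intron[al] + 1L
      e2 <- sf$native_intron[dl]
      if (e2 < e1 - 1L) notes <- c(notes, "unresolved: crossed donor/acceptor losses")
    } else {
      for (k in c(al, dl)) {
        if (!strong(k)) next
        if (is.na(sf$native_intron[k])) {
          notes <- c(notes, sprintf("unresolved: strong %s not at a native site", sf$kind[k]))
        } else {
          # lone matched loss: is the partner site of its intron observable?
          i <- sf$native_intron[k]
          iv <- intron_interval(t, i)
          partner <- if (k == dl) iv[2] + 1L else iv[1] - 1L
          wl <- abs(partner - sf$variant_pos) > DP_WINDOW
          notes <- c(notes, sprintf(
            "unresolved: lone %s at native site of intron %d%s",
            sf$kind[k], i,
            if (wl) " (partner site beyond the analysis window; window-limited)" else ""
          ))
        }
      }
    }
  }
  if (all(sf$locus == "outside")) {
    notes <- c(notes, "all signals outside the transcript span")
  }
  notes
}

#' Detect one aberration type from a SpliceAI record
#'
#' Single-detector entry points; [classify()] runs them all and resolves
#' conflicts. Each returns a one-row calls tibble, or a zero-row tibble when
#' the configuration does not support the call.
#'
#' @param r A [spliceai_record()].
#' @param t A [transcript_model()].
#' @param th [thresholds()].
#' @return A calls tibble (possibly zero rows); see [classify()] for columns.
#' @name detectors
NULL

detector_wrapper <- function(fun) {
  function(r, t, th = thresholds()) {
    sf <- signal_frame(r, t, th)
    res <- fun(sf, t, th)
    if (is.null(res)) res <- list()
    if (!is.null(res$type)) res <- list(res)
    res <- Filter(function(cl) cl$type != "no_impact", res)
    calls_tibble(res)
  }
}

#' @rdname detectors
#' @export
detect_pseudoexon <- detector_wrapper(.detect_pseudoexon)

#' @rdname detectors
#' @export
detect_exon_skipping <- detector_wrapper(.detect_exon_skipping)

#' @rdname detectors
#' @export
detect_multi_exon_skipping <- detector_wrapper(.detect_multi_exon_skipping)

#' @rdname detectors
#' @export
detect_whole_intron_retention <- detector_wrapper(.detect_whole_intron_retention)

#' @rdname detectors
#' @export
detect_partial_intron_retention <- detector_wrapper(
  function(sf, t, th) .detect_partial_intron_retention(sf, t, th, pseudoexon_active = pseudoexon_pair_present(sf, t, th))
)

#' @rdname detectors
#' @export
detect_partial_exon_deletion <- detector_wrapper(.detect_partial_exon_deletion)

# Paired same-intron gains in transcript order are pseudoexon evidence and
# are never reinterpreted as two partial retentions.
pseudoexon_pair_present <- function(sf, t, th) {
  ag <- 1L; dg <- 3L
  sf$score[ag] >= th$gain_call_threshold && sf$score[dg] >= th$gain_call_threshold &&
    sf$locus[ag] == "intron" && sf$locus[dg] == "intron" &&
    !is.na(sf$locus_idx[ag]) && sf$locus_idx[ag] == sf$locus_idx[dg] &&
    sf$sign * (sf$pos[dg] - sf$pos[ag]) > 0
}

#' Classify a SpliceAI record into aberration calls
#'
#' Runs all detectors on the localized signals and resolves collisions.
#' Combinations are allowed (e.g. exon skipping plus partial intron
#' retention from one SNV), except the three structurally indistinguishable
#' pairs: exon skipping with multi-exon skipping, exon skipping with whole
#' intron retention, and partial exon deletion with partial intron
#' retention. On a forbidden collision the call with the higher driving
#' score is kept; ties go to the loss-driven call (native-site evidence),
#' and between two gain-driven calls to partial intron retention.
#'
#' @param r A [spliceai_record()].
#' @param t A [transcript_model()] for the same gene.
#' @param th [thresholds()].
#' @return A tibble of class `sfx_calls`, one row per call, with columns
#'   `type`, `inserted_bp`, `deleted_bp`, `feature`, `from`, `to`
#'   (transcript-orientation index range), `window_limited`,
#'   `driving_score`, `driving_kind`, `note`. Always at least one row
#'   (`no_impact` when nothing fires). Record-level diagnostics are in
#'   `attr(, "notes")`.
#' @export
classify <- function(r, t, th = thresholds()) {
  stopifnot(inherits(r, "spliceai_record"), inherits(t, "transcript_model"))
  sf <- signal_frame(r, t, th)
  notes <- character()
  calls <- list()

  loss_call <- .detect_exon_skipping(sf, t, th)
  if (is.null(loss_call)) loss_call <- .detect_multi_exon_skipping(sf, t, th)
  if (is.null(loss_call)) loss_call <- .detect_whole_intron_retention(sf, t, th)
  if (!is.null(loss_call)) calls[[length(calls) + 1L]] <- loss_call

  pseudo_active <- pseudoexon_pair_present(sf, t, th)
  pe <- .detect_pseudoexon(sf, t, th)
  if (!is.null(pe)) {
    if (pe$type == "no_impact") notes <- c(notes, pe$note) else calls[[length(calls) + 1L]] <- pe
  }
  calls <- c(calls, .detect_partial_intron_retention(sf, t, th, pseudoexon_active = pseudo_active))
  if (!pseudo_active) calls <- c(calls, .detect_partial_exon_deletion(sf, t, th))

  resolved <- resolve_forbidden(calls)
  calls <- resolved$calls
  notes <- c(notes, resolved$notes)
  notes <- c(notes, unresolved_notes(sf, t, th, used_loss = !is.null(loss_call)))

  if (length(calls) == 0) {
    calls <- list(new_call("no_impact",
                           note = if (length(notes)) paste(notes, collapse = "; ") else NA_character_))
  }
  out <- calls_tibble(calls)
  attr(out, "notes") <- notes
  class(out) <- c("sfx_calls", class(out))
  out
}

resolve_forbidden <- function(calls) {
  notes <- character()
  repeat {
    types <- vapply(calls, function(cl) cl$type, character(1))
    hit <- NULL
    for (pair in FORBIDDEN_PAIRS) {
      i <- which(types == pair[1])
      j <- which(types == pair[2])
      if (length(i) && length(j)) { hit <- c(i[1], j[1]); break }
    }
    if (is.null(hit)) break
    a <- calls[[hit[1]]]; b <- calls[[hit[2]]]
    keep <- if (a$driving_score > b$driving_score) 1L
            else if (b$driving_score > a$driving_score) 2L
            else if (a$type %in% LOSS_DRIVEN) 1L
            else if (b$type %in% LOSS_DRIVEN) 2L
            else if (a$type == "partial_intron_retention") 1L
            else 2L
    drop <- calls[[hit[(keep %% 2L) + 1L]]]
    kept <- calls[[hit[keep]]]
    notes <- c(notes, sprintf(
      "indistinguishable pair %s/%s: kept %s (score %.3g) over %s (score %.3g)",
      a$type, b$type, kept$type, kept$driving_score, drop$type, drop$driving_score
    ))
    calls <- calls[-hit[(keep %% 2L) + 1L]]
  }
  list(calls = calls, notes = notes)
}
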