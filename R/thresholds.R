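#' Calling thresholds and size bounds
#'
#' Defaults follow the published calibration on curated splicing-assay
#' training data: delta scores below 0.02 are treated as noise; loss-driven
#' calls (exon skipping, whole intron retention) require scores >= 0.2, the
#' lower bound recommended by the SpliceAI authors; gain-driven calls
#' (pseudoexon, partial retention/deletion) require scores >= 0.05, the
#' threshold found to recover deep-intronic events. Gained pseudoexons are
#' constrained to 25-500 bp, a range bracketing the 50-250 bp optimum for
#' efficient exon inclusion. All thresholds are inclusive: a score equal to
#' the threshold fires.
#'
#' @param noise_floor Scores strictly below this are inert (default 0.02).
#' @param loss_call_threshold Minimum score for loss-driven calls (default 0.2).
#' @param gain_call_threshold Minimum score for gain-driven calls (default 0.05).
#' @param pseudoexon_min_bp,pseudoexon_max_bp Accepted pseudoexon size range
#'   in bp, inclusive (defaults 25 and 500).
#' @param nmd_distance PTC-to-last-junction distance (nt) beyond which
#'   nonsense-mediated decay is predicted (default 50; the "50-nt rule").
#' @param dp_convention How delta positions map to genomic coordinates; see
#'   [resolve_dp()].
#' @return An object of class `sfx_thresholds`.
#' @export
thresholds <- function(noise_floor = 0.02,
                       loss_call_threshold = 0.2,
                       gain_call_threshold = 0.05,
                       pseudoexon_min_bp = 25L,
                       pseudoexon_max_bp = 500L,
                       nmd_distance = 50L,
                       dp_convention = c("genome_forward", "strand_relative")) {
  dp_convention <- match.arg(dp_convention)
  th <- structure(
    list(
      noise_floor = noise_floor,
      loss_call_threshold = loss_call_threshold,
      gain_call_threshold = gain_call_threshold,
      pseudoexon_min_bp = as.integer(pseudoexon_min_bp),
      pseudoexon_max_bp = as.integer(pseudoexon_max_bp),
      nmd_distance = as.integer(nmd_distance),
      dp_convention = dp_convention
    ),
    class = "sfx_thresholds"
  )
  with(th, {
    if (!(noise_floor >= 0 && noise_floor <= gain_call_threshold && gain_call_threshold <= 1)) {
      stop("thresholds: need 0 <= noise_floor <= gain_call_threshold <= 1", call. = FALSE)
    }
    if (!(noise_floor <= loss_call_threshold && loss_call_threshold <= 1)) {
      stop("thresholds: need noise_floor <= loss_call_threshold <= 1", call. = FALSE)
    }
    if (!(pseudoexon_min_bp > 0 && pseudoexon_min_bp < pseudoexon_max_bp)) {
      stop("thresholds: need 0 < pseudoexon_min_bp < pseudoexon_max_bp", call. = FALSE)
    }
    if (nmd_distance < 0) stop("thresholds: nmd_distance must be >= 0", call. = FALSE)
  })
  th
}

#' @export
print.sfx_thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("<thresholds> noise_floor=%.3g loss>=%.3g gain>=%.3g ",
           "pseudoexon=[%d,%d]bp nmd=%dnt dp=%s\n"),
    x$noise_floor, x$loss_call_threshold, x$gain_call_threshold,
    x$pseudoexon_min_bp, x$pseudoexon_max_bp, x$nmd_distance, x$dp_convention
  ))
  invisible(x)
}
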