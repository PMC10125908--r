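#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.sfx_annotation <- function(x, ...) {
  r <- x$report
  cat(sprintf("<sfx_annotation> %d record(s) from %d VCF row(s); %d no-transcript, %d indel(s) skipped\n",
              r$records, r$vcf_rows, r$no_transcript, r$skipped_indel))
  tally <- unlist(r$calls_by_type)
  if (length(tally)) {
    cat("  calls:", paste(sprintf("%s=%d", names(tally), tally), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy an annotation result
#'
#' @param x An `sfx_annotation` from [run_annotate()].
#' @param ... Unused.
#' @return The per-record result tibble.
#' @export
tidy.sfx_annotation <- function(x, ...) x$results

#' One-row summary of an annotation run
#'
#' @param x An `sfx_annotation` from [run_annotate()].
#' @param ... Unused.
#' @return A one-row tibble of run counts.
#' @export
glance.sfx_annotation <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    vcf_rows = r$vcf_rows, records = r$records,
    skipped_indel = r$skipped_indel, skipped_no_info = r$skipped_no_info,
    parse_errors = r$parse_errors, no_transcript = r$no_transcript,
    spliceogenic_calls = sum(x$results$status == "ok" &
                               x$results$aberration_types != "no_impact")
  )
}

#' @export
print.sfx_benchmark <- function(x, ...) {
  cat("<sfx_benchmark>\n")
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.3f (%d/%d)\n", m$metric[i], m$value[i],
                m$numerator[i], m$denominator[i]))
  }
  invisible(x)
}

#' Tidy a benchmark: overall and per-type metrics in one tibble
#'
#' @param x An `sfx_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A tibble with columns `metric`, `value`, `numerator`,
#'   `denominator`.
#' @export
tidy.sfx_benchmark <- function(x, ...) {
  dplyr::bind_rows(
    x$metrics,
    dplyr::transmute(x$per_type, metric = paste0("accuracy_", .data$type),
                     value = .data$accuracy, numerator = .data$numerator,
                     denominator = .data$denominator)
  )
}

#' One-row summary of a benchmark
#'
#' @param x An `sfx_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A one-row tibble with `sensitivity`, `specificity`, `type_exact`
#'   and `n`.
#' @export
glance.sfx_benchmark <- function(x, ...) {
  m <- stats::setNames(as.list(x$metrics$value), x$metrics$metric)
  tibble::tibble(sensitivity = m$sensitivity, specificity = m$specificity,
                 type_exact = m$type_exact, n = nrow(x$joined))
}

#' Plot benchmark metrics
#'
#' Bar chart of the overall and per-type metrics.
#'
#' @param object An `sfx_benchmark` from [run_benchmark()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfx_benchmark <- function(object, ...) {
  d <- tidy.sfx_benchmark(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$metric, .data$value),
                                  y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d", .data$numerator,
                                                    .data$denominator)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::scale_y_continuous(limits = c(0, 1.1), breaks = seq(0, 1, 0.25)) +
    ggplot2::labs(x = NULL, y = "proportion", title = "Splicing prediction benchmark") +
    ggplot2::theme_minimal()
}

#' Plot reference vs altered transcript structure
#'
#' Draws the reference exons and the edited segment chain of an altered
#' transcript, one row each, in genomic coordinates.
#'
#' @param object An `sfx_altered` from [apply_calls()].
#' @param transcript The [transcript_model()] the calls were applied to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfx_altered <- function(object, transcript, ...) {
  ref <- tibble::tibble(start = transcript$exons[, "start"],
                        end = transcript$exons[, "end"], row = "reference")
  alt <- tibble::tibble(start = object$segments[, "start"],
                        end = object$segments[, "end"], row = "altered")
  d <- dplyr::bind_rows(ref, alt)
  d$row <- factor(d$row, levels = c("altered", "reference"))
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(
      data = tibble::tibble(row = factor(c("reference", "altered"),
                                         levels = levels(d$row)),
                            x = min(d$start), xend = max(d$end)),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$row, yend = .data$row),
      linewidth = 0.3, colour = "grey60"
    ) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                    ymin = as.numeric(.data$row) - 0.25,
                                    ymax = as.numeric(.data$row) + 0.25),
                       fill = "steelblue", colour = "grey20", linewidth = 0.2) +
    ggplot2::labs(x = sprintf("%s (%s strand)", transcript$contig, transcript$strand),
                  y = NULL,
                  title = sprintf("%s: reference vs altered structure (delta %+d bp)",
                                  transcript$transcript_id, object$delta_len)) +
    ggplot2::theme_minimal()
}
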