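empty_results <- function() {
  tibble::tibble(
    variant_id = character(), gene = character(), transcript = character(),
    aberration_types = character(), inserted_bp = integer(),
    deleted_bp = integer(), frame_effect = character(),
    protein_notation = character(), nmd_predicted = logical(),
    truncated = logical(), window_limited = logical(),
    qualifiers = character(), status = character(),
    ds_ag = double(), ds_al = double(), ds_dg = double(), ds_dl = double(),
    dp_ag = integer(), dp_al = integer(), dp_dg = integer(), dp_dl = integer()
  )
}

#' Annotate SpliceAI records with aberration calls and protein effects
#'
#' The in-memory core of the pipeline: takes a records tibble (one row per
#' variant-gene pair, as returned by [parse_spliceai_vcf()]), a gene ->
#' transcript-model mapping, and a genome, and returns one result row per
#' record. Genes absent from the mapping are emitted with status
#' `"no_transcript"` rather than dropped.
#'
#' @param records Records tibble (see [parse_spliceai_vcf()]).
#' @param transcripts Named list mapping gene symbol to
#'   [transcript_model()], as from [load_transcripts()].
#' @param genome A [genome_ref()], or `NULL` to skip protein prediction.
#' @param th [thresholds()].
#' @return A tibble with the fixed result schema (see [write_results()]):
#'   `variant_id`, `gene`, `transcript`, `aberration_types` (`";"`-joined),
#'   `inserted_bp`, `deleted_bp`, `frame_effect`, `protein_notation`,
#'   `nmd_predicted`, `truncated`, `window_limited`, `qualifiers`, `status`
#'   and the four scores/positions used.
#' @export
splice_annotate <- function(records, transcripts, genome = NULL, th = thresholds()) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(empty_results())
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    rec <- record_from_row(row)
    base <- tibble::tibble(
      variant_id = variant_id(rec$variant), gene = row$gene,
      transcript = NA_character_, aberration_types = NA_character_,
      inserted_bp = NA_integer_, deleted_bp = NA_integer_,
      frame_effect = NA_character_, protein_notation = NA_character_,
      nmd_predicted = NA, truncated = NA, window_limited = NA,
      qualifiers = NA_character_, status = "ok",
      ds_ag = row$ds_ag, ds_al = row$ds_al, ds_dg = row$ds_dg, ds_dl = row$ds_dl,
      dp_ag = row$dp_ag, dp_al = row$dp_al, dp_dg = row$dp_dg, dp_dl = row$dp_dl
    )
    t <- transcripts[[row$gene]]
    if (is.null(t)) {
      base$status <- "no_transcript"
      out[[i]] <- base
      next
    }
    if (!identical(t$contig, row$contig)) {
      base$status <- "contig_mismatch"
      base$transcript <- t$transcript_id
      out[[i]] <- base
      next
    }
    calls <- classify(rec, t, th)
    notes <- attr(calls, "notes")
    base$transcript <- t$transcript_id
    base$aberration_types <- paste(sort(calls$type), collapse = ";")
    base$inserted_bp <- sum(calls$inserted_bp)
    base$deleted_bp <- sum(calls$deleted_bp)
    base$window_limited <- any(calls$window_limited)
    base$qualifiers <- if (length(notes)) paste(notes, collapse = "; ") else NA_character_
    if (!is.null(genome)) {
      pe <- predict_protein_effect(t, calls, genome, th)
      base$frame_effect <- pe$frame
      base$protein_notation <- pe$notation
      base$nmd_predicted <- pe$nmd_predicted
      base$truncated <- pe$truncated
      if (!is.na(pe$protein_note)) {
        base$qualifiers <- if (is.na(base$qualifiers)) pe$protein_note
                           else paste(base$qualifiers, pe$protein_note, sep = "; ")
      }
    } else {
      base$frame_effect <- if (all(calls$type == "no_impact")) "none"
                           else frame_effect(sum(calls$inserted_bp) - sum(calls$deleted_bp))
    }
    out[[i]] <- base
  }
  dplyr::bind_rows(out)
}

#' Run the full annotation pipeline on files
#'
#' Reads a SpliceAI-annotated VCF, a gene-to-transcript table, a transcript
#' annotation (GTF/GFF3/refFlat) and a genome FASTA; classifies every
#' (variant, gene) pair; and optionally writes the result TSV.
#'
#' @param vcf,genes,annotation,fasta Input paths. `fasta` may be `NULL`, in
#'   which case protein prediction is skipped.
#' @param out Optional output TSV path (written with [write_results()]).
#' @param th [thresholds()].
#' @return An object of class `sfx_annotation`: list with `results` (the
#'   result tibble), `report` (named counts: rows parsed, records, skips,
#'   per-type call tallies) and `thresholds`. Use [generics::tidy()] /
#'   [generics::glance()] to extract tibbles.
#' @export
run_annotate <- function(vcf, genes, annotation, fasta = NULL, out = NULL,
                         th = thresholds()) {
  for (p in c(vcf, genes, annotation, fasta)) {
    if (!file.exists(p)) stop("run_annotate: input not found: ", p, call. = FALSE)
  }
  records <- parse_spliceai_vcf(vcf)
  table <- read_gene_transcript_table(genes)
  transcripts <- load_transcripts(annotation, table)
  genome <- if (is.null(fasta)) NULL else read_genome_fasta(fasta)
  results <- splice_annotate(records, transcripts, genome, th)
  if (!is.null(out)) write_results(results, out)

  parse_report <- attr(records, "report")
  called <- results$aberration_types[results$status == "ok"]
  type_counts <- if (length(called)) table(unlist(strsplit(called, ";"))) else integer(0)
  report <- list(
    vcf_rows = parse_report$n_rows,
    records = parse_report$n_records,
    skipped_indel = parse_report$skipped_indel,
    skipped_no_info = parse_report$skipped_no_info,
    parse_errors = length(parse_report$errors),
    no_transcript = sum(results$status == "no_transcript"),
    calls_by_type = as.list(type_counts)
  )
  structure(list(results = results, report = report, thresholds = th),
            class = "sfx_annotation")
}

#' Benchmark predictions against labels
#'
#' Compares an annotation result table with a label table sharing
#' variant keys. Sensitivity is the fraction of label-spliceogenic variants
#' called spliceogenic (any aberration type other than `no_impact`);
#' specificity the fraction of label-negative variants called `no_impact`.
#' Per-type accuracy, for each aberration type, is the fraction of
#' label-positives of that type whose prediction includes the type; the
#' strict variant (`type_exact`) additionally requires the full predicted
#' type set to equal the label set.
#'
#' @param predictions Result tibble (from [splice_annotate()] /
#'   [run_annotate()]) or a path to a TSV written by [write_results()].
#' @param labels Label tibble (see [build_corpus()]) or a path to a labels
#'   TSV. Must contain `contig`, `pos`, `ref`, `alt`, `gene`,
#'   `truth_types`, `spliceogenic`.
#' @return An object of class `sfx_benchmark`: list with `metrics` (tibble:
#'   `metric`, `value`, `numerator`, `denominator`), `per_type` (tibble) and
#'   `joined` (row-level comparison). Unmatched keys are excluded with a
#'   warning.
#' @export
run_benchmark <- function(predictions, labels) {
  if (is.character(predictions)) predictions <- read_results(predictions)
  if (is.character(labels)) {
    labels <- readr::read_tsv(labels, progress = FALSE, show_col_types = FALSE)
  }
  predictions <- tibble::as_tibble(predictions)
  labels <- tibble::as_tibble(labels)
  labels$variant_id <- sprintf("%s:%d %s>%s", labels$contig, labels$pos,
                               labels$ref, labels$alt)
  key <- c("variant_id", "gene")
  joined <- dplyr::inner_join(labels, predictions, by = key, suffix = c("_label", "_pred"))
  n_lab_only <- nrow(dplyr::anti_join(labels, predictions, by = key))
  n_pred_only <- nrow(dplyr::anti_join(predictions, labels, by = key))
  if (n_lab_only + n_pred_only > 0) {
    rlang::warn(sprintf("run_benchmark: %d label and %d prediction row(s) had no matching key and were excluded",
                        n_lab_only, n_pred_only))
  }
  if (nrow(joined) == 0) stop("run_benchmark: no shared variant keys", call. = FALSE)

  pred_spliceo <- joined$status == "ok" & joined$aberration_types != "no_impact"
  lab_spliceo <- as.logical(joined$spliceogenic)
  sens_n <- sum(pred_spliceo & lab_spliceo); sens_d <- sum(lab_spliceo)
  spec_n <- sum(!pred_spliceo & !lab_spliceo); spec_d <- sum(!lab_spliceo)

  set_split <- function(x) lapply(strsplit(x, ";"), sort)
  pred_sets <- set_split(joined$aberration_types)
  lab_sets <- set_split(joined$truth_types)
  exact <- mapply(identical, pred_sets, lab_sets)

  per_type <- dplyr::bind_rows(lapply(
    setdiff(sort(unique(unlist(lab_sets))), "no_impact"),
    function(ty) {
      sel <- vapply(lab_sets, function(s) ty %in% s, logical(1))
      hit <- vapply(which(sel), function(i) ty %in% pred_sets[[i]], logical(1))
      tibble::tibble(type = ty, accuracy = mean(hit),
                     numerator = sum(hit), denominator = sum(sel))
    }
  ))

  metrics <- tibble::tibble(
    metric = c("sensitivity", "specificity", "type_exact"),
    value = c(
      if (sens_d > 0) sens_n / sens_d else NA_real_,
      if (spec_d > 0) spec_n / spec_d else NA_real_,
      mean(exact)
    ),
    numerator = c(sens_n, spec_n, sum(exact)),
    denominator = c(sens_d, spec_d, length(exact))
  )
  joined$type_exact <- exact
  structure(list(metrics = metrics, per_type = per_type, joined = joined),
            class = "sfx_benchmark")
}

#' Emit the synthetic fixture corpus as files
#'
#' @param seed Integer seed (default 1).
#' @param outdir Output directory.
#' @param n_per_type Cases per category.
#' @return Named paths of the emitted files (FASTA, GTF, gene table, VCF,
#'   labels), invisibly.
#' @export
run_fixtures <- function(seed = 1L, outdir, n_per_type = 5L) {
  corpus <- build_corpus(seed = seed, n_per_type = n_per_type)
  write_fixture_files(corpus, outdir)
}
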