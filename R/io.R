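SPLICEAI_FIELDS <- c("ALLELE", "SYMBOL", "DS_AG", "DS_AL", "DS_DG", "DS_DL",
                     "DP_AG", "DP_AL", "DP_DG", "DP_DL")

#' Parse a SpliceAI-annotated VCF
#'
#' Reads a VCF whose `SpliceAI` INFO field carries
#' `ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`
#' annotations (comma-separated when a variant overlaps several genes).
#' One output row is produced per (SNV, gene annotation) pair. Indel rows,
#' rows without the INFO key, and annotations whose `ALLELE` does not match
#' the row's ALT are skipped and counted; malformed annotations are
#' collected as per-row errors without aborting the parse.
#'
#' @param path Path to a plain or gzipped VCF.
#' @return A tibble of class `sfx_records` with columns `contig`, `pos`,
#'   `ref`, `alt`, `gene`, `ds_ag`, `ds_al`, `ds_dg`, `ds_dl`, `dp_ag`,
#'   `dp_al`, `dp_dg`, `dp_dl`. Skip/error counts are attached as
#'   `attr(, "report")`.
#' @export
parse_spliceai_vcf <- function(path) {
  if (!file.exists(path)) stop("parse_spliceai_vcf: file not found: ", path, call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  alts <- VariantAnnotation::alt(vcf)
  has_key <- "SpliceAI" %in% rownames(VariantAnnotation::info(VariantAnnotation::header(vcf)))
  ann <- if (has_key) VariantAnnotation::info(vcf)$SpliceAI else NULL

  skipped_indel <- 0L
  skipped_no_info <- 0L
  skipped_allele <- 0L
  errors <- character()
  rows <- vector("list", length(pos))

  for (i in seq_along(pos)) {
    alt_i <- as.character(alts[[i]])
    if (nchar(ref[i]) != 1 || any(nchar(alt_i) != 1) || any(alt_i == "*")) {
      skipped_indel <- skipped_indel + 1L
      next
    }
    ai <- if (is.null(ann)) character(0) else as.character(ann[[i]])
    ai <- ai[!is.na(ai)]
    if (length(ai) == 0) {
      skipped_no_info <- skipped_no_info + 1L
      next
    }
    parsed <- list()
    for (a in ai) {
      f <- strsplit(a, "|", fixed = TRUE)[[1]]
      if (length(f) != length(SPLICEAI_FIELDS)) {
        errors <- c(errors, sprintf("%s:%d malformed SpliceAI annotation ('%s')",
                                    contig[i], pos[i], a))
        next
      }
      if (!f[1] %in% alt_i) {
        skipped_allele <- skipped_allele + 1L
        next
      }
      ds <- suppressWarnings(as.numeric(f[3:6]))
      dp <- suppressWarnings(as.integer(f[7:10]))
      if (any(is.na(ds)) || any(is.na(dp))) {
        errors <- c(errors, sprintf("%s:%d non-numeric SpliceAI fields ('%s')",
                                    contig[i], pos[i], a))
        next
      }
      parsed[[length(parsed) + 1L]] <- tibble::tibble(
        contig = contig[i], pos = pos[i], ref = ref[i], alt = f[1], gene = f[2],
        ds_ag = ds[1], ds_al = ds[2], ds_dg = ds[3], ds_dl = ds[4],
        dp_ag = dp[1], dp_al = dp[2], dp_dg = dp[3], dp_dl = dp[4]
      )
    }
    if (length(parsed)) rows[[i]] <- dplyr::bind_rows(parsed)
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      contig = character(), pos = integer(), ref = character(), alt = character(),
      gene = character(), ds_ag = double(), ds_al = double(), ds_dg = double(),
      ds_dl = double(), dp_ag = integer(), dp_al = integer(), dp_dg = integer(),
      dp_dl = integer()
    )
  }
  report <- list(
    n_rows = length(pos), n_records = nrow(out),
    skipped_indel = skipped_indel, skipped_no_info = skipped_no_info,
    skipped_allele_mismatch = skipped_allele, errors = errors
  )
  if (skipped_indel > 0) {
    rlang::warn(sprintf("parse_spliceai_vcf: skipped %d non-SNV row(s)", skipped_indel))
  }
  if (length(errors) > 0) {
    rlang::warn(sprintf("parse_spliceai_vcf: %d malformed annotation(s) collected", length(errors)))
  }
  attr(out, "report") <- report
  class(out) <- c("sfx_records", class(out))
  out
}

record_from_row <- function(row) {
  spliceai_record(
    variant(row$contig, row$pos, row$ref, row$alt), row$gene,
    ds_ag = row$ds_ag, ds_al = row$ds_al, ds_dg = row$ds_dg, ds_dl = row$ds_dl,
    dp_ag = row$dp_ag, dp_al = row$dp_al, dp_dg = row$dp_dg, dp_dl = row$dp_dl
  )
}

#' Read a gene-to-transcript table
#'
#' Tab-separated, two or more columns: gene symbol, RefSeq transcript id.
#' A header line is auto-detected and skipped; a duplicated gene keeps the
#' last row with a warning.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene` and `transcript_id`.
#' @export
read_gene_transcript_table <- function(path) {
  tbl <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(tbl) == 0 || ncol(tbl) < 2) {
    stop("read_gene_transcript_table: need a non-empty 2+ column TSV", call. = FALSE)
  }
  h1 <- tolower(tbl[[1]][1]); h2 <- tolower(tbl[[2]][1])
  if (h1 %in% c("gene", "gene_symbol", "symbol", "gene_name") ||
      h2 %in% c("transcript", "transcript_id", "refseq", "refseq_id")) {
    tbl <- tbl[-1, , drop = FALSE]
  }
  if (nrow(tbl) == 0) stop("read_gene_transcript_table: no data rows", call. = FALSE)
  out <- tibble::tibble(gene = tbl[[1]], transcript_id = tbl[[2]])
  if (any(out$transcript_id == "" | is.na(out$transcript_id))) {
    stop("read_gene_transcript_table: empty transcript id", call. = FALSE)
  }
  dup <- duplicated(out$gene, fromLast = TRUE)
  if (any(dup)) {
    rlang::warn(sprintf("read_gene_transcript_table: %d duplicated gene(s), last row wins: %s",
                        sum(dup), paste(unique(out$gene[dup]), collapse = ", ")))
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Load transcript models from an annotation file
#'
#' Accepts GTF, GFF3 (1-based inclusive; CDS excludes the stop codon, which
#' is merged back in from `stop_codon` features when present) or
#' UCSC-refFlat text (0-based half-open starts, converted at read time;
#' `cdsEnd` includes the stop codon). The dialect is chosen by file
#' extension, falling back to refFlat for tab-separated 11-column files.
#'
#' @param annotation_path Path to the annotation file.
#' @param table A gene-to-transcript tibble from
#'   [read_gene_transcript_table()].
#' @return A named list mapping gene symbol to [transcript_model()] (`NULL`
#'   for genes whose transcript is absent); missing transcript ids are
#'   reported in `attr(, "missing")`.
#' @export
load_transcripts <- function(annotation_path, table) {
  if (!file.exists(annotation_path)) {
    stop("load_transcripts: file not found: ", annotation_path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", annotation_path)))
  models <- if (ext %in% c("gtf", "gff", "gff3")) {
    load_transcripts_gxf(annotation_path, ext)
  } else {
    load_transcripts_refflat(annotation_path)
  }
  out <- stats::setNames(vector("list", nrow(table)), table$gene)
  missing <- character()
  for (i in seq_len(nrow(table))) {
    m <- models[[table$transcript_id[i]]]
    if (is.null(m)) {
      missing <- c(missing, table$transcript_id[i])
    } else {
      m$gene_symbol <- table$gene[i]
      out[[table$gene[i]]] <- m
    }
  }
  if (length(missing)) {
    rlang::warn(sprintf("load_transcripts: %d requested transcript(s) absent from annotation: %s",
                        length(missing), paste(missing, collapse = ", ")))
  }
  attr(out, "missing") <- missing
  out
}

load_transcripts_gxf <- function(path, ext) {
  gr <- rtracklayer::import(path, format = if (ext == "gtf") "gtf" else "gff3")
  mc <- S4Vectors::mcols(gr)
  tx_id <- if ("transcript_id" %in% names(mc)) {
    as.character(mc$transcript_id)
  } else if ("Parent" %in% names(mc)) {
    p <- vapply(as.list(mc$Parent), function(x) if (length(x)) x[[1]] else NA_character_,
                character(1))
    sub("^(rna-|transcript:)", "", p)
  } else {
    stop("load_transcripts: annotation lacks transcript_id/Parent attributes", call. = FALSE)
  }
  gene_nm <- if ("gene_name" %in% names(mc)) as.character(mc$gene_name)
             else if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
             else rep(NA_character_, length(gr))
  type <- as.character(mc$type)
  models <- list()
  for (id in unique(stats::na.omit(tx_id))) {
    sel <- which(tx_id == id)
    ex <- sel[type[sel] == "exon"]
    if (length(ex) == 0) next
    cds <- sel[type[sel] %in% c("CDS", "stop_codon")]
    exons <- cbind(start = GenomicRanges::start(gr)[ex], end = GenomicRanges::end(gr)[ex])
    models[[id]] <- transcript_model(
      gene_symbol = gene_nm[ex[1]] %||% id,
      transcript_id = id,
      contig = as.character(GenomicRanges::seqnames(gr))[ex[1]],
      strand = as.character(GenomicRanges::strand(gr))[ex[1]],
      exons = exons,
      cds_start = if (length(cds)) min(GenomicRanges::start(gr)[cds]) else NA_integer_,
      cds_end = if (length(cds)) max(GenomicRanges::end(gr)[cds]) else NA_integer_
    )
  }
  models
}

load_transcripts_refflat <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c(
    "geneName", "name", "chrom", "strand", "txStart", "txEnd",
    "cdsStart", "cdsEnd", "exonCount", "exonStarts", "exonEnds"
  ), col_types = "cccciiiiicc", comment = "#", progress = FALSE)
  models <- list()
  for (i in seq_len(nrow(tbl))) {
    starts <- as.integer(strsplit(tbl$exonStarts[i], ",")[[1]]) + 1L  # 0-based half-open
    ends <- as.integer(strsplit(tbl$exonEnds[i], ",")[[1]])
    no_cds <- tbl$cdsStart[i] >= tbl$cdsEnd[i]
    models[[tbl$name[i]]] <- transcript_model(
      gene_symbol = tbl$geneName[i], transcript_id = tbl$name[i],
      contig = tbl$chrom[i], strand = tbl$strand[i],
      exons = cbind(start = starts, end = ends),
      cds_start = if (no_cds) NA_integer_ else tbl$cdsStart[i] + 1L,
      cds_end = if (no_cds) NA_integer_ else tbl$cdsEnd[i]
    )
  }
  models
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

RESULT_COLUMNS <- c(
  "variant_id", "gene", "transcript", "aberration_types", "inserted_bp",
  "deleted_bp", "frame_effect", "protein_notation", "nmd_predicted",
  "truncated", "window_limited", "qualifiers", "status",
  "ds_ag", "ds_al", "ds_dg", "ds_dl", "dp_ag", "dp_al", "dp_dg", "dp_dl"
)

#' Write an annotation result table
#'
#' Tab-separated, UTF-8, one header line, fixed column order, rows in input
#' order. Multiple aberration types are joined with `";"`; missing values
#' are serialized as `"."`.
#'
#' @param rows Result tibble (see [run_annotate()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  for (col in RESULT_COLUMNS) {
    if (!col %in% names(rows)) rows[[col]] <- NA
  }
  rows <- rows[, RESULT_COLUMNS]
  out <- dplyr::mutate(rows, dplyr::across(
    dplyr::everything(),
    function(x) {
      x <- as.character(x)
      ifelse(is.na(x) | x == "", ".", x)
    }
  ))
  readr::write_tsv(out, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A tibble with `"."` restored to `NA`.
#' @export
read_results <- function(path) {
  readr::read_tsv(path, na = ".", progress = FALSE, show_col_types = FALSE)
}
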