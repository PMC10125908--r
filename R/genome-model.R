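#' Reference genome held in memory
#'
#' A `genome_ref` is a named list of uppercase nucleotide strings (alphabet
#' A, C, G, T, N), one per contig. All toy genomes produced by
#' [make_toy_gene()] use this container, and [read_genome_fasta()] loads a
#' FASTA file into it.
#'
#' @param contigs Named character vector or list of nucleotide strings.
#' @return An object of class `genome_ref`.
#' @examples
#' g <- genome_ref(c(chr1 = "ACGTACGT"))
#' seq_at(g, "chr1", 2, 4)
#' @export
genome_ref <- function(contigs) {
  contigs <- as.list(contigs)
  if (length(contigs) == 0 || is.null(names(contigs)) || any(names(contigs) == "")) {
    stop("genome_ref: contigs must be a non-empty named collection", call. = FALSE)
  }
  contigs <- lapply(contigs, function(s) {
    s <- toupper(as.character(s))
    if (nchar(s) < 1) stop("genome_ref: zero-length contig", call. = FALSE)
    if (grepl("[^ACGTN]", s)) stop("genome_ref: contig contains non-ACGTN characters", call. = FALSE)
    s
  })
  structure(list(contigs = contigs), class = "genome_ref")
}

#' Extract a genomic interval (1-based, inclusive)
#'
#' @param genome A [genome_ref()].
#' @param contig Contig name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return A character scalar of length `end - start + 1`.
#' @export
seq_at <- function(genome, contig, start, end) {
  stopifnot(inherits(genome, "genome_ref"))
  s <- genome$contigs[[contig]]
  if (is.null(s)) stop("seq_at: unknown contig '", contig, "'", call. = FALSE)
  if (start < 1 || end > nchar(s) || start > end) {
    stop("seq_at: interval [", start, ",", end, "] outside contig '", contig, "'", call. = FALSE)
  }
  substr(s, start, end)
}

#' Load a genome FASTA into memory
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A [genome_ref()].
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  genome_ref(stats::setNames(as.character(ss), nm))
}

#' Transcript model: exon/CDS structure of one RefSeq transcript
#'
#' Coordinates are 1-based inclusive genomic positions (VCF/GTF convention).
#' Exons are stored sorted by genomic start; transcript-orientation indices
#' (exon 1 = 5'-most exon of the mRNA) are derived from `strand`.
#'
#' @param gene_symbol Gene symbol.
#' @param transcript_id Transcript accession (e.g. a RefSeq `NM_` id).
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of genomic `(start, end)`
#'   intervals, 1-based inclusive, non-overlapping.
#' @param cds_start,cds_end Genomic positions of the first and last coding
#'   base (genomic order, `cds_start <= cds_end`), or `NA` for a
#'   non-coding transcript (protein prediction is then disabled).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_symbol, transcript_id, contig, strand, exons,
                             cds_start = NA_integer_, cds_end = NA_integer_) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1) stop("transcript_model: need >= 1 exon", call. = FALSE)
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "start"] > exons[, "end"])) {
    stop("transcript_model: exon start > end", call. = FALSE)
  }
  if (nrow(exons) > 1 && any(exons[-1, "start"] <= exons[-nrow(exons), "end"])) {
    stop("transcript_model: overlapping exons", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("transcript_model: strand must be '+' or '-'", call. = FALSE)
  t <- structure(
    list(
      gene_symbol = as.character(gene_symbol),
      transcript_id = as.character(transcript_id),
      contig = as.character(contig),
      strand = strand,
      exons = exons,
      cds_start = as.integer(cds_start),
      cds_end = as.integer(cds_end)
    ),
    class = "transcript_model"
  )
  if (has_cds(t)) {
    if (t$cds_start > t$cds_end) stop("transcript_model: cds_start > cds_end", call. = FALSE)
    in_ex <- function(p) any(p >= exons[, "start"] & p <= exons[, "end"])
    if (!in_ex(t$cds_start) || !in_ex(t$cds_end)) {
      stop("transcript_model: CDS boundaries not inside exons", call. = FALSE)
    }
    if (cds_genomic_length(t) < 3L) stop("transcript_model: CDS shorter than one codon", call. = FALSE)
  }
  t
}

has_cds <- function(t) !is.na(t$cds_start) && !is.na(t$cds_end)

n_exons <- function(t) nrow(t$exons)

exon_lengths <- function(t) as.integer(t$exons[, "end"] - t$exons[, "start"] + 1L)

cds_genomic_length <- function(t) {
  s <- pmax(t$exons[, "start"], t$cds_start)
  e <- pmin(t$exons[, "end"], t$cds_end)
  sum(pmax(0L, e - s + 1L))
}

# Map genomic exon row index -> transcript-orientation exon index.
tx_exon_index <- function(t, genomic_row) {
  if (t$strand == "+") genomic_row else n_exons(t) - genomic_row + 1L
}

# Inverse: transcript-orientation exon index -> genomic exon row.
genomic_exon_row <- function(t, tx_idx) {
  if (t$strand == "+") tx_idx else n_exons(t) - tx_idx + 1L
}

#' Native splice sites of a transcript
#'
#' Donor = last exonic base of the upstream exon in transcript orientation;
#' acceptor = first exonic base of the downstream exon (the convention
#' SpliceAI uses to label splice positions). Intron indices count in
#' transcript orientation starting at 1, so intron `i` separates transcript
#' exons `i` and `i + 1`.
#'
#' @param t A [transcript_model()].
#' @return A tibble with columns `kind` (`"donor"`/`"acceptor"`), `pos`
#'   (genomic position) and `intron` (transcript-orientation intron index);
#'   `2 * (n_exons - 1)` rows, empty for a single-exon transcript.
#' @examples
#' t <- transcript_model("G", "T1", "chr1", "+",
#'                       cbind(c(101, 301, 501), c(200, 400, 600)), 120, 550)
#' native_splice_sites(t)
#' @export
native_splice_sites <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- n_exons(t)
  if (n < 2) {
    return(tibble::tibble(kind = character(), pos = integer(), intron = integer()))
  }
  i <- seq_len(n - 1L)                          # transcript intron index
  if (t$strand == "+") {
    donors <- t$exons[i, "end"]                 # upstream exon, transcript orientation
    acceptors <- t$exons[i + 1L, "start"]
  } else {
    donors <- t$exons[n - i + 1L, "start"]
    acceptors <- t$exons[n - i, "end"]
  }
  tibble::tibble(
    kind = rep(c("donor", "acceptor"), n - 1L),
    pos = as.integer(rbind(donors, acceptors)),
    intron = rep(i, each = 2L)
  )
}

# Genomic interval of transcript intron i as c(start, end), genomic order.
intron_interval <- function(t, i) {
  up <- genomic_exon_row(t, i)
  dn <- genomic_exon_row(t, i + 1L)
  lo <- min(up, dn)
  hi <- max(up, dn)
  c(t$exons[lo, "end"] + 1L, t$exons[hi, "start"] - 1L)
}

intron_length <- function(t, i) {
  iv <- intron_interval(t, i)
  as.integer(iv[2] - iv[1] + 1L)
}

#' Single-nucleotide variant
#'
#' @param contig Contig name.
#' @param pos 1-based genomic position.
#' @param ref,alt Single reference/alternate bases; `ref != alt`.
#' @return An object of class `snv`.
#' @export
variant <- function(contig, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) != 1 || nchar(alt) != 1) {
    stop("variant: only single-nucleotide variants are supported", call. = FALSE)
  }
  if (ref == alt) stop("variant: ref == alt", call. = FALSE)
  structure(
    list(contig = as.character(contig), pos = as.integer(pos), ref = ref, alt = alt),
    class = "snv"
  )
}

variant_id <- function(v) sprintf("%s:%d %s>%s", v$contig, v$pos, v$ref, v$alt)

DP_WINDOW <- 4999L

#' One SpliceAI annotation: an SNV plus four delta scores and positions
#'
#' @param variant An [variant()] (SNV).
#' @param gene_symbol Gene symbol the annotation refers to.
#' @param ds_ag,ds_al,ds_dg,ds_dl Delta scores (acceptor/donor gain/loss),
#'   each in `[0, 1]`.
#' @param dp_ag,dp_al,dp_dg,dp_dl Signed delta positions, each within
#'   `[-4999, 4999]`.
#' @return An object of class `spliceai_record`.
#' @export
spliceai_record <- function(variant, gene_symbol,
                            ds_ag, ds_al, ds_dg, ds_dl,
                            dp_ag, dp_al, dp_dg, dp_dl) {
  stopifnot(inherits(variant, "snv"))
  ds <- c(ds_ag, ds_al, ds_dg, ds_dl)
  dp <- as.integer(c(dp_ag, dp_al, dp_dg, dp_dl))
  if (any(is.na(ds)) || any(ds < 0) || any(ds > 1)) {
    stop("spliceai_record: delta scores must be in [0, 1]", call. = FALSE)
  }
  if (any(is.na(dp)) || any(abs(dp) > DP_WINDOW)) {
    stop("spliceai_record: delta positions must be within +/-", DP_WINDOW, call. = FALSE)
  }
  structure(
    list(
      variant = variant, gene_symbol = as.character(gene_symbol),
      ds_ag = ds[1], ds_al = ds[2], ds_dg = ds[3], ds_dl = ds[4],
      dp_ag = dp[1], dp_al = dp[2], dp_dg = dp[3], dp_dl = dp[4]
    ),
    class = "spliceai_record"
  )
}

#' Resolve a delta position to a genomic coordinate
#'
#' SpliceAI reports splice-site offsets relative to the variant. The public
#' description does not pin down whether the sign follows the genome-forward
#' axis or the transcript strand, so both conventions are supported; the
#' default is genome-forward (`pos + dp` regardless of strand).
#'
#' @param v An [variant()].
#' @param dp Signed delta position, `|dp| <= 4999`.
#' @param strand Transcript strand, `"+"` or `"-"`.
#' @param convention `"genome_forward"` (default) or `"strand_relative"`.
#' @return Genomic position (integer).
#' @export
resolve_dp <- function(v, dp, strand = "+", convention = c("genome_forward", "strand_relative")) {
  convention <- match.arg(convention)
  dp <- as.integer(dp)
  if (is.na(dp) || abs(dp) > DP_WINDOW) {
    stop("resolve_dp: delta position outside the +/-", DP_WINDOW, " window", call. = FALSE)
  }
  if (convention == "genome_forward" || strand == "+") v$pos + dp else v$pos - dp
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s (%s) %s:%s strand %s, %d exon(s)%s\n",
    x$transcript_id, x$gene_symbol, x$contig,
    paste0(x$exons[1, "start"], "-", x$exons[nrow(x$exons), "end"]),
    x$strand, nrow(x$exons),
    if (has_cds(x)) sprintf(", CDS %d-%d", x$cds_start, x$cds_end) else ", non-coding"
  ))
  invisible(x)
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf(
    "<genome_ref> %d contig(s): %s\n", length(x$contigs),
    paste(utils::head(names(x$contigs), 5), collapse = ", ")
  ))
  invisible(x)
}

#' @export
print.spliceai_record <- function(x, ...) {
  cat(sprintf(
    "<spliceai_record> %s gene %s  DS(AG,AL,DG,DL)=%.2f,%.2f,%.2f,%.2f DP=%d,%d,%d,%d\n",
    variant_id(x$variant), x$gene_symbol,
    x$ds_ag, x$ds_al, x$ds_dg, x$ds_dl, x$dp_ag, x$dp_al, x$dp_dg, x$dp_dl
  ))
  invisible(x)
}
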