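#' Read BED-like alignment records for one sample
#'
#' The expected format is a 6-column tab-separated file per sample:
#' chrom, start (0-based), end (half-open), read_id, n_hits (number of
#' genomic placements of the read), strand. One row per placement.
#'
#' @param path Path to the alignment TSV/BED file.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `n_hits`, `sample_id`.
#' @export
read_alignments_bed <- function(path, sample_id) {
  if (!file.exists(path)) stop_config("alignment file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "read_id",
                                 "n_hits", "strand"))
  if (nrow(df) && any(df$start >= df$end)) {
    stop_data("alignment file '", path, "': start >= end at row ",
              which(df$start >= df$end)[1])
  }
  data.frame(read_id = as.character(df$read_id), chrom = df$chrom,
             start = df$start, end = df$end, strand = df$strand,
             n_hits = df$n_hits, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

#' Read SAM alignments for one sample (optional reader)
#'
#' Maps the `NH` tag to `n_hits` (records without `NH` get 1). Requires
#' the Rsamtools package.
#'
#' @inheritParams read_alignments_bed
#' @return Same layout as [read_alignments_bed()].
#' @export
read_alignments_sam <- function(path, sample_id) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop_config("reading SAM requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "qwidth", "strand", "cigar"),
    tag = "NH")
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  keep <- !is.na(x$pos)
  nh <- x$tag$NH
  if (is.null(nh)) nh <- rep(1L, length(x$pos))
  nh[is.na(nh)] <- 1L
  # aligned span on the reference from the CIGAR string
  span <- vapply(x$cigar[keep], cigar_ref_span, integer(1), USE.NAMES = FALSE)
  data.frame(read_id = x$qname[keep],
             chrom = as.character(x$rname[keep]),
             start = x$pos[keep] - 1L,
             end = x$pos[keep] - 1L + span,
             strand = as.character(x$strand[keep]),
             n_hits = nh[keep], sample_id = sample_id,
             stringsAsFactors = FALSE)
}

cigar_ref_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

#' Assign aligned reads to annotation loci
#'
#' A read placement contributes one count to a locus when it lies on the
#' same chromosome (and strand, unless `stranded = FALSE`) and the
#' overlapping length is at least `overlap_frac` of the locus length
#' (or of the read length with `overlap_denominator = "read"`). Reads with
#' more than `max_locations` genomic placements contribute nothing. When a
#' placement satisfies the rule for several loci, only the locus with the
#' largest overlap is counted (first in annotation order on ties), so each
#' placement contributes at most one count.
#'
#' @param alignments data.frame of placements (`read_id`, `chrom`, `start`,
#'   `end`, `strand`, `n_hits`, `sample_id`), e.g. rbind of
#'   [read_alignments_bed()] outputs.
#' @param annotation An `annotation_set`.
#' @param samples data.frame with columns `sample_id`, `animal_id`,
#'   `tissue`.
#' @param overlap_frac Minimum overlap fraction in (0, 1]; default 0.7.
#' @param max_locations Placement-count cutoff, strict `>` excluded
#'   (default 10).
#' @param stranded Count only same-strand overlaps (default TRUE).
#' @param overlap_denominator `"locus"` (default) or `"read"`.
#' @return A `count_matrix`: list with `counts` (integer matrix, loci x
#'   samples), `samples` (the metadata), `assigned_total` and
#'   `aligned_total` per sample.
#' @export
assign_reads <- function(alignments, annotation, samples,
                         overlap_frac = 0.7, max_locations = 10,
                         stranded = TRUE,
                         overlap_denominator = c("locus", "read")) {
  overlap_denominator <- match.arg(overlap_denominator)
  if (overlap_frac <= 0 || overlap_frac > 1) {
    stop_config("overlap_frac must be in (0, 1]")
  }
  if (anyDuplicated(samples$sample_id)) {
    stop_data("duplicate sample_id in sample metadata")
  }
  unknown <- setdiff(unique(alignments$sample_id), samples$sample_id)
  if (length(unknown)) {
    stop_data("alignments reference samples missing from metadata: ",
              paste(unknown, collapse = ", "))
  }
  loci <- annotation$loci
  sample_ids <- samples$sample_id
  counts <- matrix(0L, nrow = nrow(loci), ncol = length(sample_ids),
                   dimnames = list(loci$name, sample_ids))
  aligned_total <- vapply(sample_ids, function(s) {
    length(unique(alignments$read_id[alignments$sample_id == s]))
  }, integer(1))

  keep <- alignments$n_hits <= max_locations
  aln <- alignments[keep, , drop = FALSE]
  if (nrow(aln) && nrow(loci)) {
    locus_gr <- annotation_granges(annotation)
    read_gr <- GenomicRanges::GRanges(
      aln$chrom, IRanges::IRanges(start = aln$start + 1L, end = aln$end),
      strand = aln$strand)
    ov <- GenomicRanges::findOverlaps(read_gr, locus_gr,
                                      ignore.strand = !stranded)
    if (length(ov)) {
      q <- S4Vectors::queryHits(ov)
      s <- S4Vectors::subjectHits(ov)
      ow <- BiocGenerics::width(IRanges::pintersect(
        IRanges::IRanges(aln$start[q] + 1L, aln$end[q]),
        IRanges::IRanges(loci$start[s] + 1L, loci$end[s])))
      denom <- if (overlap_denominator == "locus") {
        loci$end[s] - loci$start[s]
      } else {
        aln$end[q] - aln$start[q]
      }
      ok <- ow / denom >= overlap_frac
      q <- q[ok]; s <- s[ok]; ow <- ow[ok]
      if (length(q)) {
        # best locus per placement: max overlap, then annotation order
        o <- order(q, -ow, s)
        first <- !duplicated(q[o])
        q <- q[o][first]; s <- s[o][first]
        tab <- table(factor(loci$name[s], levels = loci$name),
                     factor(aln$sample_id[q], levels = sample_ids))
        counts <- counts + matrix(as.integer(tab), nrow = nrow(loci),
                                  dimnames = dimnames(counts))
      }
    }
  }
  structure(list(counts = counts, samples = samples,
                 assigned_total = colSums(counts),
                 aligned_total = aligned_total,
                 parameters = list(overlap_frac = overlap_frac,
                                   max_locations = max_locations,
                                   stranded = stranded,
                                   overlap_denominator = overlap_denominator)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "loci x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Reads-per-million normalization
#'
#' `rpm[i, j] = counts[i, j] / total_j * 1e6`, where `total_j` is the
#' number of reads assigned to loci in sample j (default) or the number of
#' aligned reads. With the `assigned` denominator every non-empty column
#' sums to exactly one million.
#'
#' @param counts A `count_matrix`.
#' @param denominator `"assigned"` (default) or `"aligned"`.
#' @return An `expression_matrix`: list with `rpm` (numeric matrix),
#'   `samples`, `normalization_denominator`.
#' @export
rpm_normalize <- function(counts, denominator = c("assigned", "aligned")) {
  denominator <- match.arg(denominator)
  totals <- if (denominator == "assigned") counts$assigned_total else
    counts$aligned_total
  zero <- totals == 0
  if (any(zero)) {
    warning("sample(s) with zero ", denominator,
            " reads get all-zero RPM: ",
            paste(colnames(counts$counts)[zero], collapse = ", "))
  }
  denom <- ifelse(zero, 1, totals)
  rpm <- sweep(counts$counts, 2, denom, "/") * 1e6
  rpm[, zero] <- 0
  structure(list(rpm = rpm, samples = counts$samples,
                 normalization_denominator = denominator),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (RPM,", x$normalization_denominator,
      "denominator):", nrow(x$rpm), "loci x", ncol(x$rpm), "samples\n")
  invisible(x)
}

# tissue-median RPM matrix (loci x tissues); shared by detection and
# enrichment
tissue_medians <- function(rpm, samples) {
  tissues <- unique(samples$tissue)
  med <- vapply(tissues, function(t) {
    cols <- samples$sample_id[samples$tissue == t]
    apply(rpm[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(rpm)))
  if (nrow(rpm) == 1) med <- matrix(med, nrow = 1, dimnames = list(rownames(rpm), tissues))
  colnames(med) <- tissues
  med
}

#' Per-tissue detection calls
#'
#' A locus is detected in a tissue when the tissue's median RPM strictly
#' exceeds `detection_rpm`.
#'
#' @param expr An `expression_matrix`.
#' @param detection_rpm Detection threshold (default 100 RPM, strict `>`).
#' @return List with `detected` (logical matrix, loci x tissues) and
#'   `n_detected_tissues` (integer per locus).
#' @export
detection_matrix <- function(expr, detection_rpm = 100) {
  med <- tissue_medians(expr$rpm, expr$samples)
  det <- med > detection_rpm
  list(detected = det, n_detected_tissues = rowSums(det),
       tissue_medians = med)
}

#' Percent of reads mapped per sample
#'
#' @param read_totals data.frame with columns `sample_id`, `aligned`,
#'   `total`.
#' @return data.frame with `sample_id`, `percent_mapped`.
#' @export
percent_mapped <- function(read_totals) {
  if (any(read_totals$total == 0)) {
    stop_data("sample with zero total reads: ",
              read_totals$sample_id[read_totals$total == 0][1])
  }
  if (any(read_totals$aligned > read_totals$total)) {
    stop_data("aligned exceeds total reads for sample ",
              read_totals$sample_id[read_totals$aligned > read_totals$total][1])
  }
  data.frame(sample_id = read_totals$sample_id,
             percent_mapped = 100 * read_totals$aligned / read_totals$total,
             stringsAsFactors = FALSE)
}
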