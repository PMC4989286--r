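#' Enrichment classification configuration
#'
#' Thresholds for the tissue-enrichment (TE) and highly-tissue-enriched
#' (HTE) classification. TE requires fold-change > `fc_threshold` together
#' with a BH-adjusted one-sided Wilcoxon rank-sum q-value < `alpha`. HTE
#' requires the tissue median RPM to exceed `hte_fold` times the maximum
#' expression observed in any other tissue, with detection in at most
#' `hte_max_tissues` tissues.
#'
#' @param fc_threshold TE fold-change threshold (default 5, strict `>`).
#' @param alpha FDR level for TE (default 0.05, strict `<`).
#' @param hte_fold HTE fold threshold (default 5, strict `>`).
#' @param hte_max_tissues Maximum tissues a HTE locus may be detected in
#'   (default 2).
#' @param candidate_rpm Candidate filter: keep loci whose maximum tissue
#'   median RPM exceeds this (default 100, strict `>`).
#' @param detection_rpm Detection threshold (default 100 RPM).
#' @param pseudocount Additive RPM pseudocount in fold-change (default 1).
#' @param alternative Wilcoxon laterality: `"greater"` (default) or
#'   `"two_sided"`.
#' @param fdr_scope `"per_tissue"` (default; each tissue is its own BH
#'   family across candidate loci) or `"global"`.
#' @param hte_comparator `"sample_max"` (default; literal maximum over
#'   individual samples outside the tissue) or `"tissue_median_max"`.
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(fc_threshold = 5, alpha = 0.05, hte_fold = 5,
                              hte_max_tissues = 2, candidate_rpm = 100,
                              detection_rpm = 100, pseudocount = 1,
                              alternative = c("greater", "two_sided"),
                              fdr_scope = c("per_tissue", "global"),
                              hte_comparator = c("sample_max",
                                                 "tissue_median_max")) {
  alternative <- match.arg(alternative)
  fdr_scope <- match.arg(fdr_scope)
  hte_comparator <- match.arg(hte_comparator)
  for (v in c("fc_threshold", "hte_fold", "candidate_rpm", "detection_rpm",
              "pseudocount")) {
    if (get(v) <= 0) stop_config(v, " must be > 0")
  }
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (hte_max_tissues < 1) stop_config("hte_max_tissues must be >= 1")
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 hte_fold = hte_fold, hte_max_tissues = hte_max_tissues,
                 candidate_rpm = candidate_rpm,
                 detection_rpm = detection_rpm, pseudocount = pseudocount,
                 alternative = alternative, fdr_scope = fdr_scope,
                 hte_comparator = hte_comparator),
            class = "enrichment_config")
}

#' Candidate locus filter
#'
#' Keeps loci whose maximum tissue-median RPM strictly exceeds
#' `candidate_rpm` (i.e. expressed above the cutoff in at least one
#' tissue).
#'
#' @param expr An `expression_matrix`.
#' @param candidate_rpm RPM cutoff (strict `>`).
#' @return Character vector of retained locus names.
#' @export
candidate_filter <- function(expr, candidate_rpm = 100) {
  if (nrow(expr$rpm) == 0) return(character())
  med <- tissue_medians(expr$rpm, expr$samples)
  rownames(expr$rpm)[apply(med, 1, max) > candidate_rpm]
}

#' Fold-change of a locus in a tissue versus all other samples
#'
#' fold = (median RPM within the tissue + pseudocount) /
#' (median RPM over all samples of other tissues, pooled + pseudocount).
#'
#' @param expr An `expression_matrix`.
#' @param locus Locus name.
#' @param tissue Tissue label.
#' @param pseudocount Additive RPM pseudocount (default 1).
#' @return List with `tissue_median`, `other_median`, `fold`.
#' @export
tissue_fold_change <- function(expr, locus, tissue, pseudocount = 1) {
  samples <- expr$samples
  if (!tissue %in% samples$tissue) stop_data("unknown tissue: ", tissue)
  if (!locus %in% rownames(expr$rpm)) stop_data("unknown locus: ", locus)
  in_t <- samples$sample_id[samples$tissue == tissue]
  out_t <- samples$sample_id[samples$tissue != tissue]
  tm <- median(expr$rpm[locus, in_t])
  om <- median(expr$rpm[locus, out_t])
  list(tissue_median = tm, other_median = om,
       fold = (tm + pseudocount) / (om + pseudocount))
}

#' Wilcoxon rank-sum p-value with an exact small-sample branch
#'
#' Computes the one-sided (`greater`: x stochastically larger) or
#' two-sided rank-sum p-value. With `length(x) + length(y) <= 12` and no
#' ties, the exact permutation null distribution of the rank-sum statistic
#' is used; otherwise midranks with the normal approximation and tie
#' correction (no continuity correction). Fully tied data return p = 1.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param alternative `"greater"` or `"two_sided"`.
#' @return A p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (length(x) < 2 || length(y) < 2) {
    stop_config("both groups need at least 2 values")
  }
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  z <- c(x, y)
  if (length(unique(z)) == 1) return(1)
  r <- rank(z)
  has_ties <- anyDuplicated(z) > 0
  if (N <= 12 && !has_ties) {
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of x
    p_greater <- pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    if (alternative == "greater") return(min(1, p_greater))
    p_less <- pwilcox(u, n1, n2)
    return(min(1, 2 * min(p_greater, p_less)))
  }
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(z)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  zstat <- (W - mu) / sqrt(sigma2)
  p <- if (alternative == "greater") pnorm(zstat, lower.tail = FALSE) else
    2 * pnorm(abs(zstat), lower.tail = FALSE)
  min(1, max(p, .Machine$double.xmin))
}

# vectorized approximate branch over the rows of a matrix: one-sided
# (greater) rank-sum p of tissue columns vs the rest, midranks + tie
# correction. Equals wilcoxon_rank_sum() row-wise when N > 12 or ties.
wilcoxon_p_rows <- function(mat, in_tissue,
                            alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  apply(mat, 1, function(row) {
    wilcoxon_rank_sum(row[in_tissue], row[!in_tissue],
                      alternative = alternative)
  })
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of (m / j) * p_(j), capped at 1; input order is
#' preserved on return.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(p <= 0 | p > 1)) stop_config("p-values must be in (0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify tissue-enriched and highly-tissue-enriched loci
#'
#' For every candidate locus and every tissue computes the fold-change
#' (tissue median vs pooled other-sample median, pseudocount added), the
#' Wilcoxon rank-sum p-value of the tissue's samples against all other
#' samples, and BH q-values (per tissue by default). A record is TE when
#' fold > `fc_threshold` and q < `alpha`; HTE when the tissue median RPM
#' strictly exceeds `hte_fold` times the maximum expression observed in
#' any other tissue and the locus is detected in at most
#' `hte_max_tissues` tissues. Class per record: `HTE1` when HTE holds in
#' exactly one tissue for the locus, `HTE2` when in two, else `TE` when TE
#' holds, else `none`.
#'
#' @param expr An `expression_matrix`.
#' @param config An [enrichment_config()].
#' @return List with `records` (data.frame: `locus`, `tissue`,
#'   `tissue_median_rpm`, `other_median_rpm`, `fold_change`, `p_value`,
#'   `q_value`, `n_detected_tissues`, `class`), `tallies` (per-tissue TE /
#'   HTE2 / HTE1 counts), `candidates`.
#' @export
classify_all <- function(expr, config = enrichment_config()) {
  samples <- expr$samples
  tissues <- sort(unique(samples$tissue))
  if (length(tissues) < 2) stop_config("need >= 2 tissues")
  n_per <- table(samples$tissue)
  if (any(n_per < 2)) {
    stop_config("every tissue needs >= 2 samples; offending: ",
                paste(names(n_per)[n_per < 2], collapse = ", "))
  }
  cand <- candidate_filter(expr, config$candidate_rpm)
  empty <- data.frame(locus = character(), tissue = character(),
                      tissue_median_rpm = numeric(),
                      other_median_rpm = numeric(),
                      fold_change = numeric(), p_value = numeric(),
                      q_value = numeric(), n_detected_tissues = integer(),
                      class = character(), stringsAsFactors = FALSE)
  if (length(cand) == 0) {
    tal <- data.frame(tissue = tissues, TE = 0L, HTE2 = 0L, HTE1 = 0L,
                      stringsAsFactors = FALSE)
    return(list(records = empty, tallies = tal, candidates = cand))
  }
  # order columns by sample_id so results do not depend on input ordering
  ord <- order(samples$sample_id)
  samples <- samples[ord, , drop = FALSE]
  rpm <- expr$rpm[cand, samples$sample_id, drop = FALSE]
  rpm <- rpm[order(rownames(rpm)), , drop = FALSE]
  sub <- structure(list(rpm = rpm, samples = samples),
                   class = "expression_matrix")
  det <- detection_matrix(sub, config$detection_rpm)
  med <- det$tissue_medians[, tissues, drop = FALSE]
  n_det <- det$n_detected_tissues

  pc <- config$pseudocount
  fold <- matrix(NA_real_, nrow(rpm), length(tissues),
                 dimnames = list(rownames(rpm), tissues))
  other_med <- fold
  pmat <- fold
  hte <- matrix(FALSE, nrow(rpm), length(tissues),
                dimnames = dimnames(fold))
  for (t in tissues) {
    in_t <- samples$tissue == t
    other_med[, t] <- apply(rpm[, !in_t, drop = FALSE], 1, median)
    fold[, t] <- (med[, t] + pc) / (other_med[, t] + pc)
    pmat[, t] <- wilcoxon_p_rows(rpm, in_t,
                                 alternative = config$alternative)
    comparator <- if (config$hte_comparator == "sample_max") {
      apply(rpm[, !in_t, drop = FALSE], 1, max)
    } else {
      apply(med[, setdiff(tissues, t), drop = FALSE], 1, max)
    }
    hte[, t] <- med[, t] > config$hte_fold * comparator &
      n_det <= config$hte_max_tissues
  }
  qmat <- pmat
  if (config$fdr_scope == "per_tissue") {
    for (t in tissues) qmat[, t] <- bh_adjust(pmat[, t])
  } else {
    qmat[] <- bh_adjust(as.vector(pmat))
  }
  te <- fold > config$fc_threshold & qmat < config$alpha
  n_hte <- rowSums(hte)
  cls <- matrix("none", nrow(rpm), length(tissues),
                dimnames = dimnames(fold))
  cls[te] <- "TE"
  cls[hte & n_hte == 1] <- "HTE1"
  cls[hte & n_hte == 2] <- "HTE2"

  records <- data.frame(
    locus = rep(rownames(rpm), times = length(tissues)),
    tissue = rep(tissues, each = nrow(rpm)),
    tissue_median_rpm = as.vector(med),
    other_median_rpm = as.vector(other_med),
    fold_change = as.vector(fold),
    p_value = as.vector(pmat),
    q_value = as.vector(qmat),
    n_detected_tissues = rep(unname(n_det), times = length(tissues)),
    class = as.vector(cls),
    stringsAsFactors = FALSE)
  records <- records[order(records$tissue, records$locus), , drop = FALSE]
  rownames(records) <- NULL
  tallies <- do.call(rbind, lapply(tissues, function(t) {
    r <- records[records$tissue == t, ]
    data.frame(tissue = t, TE = sum(r$class == "TE"),
               HTE2 = sum(r$class == "HTE2"),
               HTE1 = sum(r$class == "HTE1"), stringsAsFactors = FALSE)
  }))
  list(records = records, tallies = tallies, candidates = cand)
}

#' Spearman sample-correlation QC
#'
#' Pairwise Spearman rank correlation between per-sample RPM profiles,
#' reported as rho squared, with within-tissue and between-tissue-pair
#' means. Constant sample profiles have undefined correlations: they are
#' flagged and excluded from the means.
#'
#' @param expr An `expression_matrix`.
#' @return List with `matrix` (sample x sample rho^2), `within_tissue_mean`
#'   (per tissue), `between_tissue_mean` (data.frame `tissue_a`,
#'   `tissue_b`, `mean_rho2`), `flagged_constant` (sample ids).
#' @export
spearman_qc <- function(expr) {
  rpm <- expr$rpm
  if (ncol(rpm) < 2) stop_config("need >= 2 samples")
  const <- apply(rpm, 2, function(v) length(unique(v)) == 1)
  rho <- suppressWarnings(cor(rpm, method = "spearman"))
  rho[const, ] <- NA
  rho[, const] <- NA
  diag(rho) <- 1
  rho2 <- rho^2
  samples <- expr$samples
  tissue_of <- setNames(samples$tissue, samples$sample_id)[colnames(rpm)]
  tissues <- sort(unique(tissue_of))
  pair_mean <- function(a, b) {
    ia <- which(tissue_of == a); ib <- which(tissue_of == b)
    if (identical(a, b)) {
      if (length(ia) < 2) return(NA_real_)
      m <- rho2[ia, ia, drop = FALSE]
      mean(m[upper.tri(m)], na.rm = TRUE)
    } else {
      mean(rho2[ia, ib], na.rm = TRUE)
    }
  }
  within <- vapply(tissues, function(t) pair_mean(t, t), numeric(1))
  between <- data.frame(tissue_a = character(), tissue_b = character(),
                        mean_rho2 = numeric(), stringsAsFactors = FALSE)
  if (length(tissues) >= 2) {
    pairs <- utils::combn(tissues, 2)
    between <- data.frame(
      tissue_a = pairs[1, ], tissue_b = pairs[2, ],
      mean_rho2 = apply(pairs, 2, function(p) pair_mean(p[1], p[2])),
      stringsAsFactors = FALSE)
  }
  list(matrix = rho2, within_tissue_mean = within,
       between_tissue_mean = between,
       flagged_constant = colnames(rpm)[const])
}

#' Score loci as candidate ubiquitous reference miRNAs
#'
#' For each locus, tissue medians of RPM are summarized on the log2 scale:
#' CV% = 100 * sd / mean of log2(median RPM + 1) across tissues, and the
#' SD of the same log2 medians. A locus is a stable reference candidate
#' when CV% < 10, SD <= 1, and its mean tissue-median RPM exceeds
#' `candidate_rpm`.
#'
#' @param expr An `expression_matrix`.
#' @param candidate_rpm Abundance floor (default 100 RPM).
#' @return data.frame with `locus`, `mean_rpm`, `mean_log2_rpm`,
#'   `cv_percent`, `sd_log2`, `is_stable`.
#' @export
reference_score <- function(expr, candidate_rpm = 100) {
  if (nrow(expr$rpm) == 0) stop_config("empty expression matrix")
  med <- tissue_medians(expr$rpm, expr$samples)
  lg <- log2(med + 1)
  mean_lg <- rowMeans(lg)
  sd_lg <- apply(lg, 1, sd)
  cv <- ifelse(mean_lg > 0, 100 * sd_lg / mean_lg, Inf)
  cv[sd_lg == 0] <- 0
  mean_rpm <- rowMeans(med)
  data.frame(locus = rownames(med), mean_rpm = mean_rpm,
             mean_log2_rpm = mean_lg, cv_percent = cv, sd_log2 = sd_lg,
             is_stable = cv < 10 & sd_lg <= 1 & mean_rpm > candidate_rpm,
             row.names = NULL, stringsAsFactors = FALSE)
}
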