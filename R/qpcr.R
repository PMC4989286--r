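#' Read a qPCR plate export
#'
#' Expected CSV columns: `sample_id`, `target`, `replicate`, `ct`, and
#' optionally `context` (`tissue` or `serum`). Target aliases are
#' canonicalized (e.g. the miR-855 spelling of miR-885).
#'
#' @param path CSV path.
#' @param aliases Named character vector mapping alias -> canonical target
#'   name; default maps `"miR-855"` to `"miR-885"` (including the `cfa-`
#'   prefixed forms).
#' @return data.frame with `sample_id`, `target`, `replicate`, `ct`,
#'   `context`.
#' @export
read_ct_csv <- function(path, aliases = c("miR-855" = "miR-885",
                                          "cfa-miR-855" = "cfa-miR-885")) {
  if (!file.exists(path)) stop_config("Ct file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "target", "replicate", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_data("Ct file '", path, "' missing columns: ",
              paste(miss, collapse = ", "))
  }
  if (!"context" %in% names(df)) df$context <- "tissue"
  if (any(!is.finite(df$ct) | df$ct <= 0 | df$ct > 45)) {
    stop_data("Ct file '", path, "': Ct values must lie in (0, 45]")
  }
  hit <- df$target %in% names(aliases)
  df$target[hit] <- unname(aliases[df$target[hit]])
  df[, c("sample_id", "target", "replicate", "ct", "context")]
}

#' Average technical replicates with high-Ct censoring
#'
#' Replicate Ct values strictly greater than `ct_cutoff` are removed as
#' unreliable; the mean of the survivors is returned. When every replicate
#' is removed the measurement is censored (`NA` mean, `n_used = 0`).
#'
#' @param cts Numeric vector of replicate Ct values.
#' @param ct_cutoff Censoring cutoff (default 38; the boundary value 38.0
#'   is retained).
#' @return List with `mean_ct` (NA when censored) and `n_used`.
#' @export
average_ct <- function(cts, ct_cutoff = 38) {
  if (length(cts) == 0) stop_config("no replicate Ct values")
  keep <- cts <= ct_cutoff
  if (!any(keep)) return(list(mean_ct = NA_real_, n_used = 0L))
  list(mean_ct = mean(cts[keep]), n_used = sum(keep))
}

#' Replicate-averaged Ct table
#'
#' Applies [average_ct()] per (sample, target).
#'
#' @param ct_data data.frame as from [read_ct_csv()].
#' @param ct_cutoff Censoring cutoff (default 38).
#' @return data.frame with `sample_id`, `target`, `mean_ct`,
#'   `n_replicates_used`, `censored`.
#' @export
average_ct_table <- function(ct_data, ct_cutoff = 38) {
  key <- interaction(ct_data$sample_id, ct_data$target, drop = TRUE,
                     sep = "\r")
  rows <- lapply(split(seq_len(nrow(ct_data)), key), function(i) {
    a <- average_ct(ct_data$ct[i], ct_cutoff)
    data.frame(sample_id = ct_data$sample_id[i[1]],
               target = ct_data$target[i[1]], mean_ct = a$mean_ct,
               n_replicates_used = a$n_used, censored = a$n_used == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delta-Ct relative quantification
#'
#' For each sample, dCt(target) = mean Ct(target) - mean of the reference
#' targets' mean Cts in the same sample; relative expression is
#' 2^(-dCt). Targets or samples whose references are all censored yield
#' censored results.
#'
#' @param ct_table Output of [average_ct_table()].
#' @param references Character vector of reference (normalizer) target
#'   names; a warning is issued when fewer than 2 usable references are
#'   found in a sample.
#' @return data.frame with `sample_id`, `target`, `mean_ct`,
#'   `n_replicates_used`, `delta_ct`, `rel_expr`, `censored`,
#'   `censor_reason`.
#' @export
delta_ct <- function(ct_table, references) {
  if (length(references) < 1) stop_config("need >= 1 reference target")
  out <- ct_table[!ct_table$target %in% references, , drop = FALSE]
  out$delta_ct <- NA_real_
  out$rel_expr <- NA_real_
  out$censor_reason <- ifelse(out$censored, "target_censored", "")
  for (s in unique(out$sample_id)) {
    refs <- ct_table[ct_table$sample_id == s &
                       ct_table$target %in% references &
                       !ct_table$censored, , drop = FALSE]
    rows <- which(out$sample_id == s)
    if (nrow(refs) == 0) {
      out$censored[rows] <- TRUE
      out$censor_reason[rows] <- ifelse(
        nzchar(out$censor_reason[rows]), out$censor_reason[rows],
        "references_censored")
      next
    }
    if (nrow(refs) < 2) {
      warning("sample '", s, "': only ", nrow(refs),
              " usable reference target(s)")
    }
    ref_ct <- mean(refs$mean_ct)
    ok <- rows[!out$censored[rows]]
    out$delta_ct[ok] <- out$mean_ct[ok] - ref_ct
    out$rel_expr[ok] <- 2^(-out$delta_ct[ok])
  }
  rownames(out) <- NULL
  out
}

#' Cross-platform correlation of qPCR and sequencing expression
#'
#' Ordinary least squares of log2 relative qPCR expression on
#' log2(RPM + 1), over samples with non-censored values in both
#' platforms.
#'
#' @param rel_expr Named numeric vector: per-sample qPCR relative
#'   expression (2^-dCt) for one target; NA = censored.
#' @param rpm Named numeric vector: per-sample RPM for the matched locus.
#' @return List with `r_squared`, `slope`, `intercept`, `n`.
#' @export
platform_correlation <- function(rel_expr, rpm) {
  common <- intersect(names(rel_expr), names(rpm))
  x <- log2(rpm[common] + 1)
  y <- log2(rel_expr[common])
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop_data("need >= 3 paired non-censored samples")
  x <- x[ok]; y <- y[ok]
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0 || sd(x) == 0) 0 else cor(x, y)^2
  list(r_squared = r2, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]), n = sum(ok))
}

#' Assemble a serum biomarker panel study
#'
#' Joins replicate-averaged (and optionally reference- or plate-
#' normalized) serum qPCR measurements with per-animal clinical chemistry
#' over the study timepoints. Sample ids in the Ct data must follow
#' `"<animal>_d<day>_<phase>"` or be listed in `sample_map`.
#'
#' @param ct_data Serum Ct data (as from [read_ct_csv()]).
#' @param chemistry data.frame with `animal_id`, `day`, `phase`, `ALT`,
#'   `AST`.
#' @param references Reference target names, or `NULL` (default) for
#'   reference-free normalization against the per-sample plate median of
#'   all non-censored targets (robust to the panel's own responders;
#'   flagged in the output).
#' @param ct_cutoff Censoring cutoff (default 38).
#' @param sample_map Optional data.frame `sample_id`, `animal_id`, `day`,
#'   `phase` overriding the sample-id convention.
#' @return A `panel_study`: list with `measurements` (per animal /
#'   timepoint / target `delta_ct`, `rel_expr`, `censored`), `chemistry`,
#'   `normalization` (`"reference"` or `"plate_median"`), `panel`
#'   (targets).
#' @export
panel_study <- function(ct_data, chemistry, references = NULL,
                        ct_cutoff = 38, sample_map = NULL) {
  avg <- average_ct_table(ct_data, ct_cutoff)
  if (is.null(references)) {
    # reference-free: dCt against the plate median of usable targets
    # (median, so the panel's own responders do not drag the baseline)
    avg$delta_ct <- NA_real_
    avg$rel_expr <- NA_real_
    for (s in unique(avg$sample_id)) {
      rows <- which(avg$sample_id == s)
      usable <- rows[!avg$censored[rows]]
      if (!length(usable)) next
      plate_ref <- median(avg$mean_ct[usable])
      avg$delta_ct[usable] <- avg$mean_ct[usable] - plate_ref
      avg$rel_expr[usable] <- 2^(-avg$delta_ct[usable])
    }
    meas <- avg
    normalization <- "plate_median"
  } else {
    meas <- delta_ct(avg, references)
    normalization <- "reference"
  }
  if (is.null(sample_map)) {
    m <- regmatches(meas$sample_id,
                    regexec("^(.+)_d(\\d+)_(predose|postdose)$",
                            meas$sample_id))
    bad <- vapply(m, length, integer(1)) != 4
    if (any(bad)) {
      stop_data("sample_id not in '<animal>_d<day>_<phase>' form: ",
                meas$sample_id[bad][1])
    }
    meas$animal_id <- vapply(m, `[`, character(1), 2)
    meas$day <- as.integer(vapply(m, `[`, character(1), 3))
    meas$phase <- vapply(m, `[`, character(1), 4)
  } else {
    i <- match(meas$sample_id, sample_map$sample_id)
    if (anyNA(i)) {
      stop_data("sample_id missing from sample_map: ",
                meas$sample_id[is.na(i)][1])
    }
    meas$animal_id <- sample_map$animal_id[i]
    meas$day <- sample_map$day[i]
    meas$phase <- sample_map$phase[i]
  }
  used <- unique(meas[, c("animal_id", "day", "phase")])
  key <- function(d) paste(d$animal_id, d$day, d$phase)
  if (!all(key(used) %in% key(chemistry))) {
    stop_data("chemistry missing for some (animal, timepoint) rows")
  }
  structure(list(measurements = meas, chemistry = chemistry,
                 normalization = normalization,
                 panel = sort(unique(meas$target))),
            class = "panel_study")
}

#' Correlate a panel miRNA with clinical chemistry per animal
#'
#' For each animal, ordinary least squares of the miRNA signal
#' (-dCt by default, i.e. log2 relative expression, or linear
#' `rel_expr`) against the chemistry analyte across timepoints. Animals
#' with fewer than 3 usable timepoints are reported as not evaluable.
#'
#' @param study A [panel_study()].
#' @param target Panel miRNA name.
#' @param analyte `"ALT"` or `"AST"`.
#' @param value `"neg_delta_ct"` (default) or `"rel_expr"`.
#' @return data.frame with `animal_id`, `r_squared`, `slope`, `n`,
#'   `evaluable`.
#' @export
panel_correlate <- function(study, target, analyte = c("ALT", "AST"),
                            value = c("neg_delta_ct", "rel_expr")) {
  analyte <- match.arg(analyte)
  value <- match.arg(value)
  meas <- study$measurements[study$measurements$target == target, ,
                             drop = FALSE]
  if (nrow(meas) == 0) stop_data("target not in panel: ", target)
  chem <- study$chemistry
  i <- match(paste(meas$animal_id, meas$day, meas$phase),
             paste(chem$animal_id, chem$day, chem$phase))
  meas$analyte <- chem[[analyte]][i]
  out <- lapply(split(meas, meas$animal_id), function(d) {
    y <- if (value == "neg_delta_ct") -d$delta_ct else d$rel_expr
    ok <- !d$censored & is.finite(y) & is.finite(d$analyte)
    if (sum(ok) < 3) {
      return(data.frame(animal_id = d$animal_id[1], r_squared = NA_real_,
                        slope = NA_real_, n = sum(ok), evaluable = FALSE,
                        stringsAsFactors = FALSE))
    }
    x <- d$analyte[ok]; yy <- y[ok]
    r2 <- if (sd(yy) == 0 || sd(x) == 0) 0 else cor(x, yy)^2
    fit <- lm(yy ~ x)
    data.frame(animal_id = d$animal_id[1], r_squared = r2,
               slope = unname(coef(fit)[2]), n = sum(ok),
               evaluable = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Percent CV of reference targets across tissues
#'
#' For each target, the coefficient of variation (100 * sample SD / mean)
#' of the per-tissue mean Ct; optionally also of delta-Ct-normalized
#' values when `references` is given.
#'
#' @param ct_table Output of [average_ct_table()] for tissue samples.
#' @param tissue_of Named character vector mapping sample_id -> tissue.
#' @param targets Targets to score (default: all in `ct_table`).
#' @return data.frame with `target`, `cv_percent_ct`, `n_tissues`.
#' @export
reference_cv <- function(ct_table, tissue_of, targets = NULL) {
  targets <- targets %||% sort(unique(ct_table$target))
  out <- lapply(targets, function(tg) {
    d <- ct_table[ct_table$target == tg & !ct_table$censored, ,
                  drop = FALSE]
    d$tissue <- tissue_of[d$sample_id]
    tm <- tapply(d$mean_ct, d$tissue, mean)
    if (length(tm) < 2) stop_data("target '", tg, "': need >= 2 tissues")
    data.frame(target = tg, cv_percent_ct = 100 * sd(tm) / mean(tm),
               n_tissues = length(tm), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
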