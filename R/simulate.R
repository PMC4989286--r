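DOG_TISSUES <- c("adrenal_gland", "brain", "colon", "duodenum", "heart",
                 "jejunum", "kidney", "liver", "lung", "pancreas",
                 "sciatic_nerve", "skeletal_muscle", "skin", "spleen",
                 "stomach", "testis")

#' Simulation configuration
#'
#' Defaults mirror the tissue-atlas study design: 16 tissues with 5
#' biological replicates each, around one million assigned reads per
#' sample, overdispersed negative-binomial counts, three species' mature
#' sets with partial conservation, and a proof-of-concept injury panel
#' with 2 affected and 4 control animals over 6 timepoints.
#'
#' @param seed Base RNG seed (default 17). Each generator derives its own
#'   stream from it, so generators are reproducible independently of call
#'   order.
#' @param n_chrom,chrom_length Toy genome shape.
#' @param n_loci Number of planted miRNA loci (default 300).
#' @param locus_length_range Locus lengths sampled uniformly in this range
#'   (default 18-25 nt).
#' @param species Species codes; the first is the target species.
#' @param conservation Named fractions (`all`, `pair`, `single`) of loci
#'   conserved in all species, exactly two, or one; must sum to 1.
#' @param include_multimapper Plant one extra sequence `multimapper_copies`
#'   times to exercise the multi-location filter (default TRUE, 11 copies).
#' @param multimapper_copies See above.
#' @param tissues,replicates Tissue design (16 x 5 by default).
#' @param counts_per_sample Target library size (default 1e6).
#' @param dispersion Negative-binomial dispersion, Var = mu + disp * mu^2
#'   (default 0.1).
#' @param n_te,te_fold Planted tissue-enriched loci (default 30 at fold 10).
#' @param n_hte1,hte_fold Planted single-tissue HTE loci (default 20 at
#'   fold 50).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline RPM for
#'   unplanted loci.
#' @param te_baseline_rpm,hte_baseline_rpm Baseline RPM ranges
#'   (log-uniform) for planted TE and HTE loci; HTE baselines sit below the
#'   detection cutoff so enrichment is confined to the planted tissue.
#' @param reads_per_sample,decoy_fraction,aln_samples Read-level simulation
#'   scale: reads per sample, fraction of decoy reads (failing the overlap
#'   rule or multi-mapping), and how many samples of the design get
#'   alignment files.
#' @param qpcr_intercept,qpcr_slope,qpcr_sigma,qpcr_replicates,qpcr_ceiling
#'   Ct model: Ct = intercept - slope * log2(expression) + N(0, sigma), in
#'   `qpcr_replicates` technical replicates, capped at the instrument
#'   ceiling (40 cycles).
#' @param n_injured,n_control,panel_days Panel study design.
#' @param panel_liver_targets,panel_other_targets,panel_reference_targets
#'   Panel composition.
#' @param injury_ct_gain Cycles by which liver targets drop at full injury
#'   (default 4, i.e. 16-fold).
#' @param alt_base,alt_gain,alt_sd,ast_base,ast_gain,ast_sd Clinical
#'   chemistry model (U/L): analyte = base + gain * injury + noise.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 17,
                              n_chrom = 3, chrom_length = 30000,
                              n_loci = 300,
                              locus_length_range = c(18, 25),
                              species = c("cfa", "rno", "hsa"),
                              conservation = c(all = 0.5, pair = 0.3,
                                               single = 0.2),
                              include_multimapper = TRUE,
                              multimapper_copies = 11,
                              tissues = DOG_TISSUES, replicates = 5,
                              counts_per_sample = 1e6, dispersion = 0.1,
                              n_te = 30, te_fold = 10,
                              n_hte1 = 20, hte_fold = 50,
                              baseline_meanlog = log(100),
                              baseline_sdlog = 1.5,
                              te_baseline_rpm = c(50, 500),
                              hte_baseline_rpm = c(10, 40),
                              reads_per_sample = 20000,
                              decoy_fraction = 0.05, aln_samples = 4,
                              qpcr_intercept = 36, qpcr_slope = 1,
                              qpcr_sigma = 0.15, qpcr_replicates = 3,
                              qpcr_ceiling = 40,
                              n_injured = 2, n_control = 4,
                              panel_days = c(1, 7, 14),
                              panel_liver_targets = c("miR-122", "miR-885"),
                              panel_other_targets = c("miR-1", "miR-206",
                                                      "miR-216a"),
                              panel_reference_targets = c("miR-16",
                                                          "miR-29a",
                                                          "miR-186"),
                              injury_ct_gain = 4,
                              alt_base = 30, alt_gain = 250, alt_sd = 6,
                              ast_base = 40, ast_gain = 300, ast_sd = 8) {
  if (abs(sum(conservation) - 1) > 1e-8) {
    stop_config("conservation fractions must sum to 1")
  }
  if (n_te + n_hte1 > n_loci) stop_config("more planted loci than loci")
  if (counts_per_sample <= 0 || reads_per_sample <= 0) {
    stop_config("library sizes must be positive")
  }
  if (dispersion < 0) stop_config("dispersion must be >= 0")
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    stop_config("decoy_fraction must be in [0, 1]")
  }
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  cfg
}

# enrichment and baseline planting shared by genome-based and counts-only
# truth construction; caller controls the RNG state
plant_enrichment <- function(cfg, locus_ids) {
  n <- length(locus_ids)
  planted <- sample(n, cfg$n_hte1 + cfg$n_te)
  hte_idx <- planted[seq_len(cfg$n_hte1)]
  te_idx <- setdiff(planted, hte_idx)
  baseline <- exp(rnorm(n, cfg$baseline_meanlog, cfg$baseline_sdlog))
  lunif <- function(k, range) {
    exp(runif(k, log(range[1]), log(range[2])))
  }
  baseline[hte_idx] <- lunif(length(hte_idx), cfg$hte_baseline_rpm)
  baseline[te_idx] <- lunif(length(te_idx), cfg$te_baseline_rpm)
  # rescale unplanted loci so nominal RPM values sum to one million
  null_idx <- setdiff(seq_len(n), planted)
  target_null <- 1e6 - sum(baseline[planted])
  baseline[null_idx] <- baseline[null_idx] *
    target_null / sum(baseline[null_idx])
  enr <- data.frame(locus_id = locus_ids, tissue = NA_character_,
                    fold = 1, intended_class = "none",
                    stringsAsFactors = FALSE)
  enr$tissue[hte_idx] <- sample(cfg$tissues, length(hte_idx),
                                replace = TRUE)
  enr$fold[hte_idx] <- cfg$hte_fold
  enr$intended_class[hte_idx] <- "HTE1"
  enr$tissue[te_idx] <- sample(cfg$tissues, length(te_idx), replace = TRUE)
  enr$fold[te_idx] <- cfg$te_fold
  enr$intended_class[te_idx] <- "TE"
  list(enrichment = enr,
       baseline = data.frame(locus_id = locus_ids,
                             baseline_rpm = baseline,
                             stringsAsFactors = FALSE))
}

#' Generate a toy genome with planted miRNA loci and species mature sets
#'
#' Plants `n_loci` non-overlapping loci (random strand) in a random
#' genome; each locus sequence is verified to occur exactly once
#' genome-wide across both strands. Species mature sets are sampled from
#' the loci according to the conservation fractions (the target species'
#' name is used whenever it carries the sequence). Optionally one extra
#' sequence is planted `multimapper_copies` times to exercise the
#' multi-location exclusion. Enrichment ground truth for the count
#' generator is planted at the same time.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genome` (`DNAStringSet`), `species_sets` (list of
#'   mature-sequence data.frames, one per species) and `truth` (planted
#'   loci, species membership, multimapper, enrichment, baseline).
#' @export
gen_genome_and_annotation <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 1L)
  slot_pitch <- 3L * cfg$locus_length_range[2]
  slots <- do.call(rbind, lapply(seq_len(cfg$n_chrom), function(k) {
    starts <- seq(slot_pitch, cfg$chrom_length - slot_pitch,
                  by = slot_pitch)
    data.frame(chrom = sprintf("chr%d", k), start = starts,
               stringsAsFactors = FALSE)
  }))
  n_multi <- if (cfg$include_multimapper) cfg$multimapper_copies else 0L
  if (cfg$n_loci + n_multi > nrow(slots)) {
    stop_data("infeasible placement: ", cfg$n_loci + n_multi,
              " loci do not fit ", nrow(slots), " genome slots")
  }
  chrom_seq <- lapply(seq_len(cfg$n_chrom),
                      function(k) strsplit(random_dna(cfg$chrom_length),
                                           "")[[1]])
  names(chrom_seq) <- sprintf("chr%d", seq_len(cfg$n_chrom))
  pick <- slots[sample(nrow(slots), cfg$n_loci + n_multi), , drop = FALSE]
  locus_rows <- pick[seq_len(cfg$n_loci), , drop = FALSE]
  multi_rows <- pick[setdiff(seq_len(nrow(pick)), seq_len(cfg$n_loci)), ,
                     drop = FALSE]
  lens <- sample(seq(cfg$locus_length_range[1], cfg$locus_length_range[2]),
                 cfg$n_loci, replace = TRUE)
  strands <- sample(c("+", "-"), cfg$n_loci, replace = TRUE)

  genome_string <- function() {
    Biostrings::DNAStringSet(vapply(chrom_seq, paste, character(1),
                                    collapse = ""))
  }
  substring_at <- function(chrom, start, len) {
    paste(chrom_seq[[chrom]][(start + 1):(start + len)], collapse = "")
  }
  count_occurrences <- function(seqs) {
    g <- genome_string()
    vapply(seqs, function(s) {
      p <- Biostrings::DNAString(s)
      sum(Biostrings::vcountPattern(p, g)) +
        sum(Biostrings::vcountPattern(Biostrings::reverseComplement(p), g))
    }, integer(1))
  }

  # locus mature sequence read off the genome (reverse-complement on -);
  # resample windows until every locus sequence is unique genome-wide
  locus_seq <- function(i) {
    s <- substring_at(locus_rows$chrom[i], locus_rows$start[i], lens[i])
    if (strands[i] == "-") revcomp(s) else s
  }
  seqs <- vapply(seq_len(cfg$n_loci), locus_seq, character(1))
  for (iter in seq_len(20)) {
    occ <- count_occurrences(seqs)
    bad <- which(occ != 1L | duplicated(seqs) |
                   duplicated(seqs, fromLast = TRUE))
    if (!length(bad)) break
    if (iter == 20) stop_data("could not plant unique locus sequences")
    for (i in bad) {
      w <- (locus_rows$start[i] + 1):(locus_rows$start[i] + lens[i])
      chrom_seq[[locus_rows$chrom[i]]][w] <-
        sample(c("A", "C", "G", "T"), lens[i], replace = TRUE)
      seqs[i] <- locus_seq(i)
    }
  }

  multimapper <- NULL
  if (n_multi > 0) {
    mlen <- cfg$locus_length_range[1] + 2L
    mseq <- substring_at(multi_rows$chrom[1], multi_rows$start[1], mlen)
    for (j in seq_len(nrow(multi_rows))) {
      w <- (multi_rows$start[j] + 1):(multi_rows$start[j] + mlen)
      chrom_seq[[multi_rows$chrom[j]]][w] <- strsplit(mseq, "")[[1]]
    }
    # re-verify the unique loci against the updated genome
    occ <- count_occurrences(seqs)
    if (any(occ != 1L)) stop_data("multimapper planting broke uniqueness")
    multimapper <- list(
      sequence = mseq, n_copies = n_multi,
      positions = data.frame(chrom = multi_rows$chrom,
                             start = multi_rows$start,
                             end = multi_rows$start + mlen, strand = "+",
                             stringsAsFactors = FALSE))
  }

  locus_ids <- sprintf("mir-%03d", seq_len(cfg$n_loci))
  cat_draw <- sample(names(cfg$conservation), cfg$n_loci, replace = TRUE,
                     prob = cfg$conservation)
  membership <- lapply(seq_len(cfg$n_loci), function(i) {
    switch(cat_draw[i],
           all = cfg$species,
           pair = sort(sample(cfg$species, 2)),
           single = sample(cfg$species, 1))
  })
  loci <- data.frame(locus_id = locus_ids, chrom = locus_rows$chrom,
                     start = locus_rows$start,
                     end = locus_rows$start + lens, strand = strands,
                     length = lens, sequence = seqs,
                     species = vapply(membership, paste, character(1),
                                      collapse = ","),
                     stringsAsFactors = FALSE)
  species_sets <- lapply(cfg$species, function(sp) {
    idx <- which(vapply(membership, function(m) sp %in% m, logical(1)))
    df <- data.frame(
      name = sprintf("%s-miR-%d", sp, idx), species = sp,
      sequence = seqs[idx], stringsAsFactors = FALSE)
    if (!is.null(multimapper)) {
      df <- rbind(df, data.frame(name = sprintf("%s-miR-multi", sp),
                                 species = sp,
                                 sequence = multimapper$sequence,
                                 stringsAsFactors = FALSE))
    }
    df
  })
  names(species_sets) <- cfg$species
  planted <- plant_enrichment(cfg, locus_ids)
  truth <- list(loci = loci, multimapper = multimapper,
                enrichment = planted$enrichment,
                baseline = planted$baseline, seed = cfg$seed)
  list(genome = genome_string(), species_sets = species_sets,
       truth = truth)
}

# expected per-locus representative names under the default precedence
# (target species first): used to map planted loci to annotation loci
planted_locus_names <- function(cfg, truth) {
  vapply(seq_len(nrow(truth$loci)), function(i) {
    sp <- strsplit(truth$loci$species[i], ",")[[1]]
    best <- sp[order(match(sp, cfg$species))][1]
    sprintf("%s-miR-%d", best, i)
  }, character(1))
}

#' Sample metadata for the simulated atlas design
#'
#' @param cfg A [simulation_config()].
#' @return data.frame with `sample_id`, `animal_id`, `tissue`.
#' @export
sim_sample_meta <- function(cfg = simulation_config()) {
  grid <- expand.grid(animal = seq_len(cfg$replicates),
                      tissue = cfg$tissues, stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_dog%d", grid$tissue, grid$animal),
             animal_id = sprintf("dog%d", grid$animal),
             tissue = grid$tissue, stringsAsFactors = FALSE)
}

#' Simulate the tissue count matrix with planted enrichment
#'
#' Counts are negative binomial with mean `lib_size * p[i, j]`
#' (Var = mu + dispersion * mu^2), where `p[i, j]` is the locus baseline
#' relative abundance multiplied by the planted fold when sample j's
#' tissue is locus i's enriched tissue, renormalized per sample.
#'
#' @param cfg A [simulation_config()].
#' @param truth Optional planted truth from [gen_genome_and_annotation()];
#'   when `NULL`, a counts-only truth (locus ids `locus_001`, ...) is
#'   planted.
#' @return List with `counts` (a `count_matrix`), `samples`, `truth`.
#' @export
gen_counts <- function(cfg = simulation_config(), truth = NULL) {
  set.seed(cfg$seed + 2L)
  if (is.null(truth)) {
    locus_ids <- sprintf("locus_%03d", seq_len(cfg$n_loci))
    planted <- plant_enrichment(cfg, locus_ids)
    truth <- list(loci = NULL, enrichment = planted$enrichment,
                  baseline = planted$baseline, seed = cfg$seed)
  }
  locus_ids <- truth$baseline$locus_id
  samples <- sim_sample_meta(cfg)
  base <- truth$baseline$baseline_rpm
  enr <- truth$enrichment
  mu_rel <- matrix(base, nrow = length(locus_ids), ncol = nrow(samples),
                   dimnames = list(locus_ids, samples$sample_id))
  for (k in which(enr$intended_class != "none")) {
    cols <- samples$tissue == enr$tissue[k]
    mu_rel[k, cols] <- mu_rel[k, cols] * enr$fold[k]
  }
  p <- sweep(mu_rel, 2, colSums(mu_rel), "/")
  lib <- round(cfg$counts_per_sample *
                 exp(rnorm(nrow(samples), 0, 0.05)))
  mu <- sweep(p, 2, lib, "*")
  counts <- matrix(
    if (cfg$dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
    } else {
      stats::rpois(length(mu), lambda = mu)
    },
    nrow = nrow(mu), dimnames = dimnames(mu))
  cm <- structure(list(counts = counts, samples = samples,
                       assigned_total = colSums(counts),
                       aligned_total = colSums(counts),
                       parameters = list(simulated = TRUE)),
                  class = "count_matrix")
  list(counts = cm, samples = samples, truth = truth)
}

#' Simulate per-sample read alignments over the planted loci
#'
#' For each of the first `aln_samples` samples of the design, reads are
#' apportioned to loci proportionally to expression (baseline times
#' planted fold) and placed with a uniform offset small enough to keep at
#' least 70% overlap with the locus. A `decoy_fraction` of reads fails
#' quantification by construction: half are shifted a full locus length
#' away (zero overlap) and half (when a multimapper is planted) sit on the
#' multimapper copies with `n_hits` above the location cutoff.
#'
#' @param cfg A [simulation_config()].
#' @param truth Planted truth from [gen_genome_and_annotation()].
#' @return List with `alignments` (placement data.frame for all samples),
#'   `samples` (metadata subset), `expected_counts` (loci x samples matrix
#'   of non-decoy reads generated).
#' @export
gen_read_alignments <- function(cfg = simulation_config(), truth) {
  if (is.null(truth$loci)) stop_config("truth has no placed loci")
  set.seed(cfg$seed + 3L)
  samples <- utils::head(sim_sample_meta(cfg), cfg$aln_samples)
  loci <- truth$loci
  base <- truth$baseline$baseline_rpm
  enr <- truth$enrichment
  has_multi <- !is.null(truth$multimapper)
  expected <- matrix(0L, nrow(loci), nrow(samples),
                     dimnames = list(loci$locus_id, samples$sample_id))
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    w <- base
    hit <- enr$intended_class != "none" & enr$tissue == samples$tissue[j]
    w[which(hit)] <- w[which(hit)] * enr$fold[which(hit)]
    n_decoy <- round(cfg$reads_per_sample * cfg$decoy_fraction)
    n_real <- cfg$reads_per_sample - n_decoy
    n_per_locus <- as.vector(stats::rmultinom(1, n_real, w / sum(w)))
    expected[, j] <- n_per_locus
    li <- rep(seq_len(nrow(loci)), n_per_locus)
    real <- NULL
    if (length(li)) {
      L <- loci$length[li]
      max_off <- floor((1 - 0.7) * L)
      off <- floor(runif(length(li), -max_off, max_off + 1))
      real <- data.frame(chrom = loci$chrom[li],
                         start = loci$start[li] + off,
                         end = loci$end[li] + off,
                         strand = loci$strand[li], n_hits = 1L,
                         stringsAsFactors = FALSE)
    }
    decoys <- NULL
    if (n_decoy > 0) {
      n_mm <- if (has_multi) n_decoy %/% 2 else 0L
      n_shift <- n_decoy - n_mm
      si <- sample(nrow(loci), n_shift, replace = TRUE)
      shift <- data.frame(chrom = loci$chrom[si],
                          start = loci$end[si],
                          end = loci$end[si] + loci$length[si],
                          strand = loci$strand[si], n_hits = 1L,
                          stringsAsFactors = FALSE)
      decoys <- shift
      if (n_mm > 0) {
        mp <- truth$multimapper$positions
        mi <- sample(nrow(mp), n_mm, replace = TRUE)
        mm <- data.frame(chrom = mp$chrom[mi], start = mp$start[mi],
                         end = mp$end[mi], strand = mp$strand[mi],
                         n_hits = truth$multimapper$n_copies,
                         stringsAsFactors = FALSE)
        decoys <- rbind(decoys, mm)
      }
    }
    aln <- rbind(real, decoys)
    aln$read_id <- sprintf("%s_r%06d", samples$sample_id[j],
                           seq_len(nrow(aln)))
    aln$sample_id <- samples$sample_id[j]
    out[[j]] <- aln[, c("read_id", "chrom", "start", "end", "strand",
                        "n_hits", "sample_id")]
  }
  list(alignments = do.call(rbind, out), samples = samples,
       expected_counts = expected)
}

#' Simulate qPCR Ct data from an expression matrix
#'
#' Replicate Ct = intercept - slope * log2(expression) + N(0, sigma),
#' capped at the instrument ceiling (zero expression is reported at the
#' ceiling). Values above the ceiling are written as the ceiling; the
#' analysis-stage censoring at 38 cycles is applied downstream, not here.
#'
#' @param cfg A [simulation_config()].
#' @param expression Numeric matrix (targets x samples) of positive
#'   expression values (e.g. RPM).
#' @param targets Optional subset of rownames to model.
#' @param context `"tissue"` or `"serum"` label for the records.
#' @return data.frame in plate-export layout: `sample_id`, `target`,
#'   `replicate`, `ct`, `context`.
#' @export
gen_qpcr <- function(cfg = simulation_config(), expression,
                     targets = rownames(expression),
                     context = "tissue") {
  set.seed(cfg$seed + 4L)
  expression <- expression[targets, , drop = FALSE]
  grid <- expand.grid(replicate = seq_len(cfg$qpcr_replicates),
                      sample_id = colnames(expression),
                      target = targets, stringsAsFactors = FALSE)
  expr <- expression[cbind(grid$target, grid$sample_id)]
  ct_true <- ifelse(expr > 0,
                    cfg$qpcr_intercept - cfg$qpcr_slope * log2(expr),
                    Inf)
  ct <- ct_true + rnorm(nrow(grid), 0, cfg$qpcr_sigma)
  ct <- pmin(ct, cfg$qpcr_ceiling)
  ct <- pmax(ct, 1)
  data.frame(sample_id = grid$sample_id, target = grid$target,
             replicate = grid$replicate, ct = ct, context = context,
             stringsAsFactors = FALSE)
}

#' Simulate a proof-of-concept serum biomarker panel study
#'
#' Injured animals carry a rising latent injury trajectory over the
#' timepoints (days x predose/postdose) that drives both a drop in liver
#' target Ct (elevated circulating miRNA) and elevated ALT/AST, each with
#' independent noise; control animals stay at baseline. Non-liver panel
#' targets and reference targets are unaffected.
#'
#' @param cfg A [simulation_config()].
#' @return List with `ct` (serum plate export), `chemistry` (`animal_id`,
#'   `day`, `phase`, `ALT`, `AST`), `injury_profile` (latent injury per
#'   animal and timepoint), `injured` / `control` animal ids.
#' @export
gen_panel_study <- function(cfg = simulation_config()) {
  set.seed(cfg$seed + 5L)
  n_anim <- cfg$n_injured + cfg$n_control
  animals <- sprintf("dog%d", seq_len(n_anim))
  injured <- animals[seq_len(cfg$n_injured)]
  tp <- expand.grid(phase = c("predose", "postdose"),
                    day = cfg$panel_days, stringsAsFactors = FALSE)
  tp <- tp[order(tp$day, match(tp$phase, c("predose", "postdose"))), ]
  shape <- seq(0, 1, length.out = nrow(tp))^1.5
  prof <- do.call(rbind, lapply(animals, function(a) {
    sev <- if (a %in% injured) runif(1, 0.8, 1.2) else 0
    data.frame(animal_id = a, day = tp$day, phase = tp$phase,
               injury = sev * shape, stringsAsFactors = FALSE)
  }))
  prof$sample_id <- sprintf("%s_d%d_%s", prof$animal_id, prof$day,
                            prof$phase)
  chemistry <- data.frame(
    animal_id = prof$animal_id, day = prof$day, phase = prof$phase,
    ALT = cfg$alt_base + cfg$alt_gain * prof$injury +
      rnorm(nrow(prof), 0, cfg$alt_sd),
    AST = cfg$ast_base + cfg$ast_gain * prof$injury +
      rnorm(nrow(prof), 0, cfg$ast_sd),
    stringsAsFactors = FALSE)
  chemistry$ALT <- pmax(chemistry$ALT, 1)
  chemistry$AST <- pmax(chemistry$AST, 1)
  # liver targets start high (low abundance in healthy serum) and drop
  # with injury; tiers are spaced so the plate median always falls on a
  # flat target, keeping reference-free normalization honest
  base_ct <- c(setNames(rep(36, length(cfg$panel_liver_targets)),
                        cfg$panel_liver_targets),
               setNames(rep(30, length(cfg$panel_other_targets)),
                        cfg$panel_other_targets),
               setNames(rep(25, length(cfg$panel_reference_targets)),
                        cfg$panel_reference_targets))
  rows <- expand.grid(i = seq_len(nrow(prof)),
                      target = names(base_ct),
                      replicate = seq_len(cfg$qpcr_replicates),
                      stringsAsFactors = FALSE)
  liver <- rows$target %in% cfg$panel_liver_targets
  mu_ct <- base_ct[rows$target] -
    ifelse(liver, cfg$injury_ct_gain * prof$injury[rows$i], 0)
  ct <- mu_ct + rnorm(nrow(rows), 0, cfg$qpcr_sigma)
  ct <- pmax(pmin(ct, cfg$qpcr_ceiling), 1)
  ct_df <- data.frame(sample_id = prof$sample_id[rows$i],
                      target = rows$target, replicate = rows$replicate,
                      ct = unname(ct), context = "serum",
                      stringsAsFactors = FALSE)
  ct_df <- ct_df[order(ct_df$sample_id, ct_df$target, ct_df$replicate), ]
  rownames(ct_df) <- NULL
  list(ct = ct_df, chemistry = chemistry,
       injury_profile = prof[, c("animal_id", "day", "phase", "injury")],
       injured = injured, control = setdiff(animals, injured))
}

#' Write a full simulated study to disk
#'
#' Produces every input the pipeline consumes: `genome.fa`, per-species
#' mature FASTAs, per-sample alignment BED files, `samples.tsv`,
#' `counts.tsv`, tissue qPCR `ct.csv`, serum `serum_ct.csv` plus
#' `chem.csv`, and the planted ground truth as `truth.json`. All outputs
#' are byte-identical across reruns with the same configuration.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the written `paths` and the in-memory
#'   `truth`.
#' @export
simulate_atlas <- function(cfg = simulation_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- gen_genome_and_annotation(cfg)
  paths <- c(genome = file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(gen$genome, paths[["genome"]])
  for (sp in names(gen$species_sets)) {
    s <- gen$species_sets[[sp]]
    p <- file.path(dir, sprintf("mature_%s.fa", sp))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(s$sequence, s$name)), p)
    paths[[paste0("mature_", sp)]] <- p
  }
  cnt <- gen_counts(cfg, gen$truth)
  paths[["samples"]] <- file.path(dir, "samples.tsv")
  write_tsv(cnt$samples, paths[["samples"]])
  paths[["counts"]] <- file.path(dir, "counts.tsv")
  write_matrix_tsv(cnt$counts$counts, paths[["counts"]])
  aln <- gen_read_alignments(cfg, gen$truth)
  aln_dir <- file.path(dir, "aln")
  dir.create(aln_dir, showWarnings = FALSE)
  for (s in aln$samples$sample_id) {
    a <- aln$alignments[aln$alignments$sample_id == s, , drop = FALSE]
    p <- file.path(aln_dir, paste0(s, ".bed"))
    write.table(a[, c("chrom", "start", "end", "read_id", "n_hits",
                      "strand")],
                p, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, eol = "\n")
    paths[[paste0("aln_", s)]] <- p
  }
  rpm <- rpm_normalize(cnt$counts)
  qp_targets <- utils::head(rownames(rpm$rpm), 8)
  qp <- gen_qpcr(cfg, rpm$rpm, targets = qp_targets)
  paths[["ct"]] <- file.path(dir, "ct.csv")
  utils::write.csv(qp, paths[["ct"]], row.names = FALSE, quote = FALSE)
  panel <- gen_panel_study(cfg)
  paths[["serum_ct"]] <- file.path(dir, "serum_ct.csv")
  utils::write.csv(panel$ct, paths[["serum_ct"]], row.names = FALSE,
                   quote = FALSE)
  paths[["chem"]] <- file.path(dir, "chem.csv")
  utils::write.csv(panel$chemistry, paths[["chem"]], row.names = FALSE,
                   quote = FALSE)
  truth <- gen$truth
  truth$injury_profile <- panel$injury_profile
  truth$injured_animals <- panel$injured
  paths[["truth"]] <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(paths = paths, truth = truth))
}
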