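small_cfg <- function(...) {
  defaults <- list(seed = 19, n_loci = 30, n_chrom = 2,
                   chrom_length = 5000, n_te = 4, n_hte1 = 3,
                   tissues = c("brain", "liver", "heart", "kidney"),
                   replicates = 3, counts_per_sample = 1e5,
                   reads_per_sample = 5000, aln_samples = 3)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

truth_annotation <- function(truth) {
  structure(list(loci = data.frame(
    chrom = truth$loci$chrom, start = truth$loci$start,
    end = truth$loci$end, strand = truth$loci$strand,
    name = truth$loci$locus_id, species_provenance = truth$loci$species,
    members = truth$loci$locus_id, stringsAsFactors = FALSE),
    genome_id = "sim", parameters = list()), class = "annotation_set")
}

test_that("simulated study output is byte-identical across reruns", {
  d1 <- tempfile(); d2 <- tempfile()
  cfg <- small_cfg()
  simulate_atlas(cfg, d1)
  simulate_atlas(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  m1 <- tools::md5sum(file.path(d1, f1))
  m2 <- tools::md5sum(file.path(d2, f2))
  expect_equal(unname(m1), unname(m2))
  # a different seed changes the genome
  d3 <- tempfile()
  simulate_atlas(simulation_config(seed = 20, n_loci = 30, n_chrom = 2,
                                   chrom_length = 5000, n_te = 4,
                                   n_hte1 = 3,
                                   tissues = c("brain", "liver", "heart",
                                               "kidney"),
                                   replicates = 3,
                                   counts_per_sample = 1e5,
                                   reads_per_sample = 5000,
                                   aln_samples = 3), d3)
  expect_false(unname(tools::md5sum(file.path(d3, "genome.fa"))) ==
                 unname(m1[which(f1 == "genome.fa")]))
})

test_that("planted genome files round-trip through the package readers", {
  d <- tempfile()
  cfg <- small_cfg()
  sim <- simulate_atlas(cfg, d)
  gen <- gen_genome_and_annotation(cfg)
  mat <- load_mature_fasta(file.path(d, "mature_cfa.fa"), "cfa")
  expect_equal(mat$sequence, gen$species_sets$cfa$sequence)
  g <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(as.character(g), as.character(gen$genome))
  counts <- read.table(file.path(d, "counts.tsv"), sep = "\t",
                       header = TRUE, check.names = FALSE)
  expect_equal(nrow(counts), cfg$n_loci)
  aln <- read_alignments_bed(
    list.files(file.path(d, "aln"), full.names = TRUE)[1], "s")
  expect_true(all(aln$end > aln$start))
})

test_that("planted mature sequences sit verbatim at their loci", {
  gen <- gen_genome_and_annotation(small_cfg())
  g <- gen$genome
  for (i in seq_len(10)) {
    l <- gen$truth$loci[i, ]
    sub <- as.character(Biostrings::subseq(g[[l$chrom]], l$start + 1, l$end))
    if (l$strand == "-") {
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    }
    expect_equal(sub, l$sequence)
  }
})

test_that("conservation fractions drive species membership", {
  cfg0 <- simulation_config(seed = 31, n_loci = 40, n_chrom = 2,
                            chrom_length = 6000,
                            conservation = c(all = 0, pair = 0, single = 1),
                            n_te = 0, n_hte1 = 0)
  gen <- gen_genome_and_annotation(cfg0)
  counts <- vapply(strsplit(gen$truth$loci$species, ","), length,
                   integer(1))
  expect_true(all(counts == 1))
  cons <- consolidate_sequences(gen$species_sets,
                                species_precedence = cfg0$species)
  # no conservation: one consolidated record per planted locus (plus the
  # multimapper shared across species) with singleton provenance
  planted <- cons[cons$sequence %in% gen$truth$loci$sequence, ]
  expect_true(all(lengths(planted$species_provenance) == 1))
  cfg1 <- simulation_config(seed = 31, n_loci = 40, n_chrom = 2,
                            chrom_length = 6000,
                            conservation = c(all = 1, pair = 0, single = 0),
                            n_te = 0, n_hte1 = 0)
  gen1 <- gen_genome_and_annotation(cfg1)
  expect_equal(nrow(gen1$species_sets$cfa), nrow(gen1$species_sets$hsa))
})

test_that("decoy-free alignments are counted back exactly", {
  cfg <- small_cfg(decoy_fraction = 0)
  gen <- gen_genome_and_annotation(cfg)
  aln <- gen_read_alignments(cfg, gen$truth)
  cm <- assign_reads(aln$alignments, truth_annotation(gen$truth),
                     aln$samples)
  expect_equal(unname(cm$counts), unname(aln$expected_counts))
  expect_equal(unname(colSums(cm$counts)),
               rep(cfg$reads_per_sample, nrow(aln$samples)))
})

test_that("pure-decoy alignments produce zero counts", {
  cfg <- small_cfg(decoy_fraction = 1)
  gen <- gen_genome_and_annotation(cfg)
  aln <- gen_read_alignments(cfg, gen$truth)
  cm <- assign_reads(aln$alignments, truth_annotation(gen$truth),
                     aln$samples)
  expect_equal(sum(cm$counts), 0)
  # multimapper decoys carry n_hits above the cutoff
  expect_true(any(aln$alignments$n_hits == cfg$multimapper_copies))
})

test_that("count simulation approaches Poisson as dispersion vanishes", {
  cfg <- small_cfg(dispersion = 0, counts_per_sample = 5e5)
  cnt <- gen_counts(cfg)
  truth <- cnt$truth
  base <- truth$baseline$baseline_rpm
  enr <- truth$enrichment
  mu_rel <- matrix(base, length(base), nrow(cnt$samples))
  for (k in which(enr$intended_class != "none")) {
    mu_rel[k, cnt$samples$tissue == enr$tissue[k]] <-
      base[k] * enr$fold[k]
  }
  p <- sweep(mu_rel, 2, colSums(mu_rel), "/")
  lib <- cnt$counts$assigned_total
  mu <- sweep(p, 2, lib, "*")
  z <- abs(cnt$counts$counts - mu) / sqrt(pmax(mu, 1e-9))
  expect_gt(mean(z <= 3), 0.99)
})

test_that("unplanted loci have comparable medians across tissues", {
  cfg <- simulation_config(seed = 23, n_loci = 80, n_te = 0, n_hte1 = 0,
                           tissues = c("a", "b", "c", "d"),
                           replicates = 5, counts_per_sample = 1e6,
                           dispersion = 0.05)
  cnt <- gen_counts(cfg)
  expr <- rpm_normalize(cnt$counts)
  med <- sapply(unique(cnt$samples$tissue), function(t) {
    apply(expr$rpm[, cnt$samples$tissue == t], 1, median)
  })
  abundant <- rowMeans(med) >= 100
  ratio <- apply(med[abundant, ], 1, max) / apply(med[abundant, ], 1, min)
  expect_true(all(ratio < 2))
})

test_that("qPCR simulation is deterministic and censors low expression", {
  cfg <- small_cfg()
  expr <- matrix(c(1000, 0.001), 1, 2,
                 dimnames = list("tgt", c("hi", "lo")))
  a <- gen_qpcr(cfg, expr)
  b <- gen_qpcr(cfg, expr)
  expect_identical(a, b)
  avg <- average_ct_table(a)
  expect_false(avg$censored[avg$sample_id == "hi"])
  expect_true(avg$censored[avg$sample_id == "lo"])  # Ct ~ 46 -> capped 40 -> cut
  expect_true(all(a$ct <= cfg$qpcr_ceiling))
})

test_that("panel simulation separates injured from control animals", {
  pan <- gen_panel_study(simulation_config(seed = 17))
  st <- panel_study(pan$ct, pan$chemistry)
  liver <- panel_correlate(st, "miR-122", "ALT")
  inj <- liver$r_squared[liver$animal_id %in% pan$injured]
  ctl <- liver$r_squared[liver$animal_id %in% pan$control]
  expect_true(all(inj >= 0.7))
  expect_gt(min(inj), max(ctl))
  # control liver delta-Ct stays within a noise band
  m <- st$measurements
  ctl_dct <- m$delta_ct[m$target == "miR-122" &
                          m$animal_id %in% pan$control]
  expect_lt(diff(range(ctl_dct)), 1)
})
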