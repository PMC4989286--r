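test_that("mature FASTA loading normalizes RNA records and validates", {
  p <- write_fasta(c(m1 = "ugaggua"))
  got <- load_mature_fasta(p, "cfa")
  expect_equal(got$name, "m1")
  expect_equal(got$sequence, "TGAGGTA")
  expect_equal(got$species, "cfa")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(nrow(load_mature_fasta(empty, "cfa")), 0)

  dup <- write_fasta(c(m1 = "ACGTACGTACGTACG", m1 = "TTTTACGTACGTACG"))
  expect_error(load_mature_fasta(dup, "cfa"), "duplicate")

  bad <- write_fasta(c(m1 = "ACGTXACGT"))
  expect_error(load_mature_fasta(bad, "cfa"), "outside")

  # headers are truncated at whitespace, miRBase style
  p2 <- tempfile(fileext = ".fa")
  writeLines(">cfa-miR-122-5p MIMAT0006779 Canis familiaris\nuggagugugacaaugguguuug", p2)
  expect_equal(load_mature_fasta(p2, "cfa")$name, "cfa-miR-122-5p")
})

test_that("consolidation collapses conserved sequences with full membership", {
  dog <- data.frame(name = "d1", species = "cfa", sequence = "ACGT")
  rat <- data.frame(name = "r1", species = "rno", sequence = "ACGT")
  hum <- data.frame(name = "h1", species = "hsa", sequence = "ACGT")
  got <- consolidate_sequences(list(dog, rat, hum))
  expect_equal(nrow(got), 1)
  expect_equal(length(got$member_names[[1]]), 3)
  expect_equal(got$species_provenance[[1]], c("cfa", "hsa", "rno"))

  dog2 <- data.frame(name = c("dA", "dC"), species = "cfa",
                     sequence = c("AAAA", "CCCC"))
  rat2 <- data.frame(name = "rC", species = "rno", sequence = "CCCC")
  got2 <- consolidate_sequences(list(dog2, rat2))
  expect_equal(nrow(got2), 2)
  cc <- got2[got2$sequence == "CCCC", ]
  expect_setequal(cc$member_species[[1]], c("cfa", "rno"))

  # pairwise-distinct sequences stay distinct
  sets <- lapply(1:3, function(k) {
    data.frame(name = paste0("s", k, "_", 1:2),
               species = c("cfa", "rno", "hsa")[k],
               sequence = c(paste0(strrep("A", k), "CGTT"),
                            paste0(strrep("G", k), "CTTA")))
  })
  expect_equal(nrow(consolidate_sequences(sets)), 6)
})

test_that("consolidation is idempotent and order-independent", {
  set.seed(11)
  sets <- lapply(c("cfa", "rno", "hsa"), function(sp) {
    data.frame(name = paste0(sp, "-m", 1:8), species = sp,
               sequence = replicate(8, paste(
                 sample(c("A", "C", "G", "T"), 16, TRUE), collapse = "")),
               stringsAsFactors = FALSE)
  })
  # force sharing
  sets[[2]]$sequence[1:3] <- sets[[1]]$sequence[1:3]
  sets[[3]]$sequence[2:4] <- sets[[1]]$sequence[2:4]
  prec <- c("cfa", "rno", "hsa")
  a <- consolidate_sequences(sets, species_precedence = prec)
  b <- consolidate_sequences(rev(sets), species_precedence = prec)
  key <- function(x) x[order(x$sequence), c("sequence", "representative_name")]
  expect_equal(key(a), key(b), ignore_attr = TRUE)
  # every distinct input sequence appears exactly once, total preserved
  all_seq <- unique(unlist(lapply(sets, `[[`, "sequence")))
  expect_setequal(a$sequence, all_seq)
  expect_equal(sum(lengths(a$member_names)),
               sum(vapply(sets, nrow, integer(1))))
  # idempotent: re-consolidating the representatives changes nothing
  again <- consolidate_sequences(
    data.frame(name = a$representative_name,
               species = vapply(a$member_species, `[`, "", 1),
               sequence = a$sequence), species_precedence = prec)
  expect_setequal(again$sequence, a$sequence)
})

test_that("duplicate (name, species) pairs are rejected", {
  s <- data.frame(name = c("m1", "m1"), species = "cfa",
                  sequence = c("AAAA", "CCCC"))
  expect_error(consolidate_sequences(list(s)), "duplicate")
})

cons_of <- function(seqs) {
  consolidate_sequences(data.frame(
    name = paste0("q", seq_along(seqs)), species = "cfa",
    sequence = seqs, stringsAsFactors = FALSE))
}

test_that("exact placement matches the naive scan on small genomes", {
  g <- c(chr1 = "TTACGTTT")
  got <- align_exact(cons_of("ACGT"),
                     Biostrings::DNAStringSet(g))
  expect_true(any(got$hits$start == 2 & got$hits$end == 6 &
                    got$hits$strand == "+"))
  oracle <- naive_scan("ACGT", g)
  expect_equal(got$hits[, c("chrom", "start", "end", "strand")],
               oracle, ignore_attr = TRUE)

  # two forward placements are retained (2 <= 10)
  g2 <- c(chr1 = "TTAACGTTTAACGTT")
  got2 <- align_exact(cons_of("AACGTT"), Biostrings::DNAStringSet(g2))
  expect_equal(nrow(got2$hits), nrow(naive_scan("AACGTT", g2)))
  expect_equal(nrow(got2$excluded), 0)
})

test_that("N in the genome never matches", {
  # the only near-placement of ACGT has its G replaced by N
  g <- c(chr1 = "GGACNTGG")
  got <- align_exact(cons_of("ACGT"), Biostrings::DNAStringSet(g))
  expect_equal(nrow(got$hits), 0)
  expect_equal(got$unmapped$seq_key, "ACGT")
  expect_equal(nrow(naive_scan("ACGT", g)), 0)
})

test_that("promiscuous mappers are excluded at strictly more than the cutoff", {
  seq11 <- "GATTACAGATTACAGCTA"
  glue <- function(n) paste(rep(c(seq11, "CCCCCCCC"), n), collapse = "")
  g11 <- c(chr1 = glue(11))
  got <- align_exact(cons_of(seq11), Biostrings::DNAStringSet(g11))
  expect_equal(nrow(got$hits), 0)
  expect_equal(got$excluded$n_hits, 11)

  g10 <- c(chr1 = glue(10))
  got10 <- align_exact(cons_of(seq11), Biostrings::DNAStringSet(g10))
  expect_equal(nrow(got10$hits), 10)
  expect_equal(nrow(got10$excluded), 0)
})

test_that("merging clusters overlapping same-strand hits transitively", {
  cons <- cons_of(c(strrep("A", 22), strrep("C", 22)))
  mk <- function(start, end, strand, key = strrep("A", 22)) {
    data.frame(seq_key = key, rep_name = "q1", chrom = "chr1",
               start = start, end = end, strand = strand,
               stringsAsFactors = FALSE)
  }
  one <- merge_loci(rbind(mk(10, 32, "+"), mk(12, 34, "+")), cons)
  expect_equal(nrow(one$loci), 1)
  expect_equal(one$loci$start, 10)
  expect_equal(one$loci$end, 34)

  two <- merge_loci(rbind(mk(10, 32, "+"), mk(10, 32, "-")), cons)
  expect_equal(nrow(two$loci), 2)

  far <- merge_loci(rbind(mk(10, 32, "+"), mk(200, 222, "+")), cons,
                    gap_tolerance = 0)
  expect_equal(nrow(far$loci), 2)

  gap <- merge_loci(rbind(mk(10, 32, "+"), mk(40, 62, "+")), cons,
                    gap_tolerance = 8)
  expect_equal(nrow(gap$loci), 1)
  expect_equal(merge_loci(rbind(mk(10, 32, "+"), mk(40, 62, "+")), cons,
                          gap_tolerance = 7)$loci |> nrow(), 2)
})

test_that("merging agrees with brute-force transitive clustering", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:4) {
    n <- 120
    hits <- data.frame(
      seq_key = strrep("A", 20), rep_name = "q",
      chrom = sample(c("chr1", "chr2"), n, TRUE),
      start = sample(0:400, n, TRUE), strand = sample(c("+", "-"), n, TRUE),
      stringsAsFactors = FALSE)
    hits$end <- hits$start + sample(18:25, n, TRUE)
    cons <- cons_of(strrep("A", 20))
    got <- merge_loci(hits, cons, gap_tolerance = rep %% 3)
    oracle <- brute_cluster(hits, gap_tolerance = rep %% 3)
    key <- function(d) {
      d <- d[order(d$chrom, d$start, d$strand), c("chrom", "start", "end", "strand")]
      rownames(d) <- NULL
      d
    }
    expect_equal(key(got$loci), key(oracle), ignore_attr = TRUE)
    # merged loci pairwise non-overlapping per strand
    l <- got$loci
    grp <- split(l, paste(l$chrom, l$strand))
    for (g in grp) {
      g <- g[order(g$start), ]
      if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
    }
  }
})

test_that("locus names follow species precedence with -locN on collision", {
  sets <- list(
    data.frame(name = "cfa-miR-9", species = "cfa",
               sequence = "ACGTACGTACGTACGTAA"),
    data.frame(name = "rno-miR-9", species = "rno",
               sequence = "ACGTACGTACGTACGTAA"),
    data.frame(name = "rno-miR-77", species = "rno",
               sequence = "GGGTTTCCCAAAGGGTTT"))
  cons <- consolidate_sequences(sets, species_precedence = c("cfa", "rno"))
  hits <- data.frame(
    seq_key = c("ACGTACGTACGTACGTAA", "GGGTTTCCCAAAGGGTTT",
                "GGGTTTCCCAAAGGGTTT"),
    rep_name = c("cfa-miR-9", "rno-miR-77", "rno-miR-77"),
    chrom = "chr1", start = c(10, 100, 300), end = c(28, 118, 318),
    strand = "+", stringsAsFactors = FALSE)
  ann <- merge_loci(hits, cons, species_precedence = c("cfa", "rno"))
  expect_equal(ann$loci$name,
               c("cfa-miR-9", "rno-miR-77-loc1", "rno-miR-77-loc2"))
  expect_equal(ann$loci$species_provenance[1], "cfa,rno")
})

test_that("the harmonization funnel recovers planted loci end to end", {
  cfg <- simulation_config(seed = 5, n_loci = 50, n_chrom = 2,
                           chrom_length = 8000, n_te = 5, n_hte1 = 5)
  gen <- gen_genome_and_annotation(cfg)
  d <- tempfile()
  dir.create(d)
  fastas <- lapply(names(gen$species_sets), function(sp) {
    s <- gen$species_sets[[sp]]
    write_fasta(setNames(s$sequence, s$name),
                file.path(d, paste0(sp, ".fa")))
  })
  names(fastas) <- names(gen$species_sets)
  res <- build_annotation(list(species_fastas = fastas,
                               genome = local({
                                 p <- file.path(d, "g.fa")
                                 Biostrings::writeXStringSet(gen$genome, p)
                                 p
                               }),
                               target_species = "cfa"))
  expect_equal(nrow(res$annotation$loci), 50)
  tr <- gen$truth$loci[order(gen$truth$loci$chrom, gen$truth$loci$start), ]
  expect_equal(res$annotation$loci$start, tr$start)
  expect_equal(res$annotation$loci$end, tr$end)
  expect_equal(res$annotation$loci$strand, tr$strand)
  # the multimapper was consolidated but excluded at alignment
  expect_equal(res$excluded$n_hits, 11)
  expect_equal(res$funnel$count,
               c(sum(vapply(gen$species_sets, nrow, integer(1))),
                 51, 50, 50))
})

test_that("species sets with no genome match give an empty annotation", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 500)))
  res <- build_annotation(list(
    species_fastas = list(cfa = write_fasta(c(m1 = "CGCGCGCGTATATATA"))),
    genome = local({
      p <- tempfile(fileext = ".fa")
      Biostrings::writeXStringSet(g, p)
      p
    })))
  expect_equal(nrow(res$annotation$loci), 0)
  expect_equal(res$funnel$count[res$funnel$step == "aligned_sequences"], 0)
})

test_that("annotation round-trips through GFF3", {
  cfg <- simulation_config(seed = 3, n_loci = 20, n_chrom = 2,
                           chrom_length = 4000, n_te = 2, n_hte1 = 2)
  gen <- gen_genome_and_annotation(cfg)
  cons <- consolidate_sequences(gen$species_sets)
  aln <- align_exact(cons, gen$genome)
  ann <- merge_loci(aln$hits, cons)
  d <- tempfile()
  paths <- write_annotation(ann, d)
  back <- read_annotation(paths[["gff3"]])
  expect_equal(back$loci[, c("chrom", "start", "end", "strand", "name")],
               ann$loci[, c("chrom", "start", "end", "strand", "name")],
               ignore_attr = TRUE)
  expect_equal(back$loci$species_provenance, ann$loci$species_provenance)
  # BED is 0-based half-open on disk
  bed <- read.table(paths[["bed"]], sep = "\t")
  expect_equal(sort(bed$V2), sort(ann$loci$start))
})
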