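#' Load a mature miRNA FASTA file
#'
#' Reads miRBase-style mature sequence FASTA and normalizes records for
#' genome placement: identifiers are truncated at the first whitespace,
#' sequences are uppercased and U is replaced by T (mature miRNAs are
#' deposited as RNA).
#'
#' @param path Path to a FASTA file of mature miRNA sequences.
#' @param species Species code attached to every record (conventionally the
#'   three-letter miRBase prefix, e.g. `"cfa"`, `"rno"`, `"hsa"`).
#' @return A data.frame with columns `name`, `species`, `sequence` (DNA
#'   alphabet, uppercase).
#' @export
load_mature_fasta <- function(path, species) {
  if (!file.exists(path)) stop_config("mature FASTA not found: ", path)
  if (length(readLines(path, warn = FALSE)) == 0) {
    return(data.frame(name = character(), species = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_data("malformed FASTA '", path, "': ",
                                  conditionMessage(e))
  )
  if (length(set) == 0) {
    return(data.frame(name = character(), species = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) {
    stop_data("FASTA '", path, "': record ", which(!nzchar(ids))[1],
              " has an empty identifier")
  }
  if (anyDuplicated(ids)) {
    stop_data("FASTA '", path, "': duplicate record name '",
              ids[duplicated(ids)][1], "'")
  }
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTU]", seqs)
  if (any(bad)) {
    stop_data("FASTA '", path, "': record '", ids[bad][1],
              "' contains characters outside {A,C,G,T,U}")
  }
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  data.frame(name = unname(ids), species = species, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Consolidate mature sequences across species
#'
#' Collapses per-species mature sequence sets to one record per distinct
#' sequence string, so that a miRNA conserved across species is placed on
#' the genome once. Each consolidated record keeps the full membership
#' (which name in which species carries the sequence) and a representative
#' name chosen by species precedence.
#'
#' @param sets A list of data.frames as returned by [load_mature_fasta()]
#'   (may also be a single pre-combined data.frame).
#' @param species_precedence Character vector ordering species for
#'   representative-name choice; species absent from the vector rank after
#'   it in first-appearance order. Default: first-appearance order of the
#'   input (put the target species first to prefer its names).
#' @return A data.frame with columns `sequence`, `representative_name`, and
#'   list-columns `member_names`, `member_species` (parallel vectors), plus
#'   `species_provenance` (sorted unique species per record).
#' @export
consolidate_sequences <- function(sets, species_precedence = NULL) {
  if (is.data.frame(sets)) sets <- list(sets)
  if (length(sets) < 1) stop_config("need at least one species set")
  all <- do.call(rbind, lapply(sets, function(s) {
    s[, c("name", "species", "sequence"), drop = FALSE]
  }))
  if (anyDuplicated(all[, c("name", "species")])) {
    stop_data("duplicate (name, species) pair in input sets")
  }
  if (nrow(all) == 0) {
    return(data.frame(sequence = character(),
                      representative_name = character(),
                      member_names = I(list()), member_species = I(list()),
                      species_provenance = I(list()),
                      stringsAsFactors = FALSE))
  }
  prec <- unique(c(species_precedence, all$species))
  idx <- split(seq_len(nrow(all)), all$sequence)
  # deterministic record order: first appearance of each sequence
  idx <- idx[order(vapply(idx, min, integer(1)))]
  rec <- lapply(idx, function(i) {
    nm <- all$name[i]
    sp <- all$species[i]
    o <- order(match(sp, prec), nm)
    list(sequence = all$sequence[i[1]],
         representative_name = nm[o[1]],
         member_names = nm[o], member_species = sp[o],
         species_provenance = sort(unique(sp)))
  })
  data.frame(
    sequence = vapply(rec, `[[`, character(1), "sequence"),
    representative_name = vapply(rec, `[[`, character(1),
                                 "representative_name"),
    member_names = I(unname(lapply(rec, `[[`, "member_names"))),
    member_species = I(unname(lapply(rec, `[[`, "member_species"))),
    species_provenance = I(unname(lapply(rec, `[[`, "species_provenance"))),
    row.names = NULL, stringsAsFactors = FALSE)
}

load_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (!file.exists(genome)) stop_config("genome FASTA not found: ", genome)
  g <- Biostrings::readDNAStringSet(genome)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Place consolidated sequences on a genome with zero mismatches
#'
#' Finds every exact occurrence of each consolidated sequence on both
#' strands of the genome (an `N` in the genome never matches). Sequences
#' with more than `max_locations` total placements are promiscuous mappers
#' and are excluded entirely; sequences with no placement are reported as
#' unmapped. A placement is reported once per (chrom, start, strand), so a
#' palindromic sequence matching a site on both strands counts as two
#' locations.
#'
#' @param consolidated Output of [consolidate_sequences()].
#' @param genome Path to a genome FASTA, or a `DNAStringSet`.
#' @param max_locations Sequences with strictly more than this many
#'   placements are excluded (default 10).
#' @return A list with `hits` (data.frame `seq_key`, `rep_name`, `chrom`,
#'   `start`, `end`, `strand`; 0-based half-open), `excluded` (data.frame
#'   `seq_key`, `rep_name`, `n_hits`) and `unmapped` (data.frame `seq_key`,
#'   `rep_name`).
#' @export
align_exact <- function(consolidated, genome, max_locations = 10) {
  g <- load_genome(genome)
  chroms <- names(g)
  hit_list <- vector("list", nrow(consolidated))
  n_hits <- integer(nrow(consolidated))
  for (i in seq_len(nrow(consolidated))) {
    s <- Biostrings::DNAString(consolidated$sequence[i])
    L <- length(s)
    fwd <- Biostrings::vmatchPattern(s, g)
    rev <- Biostrings::vmatchPattern(Biostrings::reverseComplement(s), g)
    rows <- list()
    for (k in seq_along(chroms)) {
      fs <- BiocGenerics::start(fwd[[k]])
      rs <- BiocGenerics::start(rev[[k]])
      if (length(fs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chroms[k], start = fs - 1L, end = fs - 1L + L,
          strand = "+", stringsAsFactors = FALSE)
      }
      if (length(rs)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chroms[k], start = rs - 1L, end = rs - 1L + L,
          strand = "-", stringsAsFactors = FALSE)
      }
    }
    h <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 strand = character(), stringsAsFactors = FALSE)
    n_hits[i] <- nrow(h)
    hit_list[[i]] <- h
  }
  keep <- n_hits >= 1 & n_hits <= max_locations
  hits <- do.call(rbind, c(list(
    data.frame(seq_key = character(), rep_name = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), stringsAsFactors = FALSE)),
    lapply(which(keep), function(i) {
      cbind(data.frame(seq_key = consolidated$sequence[i],
                       rep_name = consolidated$representative_name[i],
                       stringsAsFactors = FALSE),
            hit_list[[i]])
    })))
  o <- order(hits$chrom, hits$start, hits$strand, hits$seq_key)
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  list(
    hits = hits,
    excluded = data.frame(
      seq_key = consolidated$sequence[n_hits > max_locations],
      rep_name = consolidated$representative_name[n_hits > max_locations],
      n_hits = n_hits[n_hits > max_locations], stringsAsFactors = FALSE),
    unmapped = data.frame(
      seq_key = consolidated$sequence[n_hits == 0],
      rep_name = consolidated$representative_name[n_hits == 0],
      stringsAsFactors = FALSE)
  )
}

#' Merge co-located genome hits into miRNA loci
#'
#' Hits on the same chromosome and strand that overlap, or are separated by
#' at most `gap_tolerance` bases, are clustered transitively
#' (single-linkage); each cluster becomes one locus spanning the union of
#' its members. The locus is named after the member sequence whose species
#' provenance ranks highest in `species_precedence`; name collisions across
#' loci (a sequence hitting several places) get a `-locN` suffix in
#' coordinate order.
#'
#' @param hits `hits` data.frame from [align_exact()].
#' @param consolidated Output of [consolidate_sequences()] (provenance
#'   lookup for locus naming).
#' @param gap_tolerance Maximum gap (bases) between hits merged into one
#'   locus; 0 merges only overlapping or abutting hits.
#' @param species_precedence Passed through for locus naming; default
#'   first-appearance order in `consolidated`.
#' @param genome_id Identifier stored on the annotation set.
#' @return An `annotation_set`: list with `loci` (data.frame `chrom`,
#'   `start`, `end`, `strand`, `name`, `species_provenance`, `members`;
#'   0-based half-open, comma-joined provenance/member fields),
#'   `genome_id`, `parameters`.
#' @export
merge_loci <- function(hits, consolidated, gap_tolerance = 0,
                       species_precedence = NULL, genome_id = "genome") {
  if (gap_tolerance < 0) stop_config("gap_tolerance must be >= 0")
  params <- list(gap_tolerance = gap_tolerance,
                 species_precedence = species_precedence)
  if (nrow(hits) == 0) {
    loci <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       name = character(), species_provenance = character(),
                       members = character(), stringsAsFactors = FALSE)
    return(structure(list(loci = loci, genome_id = genome_id,
                          parameters = params), class = "annotation_set"))
  }
  prec <- unique(c(species_precedence,
                   unlist(consolidated$member_species, use.names = FALSE)))
  prov <- consolidated$species_provenance
  names(prov) <- consolidated$sequence
  rep_of <- consolidated$representative_name
  names(rep_of) <- consolidated$sequence

  gr <- GenomicRanges::GRanges(
    hits$chrom,
    IRanges::IRanges(start = hits$start + 1L, end = hits$end),
    strand = hits$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = gap_tolerance + 1L,
                               with.revmap = TRUE, ignore.strand = FALSE)
  ord <- order(as.character(GenomicRanges::seqnames(red)),
               BiocGenerics::start(red),
               as.character(BiocGenerics::strand(red)))
  red <- red[ord]
  revmap <- S4Vectors::mcols(red)$revmap
  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = BiocGenerics::start(red) - 1L,
    end = BiocGenerics::end(red),
    strand = as.character(BiocGenerics::strand(red)),
    stringsAsFactors = FALSE)
  name <- character(nrow(loci))
  provenance <- character(nrow(loci))
  members <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    keys <- unique(hits$seq_key[revmap[[i]]])
    score <- vapply(keys, function(k) min(match(prov[[k]], prec)),
                    numeric(1))
    reps <- rep_of[keys]
    best <- order(score, reps)[1]
    name[i] <- reps[best]
    provenance[i] <- paste(sort(unique(unlist(prov[keys]))), collapse = ",")
    members[i] <- paste(sort(unique(reps)), collapse = ",")
  }
  # disambiguate loci sharing a representative name, in coordinate order
  for (nm in unique(name[duplicated(name)])) {
    at <- which(name == nm)
    name[at] <- paste0(nm, "-loc", seq_along(at))
  }
  loci$name <- name
  loci$species_provenance <- provenance
  loci$members <- members
  structure(list(loci = loci, genome_id = genome_id, parameters = params),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$loci), "loci on genome '", x$genome_id,
      "'\n", sep = "")
  print(head(x$loci), ...)
  invisible(x)
}

#' Build a harmonized annotation from species FASTAs and a genome
#'
#' Runs the four-step harmonization: load per-species mature sets,
#' consolidate identical sequences across species, place consolidated
#' sequences on the genome with zero mismatches (dropping sequences with
#' more than `max_locations` placements), and merge co-located hits into
#' loci. A funnel report records how many records survive each step.
#'
#' @param config A list with `species_fastas` (named list species ->
#'   FASTA path), `genome` (FASTA path or `DNAStringSet`), and optionally
#'   `target_species`, `max_locations` (default 10), `gap_tolerance`
#'   (default 0), `genome_id`.
#' @return A list with `annotation` (an `annotation_set`), `funnel`
#'   (data.frame `step`, `count`), `consolidated`, `excluded`, `unmapped`.
#' @export
build_annotation <- function(config) {
  req <- c("species_fastas", "genome")
  miss <- setdiff(req, names(config))
  if (length(miss)) stop_config("config missing: ", paste(miss, collapse = ", "))
  sp <- names(config$species_fastas)
  if (is.null(sp) || any(!nzchar(sp))) {
    stop_config("species_fastas must be a named list (species -> path)")
  }
  precedence <- unique(c(config$target_species, sp))
  max_locations <- config$max_locations %||% 10
  gap_tolerance <- config$gap_tolerance %||% 0
  sets <- lapply(sp, function(s) load_mature_fasta(config$species_fastas[[s]], s))
  n_input <- sum(vapply(sets, nrow, integer(1)))
  cons <- consolidate_sequences(sets, species_precedence = precedence)
  aln <- align_exact(cons, config$genome, max_locations = max_locations)
  ann <- merge_loci(aln$hits, cons, gap_tolerance = gap_tolerance,
                    species_precedence = precedence,
                    genome_id = config$genome_id %||% "genome")
  ann$parameters$max_locations <- max_locations
  funnel <- data.frame(
    step = c("input_sequences", "consolidated_sequences",
             "aligned_sequences", "merged_loci"),
    count = c(n_input, nrow(cons),
              length(unique(aln$hits$seq_key)), nrow(ann$loci)),
    stringsAsFactors = FALSE)
  list(annotation = ann, funnel = funnel, consolidated = cons,
       excluded = aln$excluded, unmapped = aln$unmapped)
}

#' Write an annotation set to BED6, GFF3 and a funnel report
#'
#' BED output is 0-based half-open; GFF3 is 1-based inclusive with feature
#' type `miRNA` and attributes `Name`, `species_provenance`, `members`. A
#' JSON run manifest records the parameters and file checksums.
#'
#' @param result Output of [build_annotation()], or a bare
#'   `annotation_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_annotation <- function(result, dir) {
  ann <- if (inherits(result, "annotation_set")) result else result$annotation
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  loci <- ann$loci
  paths <- c(bed = file.path(dir, "annotation.bed"),
             gff3 = file.path(dir, "annotation.gff3"),
             funnel = file.path(dir, "funnel.tsv"),
             manifest = file.path(dir, "manifest.json"))
  gr <- annotation_granges(ann)
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, paths[["bed"]], format = "BED")
  S4Vectors::mcols(gr)$score <- NULL
  S4Vectors::mcols(gr)$type <- "miRNA"
  S4Vectors::mcols(gr)$Name <- loci$name
  S4Vectors::mcols(gr)$species_provenance <- loci$species_provenance
  S4Vectors::mcols(gr)$members <- loci$members
  rtracklayer::export(gr, paths[["gff3"]], format = "GFF3")
  funnel <- if (!inherits(result, "annotation_set")) result$funnel else
    data.frame(step = "merged_loci", count = nrow(loci))
  write_tsv(funnel, paths[["funnel"]])
  manifest <- list(
    genome_id = ann$genome_id,
    parameters = ann$parameters,
    n_loci = nrow(loci),
    files = as.list(vapply(paths[c("bed", "gff3", "funnel")],
                           function(p) unname(tools::md5sum(p)),
                           character(1))))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}

annotation_granges <- function(ann) {
  loci <- ann$loci
  GenomicRanges::GRanges(
    loci$chrom,
    IRanges::IRanges(start = loci$start + 1L, end = loci$end,
                     names = loci$name),
    strand = loci$strand)
}

#' Read an annotation set from GFF3
#'
#' Inverse of [write_annotation()]: restores loci (0-based half-open
#' internally), names, species provenance and member lists.
#'
#' @param path GFF3 path written by [write_annotation()].
#' @param genome_id Genome identifier to attach (not stored in GFF3).
#' @return An `annotation_set`.
#' @export
read_annotation <- function(path, genome_id = "genome") {
  gr <- rtracklayer::import(path, format = "GFF3")
  mc <- S4Vectors::mcols(gr)
  loci <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    name = as.character(mc$Name),
    species_provenance = as.character(mc$species_provenance),
    members = as.character(mc$members),
    stringsAsFactors = FALSE)
  o <- order(loci$chrom, loci$start, loci$strand)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, genome_id = genome_id, parameters = list()),
            class = "annotation_set")
}
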