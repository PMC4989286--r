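# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (Biostrings matching, IRanges reduce, findOverlaps) so
# they can vouch for them.

# exact-match scan over every position of every chromosome, both strands;
# genome given as a named character vector. 0-based half-open output.
naive_scan <- function(pattern, genome) {
  out <- list()
  scan_one <- function(chars, pat, chrom, strand) {
    p <- strsplit(pat, "")[[1]]
    L <- length(p)
    n <- length(chars)
    if (n < L) return(NULL)
    pos <- which(chars == p[1])
    pos <- pos[pos <= n - L + 1]
    for (k in seq_len(L - 1)) {
      if (!length(pos)) break
      pos <- pos[chars[pos + k] == p[k + 1]]
    }
    if (!length(pos)) return(NULL)
    data.frame(chrom = chrom, start = pos - 1L, end = pos - 1L + L,
               strand = strand, stringsAsFactors = FALSE)
  }
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (chrom in names(genome)) {
    chars <- strsplit(genome[[chrom]], "")[[1]]
    out[[length(out) + 1]] <- scan_one(chars, pattern, chrom, "+")
    out[[length(out) + 1]] <- scan_one(chars, rc(pattern), chrom, "-")
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# transitive (single-linkage) interval clustering via an explicit
# adjacency relation and connected components
brute_cluster <- function(hits, gap_tolerance = 0) {
  skip_if_not_installed("igraph")
  n <- nrow(hits)
  grp <- paste(hits$chrom, hits$strand)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    grp[i] == grp[j] &
      pmax(hits$start[i], hits$start[j]) -
        pmin(hits$end[i], hits$end[j]) <= gap_tolerance
  })
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  do.call(rbind, lapply(split(seq_len(n), comp), function(i) {
    data.frame(chrom = hits$chrom[i[1]], start = min(hits$start[i]),
               end = max(hits$end[i]), strand = hits$strand[i[1]],
               stringsAsFactors = FALSE)
  }))
}

# per-read, per-locus overlap counting; loci and reads 0-based half-open
brute_assign <- function(aln, loci, samples, overlap_frac = 0.7,
                         max_locations = 10, stranded = TRUE) {
  counts <- matrix(0L, nrow(loci), nrow(samples),
                   dimnames = list(loci$name, samples$sample_id))
  for (r in seq_len(nrow(aln))) {
    if (aln$n_hits[r] > max_locations) next
    best <- 0L
    best_ov <- -1L
    for (l in seq_len(nrow(loci))) {
      if (aln$chrom[r] != loci$chrom[l]) next
      if (stranded && aln$strand[r] != loci$strand[l]) next
      ov <- min(aln$end[r], loci$end[l]) - max(aln$start[r], loci$start[l])
      if (ov <= 0) next
      if (ov / (loci$end[l] - loci$start[l]) >= overlap_frac &&
          ov > best_ov) {
        best <- l
        best_ov <- ov
      }
    }
    if (best > 0) {
      counts[best, aln$sample_id[r]] <- counts[best, aln$sample_id[r]] + 1L
    }
  }
  counts
}

# same per-read brute force, vectorized over loci per read so it scales
# to thousands of reads while staying independent of findOverlaps
brute_assign_vec <- function(aln, loci, samples, overlap_frac = 0.7,
                             max_locations = 10, stranded = TRUE) {
  counts <- matrix(0L, nrow(loci), nrow(samples),
                   dimnames = list(loci$name, samples$sample_id))
  llen <- loci$end - loci$start
  for (r in seq_len(nrow(aln))) {
    if (aln$n_hits[r] > max_locations) next
    ok <- loci$chrom == aln$chrom[r]
    if (stranded) ok <- ok & loci$strand == aln$strand[r]
    ov <- pmin(aln$end[r], loci$end) - pmax(aln$start[r], loci$start)
    ok <- ok & ov > 0 & ov / llen >= overlap_frac
    if (any(ok)) {
      best <- which(ok)[which.max(ov[ok])]
      counts[best, aln$sample_id[r]] <- counts[best, aln$sample_id[r]] + 1L
    }
  }
  counts
}

# full enumeration of the rank-sum permutation null (no ties assumed)
enum_wilcoxon <- function(x, y, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  n1 <- length(x)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n1)])
  sets <- utils::combn(length(r), n1)
  W_all <- apply(sets, 2, function(i) sum(seq_along(r)[i]))
  if (alternative == "greater") {
    mean(W_all >= W_obs)
  } else {
    mu <- n1 * (length(r) + 1) / 2
    mean(abs(W_all - mu) >= abs(W_obs - mu))
  }
}

# hand step-up BH
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# small expression fixture: named matrix + design in one object
make_expr <- function(rpm, tissues) {
  stopifnot(ncol(rpm) == length(tissues))
  if (is.null(colnames(rpm))) {
    colnames(rpm) <- sprintf("s%02d", seq_len(ncol(rpm)))
  }
  if (is.null(rownames(rpm))) {
    rownames(rpm) <- sprintf("L%02d", seq_len(nrow(rpm)))
  }
  samples <- data.frame(sample_id = colnames(rpm),
                        animal_id = colnames(rpm), tissue = tissues,
                        stringsAsFactors = FALSE)
  structure(list(rpm = rpm, samples = samples,
                 normalization_denominator = "assigned"),
            class = "expression_matrix")
}

write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(paste0(">", names(seqs), "\n", unname(seqs)), path)
  path
}
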