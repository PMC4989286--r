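#' @keywords internal
"_PACKAGE"

#' @importFrom stats median sd cor lm coef pnorm pwilcox p.adjust rnbinom
#'   rnorm runif setNames complete.cases
#' @importFrom utils read.table write.table head
NULL

# Abort with a classed condition so callers (and the CLI) can map error
# families to exit codes.
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("miratlas_data_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("miratlas_config_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stable TSV writers: fixed eol/quote conventions so reruns are byte-identical
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "", quote = "\"", ...)
}

write_matrix_tsv <- function(mat, path, id_col = "locus") {
  df <- data.frame(mat, check.names = FALSE, stringsAsFactors = FALSE)
  df <- cbind(setNames(data.frame(rownames(mat), stringsAsFactors = FALSE),
                       id_col), df)
  write_tsv(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

# md5 of an in-memory object via its JSON serialization (file-free inputs)
hash_object <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(jsonlite::serializeJSON(x, digits = NA)), tf)
  unname(tools::md5sum(tf))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
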