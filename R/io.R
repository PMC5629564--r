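#' Read and write count matrices
#'
#' Count matrices are stored as tab-delimited text with gene identifiers in
#' the first column and one column of non-negative integer counts per sample,
#' with a header row of sample identifiers.  Comment lines starting with `#`
#' are skipped.
#'
#' @param path file path.
#' @param x integer matrix with gene row names and sample column names.
#' @param header_lines optional character vector of comment lines (written
#'   prefixed with `#`) recording provenance, e.g. the generating command.
#' @return `read_counts` returns an integer matrix with gene row names;
#'   `write_counts` returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' write_counts(m, tf)
#' read_counts(tf)
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("count file must have a gene-id column plus >=1 sample column",
         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(is.na(m)) || any(m < 0) || any(m != floor(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' @rdname read_counts
#' @export
write_counts <- function(x, path, header_lines = NULL) {
  stopifnot(is.matrix(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines))
    writeLines(paste0("# ", header_lines), con)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
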