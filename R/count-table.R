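#' Genus-level count table
#'
#' The universal data currency of the package: a non-negative integer
#' matrix of reads with samples in rows and genera in columns, plus the
#' per-sample library sizes (row sums).
#'
#' @param counts non-negative integer matrix, samples x genera, with
#'   unique rownames (sample ids) and colnames (genus names).
#' @return An object of class `genus_count_table`: a list with elements
#'   `counts`, `sample_ids`, `genus_names`, `library_size`.
#' @examples
#' m <- matrix(c(5L, 0L, 3L, 2L), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("gA", "gB")))
#' tab <- genus_count_table(m)
#' tab$library_size
#' @export
genus_count_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("G", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicated sample ids in count table")
  if (anyDuplicated(colnames(counts)))
    stop("duplicated genus names in count table")
  if (any(counts < 0) || any(is.na(counts)))
    stop("counts must be non-negative and non-missing")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(
    list(counts = counts,
         sample_ids = rownames(counts),
         genus_names = colnames(counts),
         library_size = as.integer(rowSums(counts))),
    class = "genus_count_table")
}

#' @export
print.genus_count_table <- function(x, ...) {
  cat(sprintf("genus_count_table: %d samples x %d genera, median depth %d\n",
              nrow(x$counts), ncol(x$counts),
              as.integer(median(x$library_size))))
  invisible(x)
}

#' @export
dim.genus_count_table <- function(x) dim(x$counts)

## internal: rebuild after subsetting/transforming the matrix
as_count_table <- function(m) genus_count_table(m)

#' Read / write count tables as TSV
#'
#' Plain-text interchange: samples in rows, genera in columns, first
#' column `sample_id`.
#'
#' @param table a [genus_count_table()].
#' @param path file path.
#' @return `read_count_tsv` returns a `genus_count_table`;
#'   `write_count_tsv` returns `path` invisibly.
#' @export
write_count_tsv <- function(table, path) {
  stopifnot(inherits(table, "genus_count_table"))
  df <- data.frame(sample_id = table$sample_ids, table$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  genus_count_table(m)
}
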