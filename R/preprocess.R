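#' Agglomerate feature-level counts to genus level
#'
#' Sums counts of features (e.g. amplicon sequence variants) that share a
#' genus label. Features mapping to the sentinel label are pooled into a
#' single `"unclassified"` column, which is kept and flagged via the
#' `unclassified` attribute.
#'
#' @param table feature-level [genus_count_table()] (columns = features).
#' @param tax named character vector or two-column data.frame mapping
#'   every feature id to a genus label; use `sentinel` for unassigned.
#' @param sentinel label marking unassigned features.
#' @return genus-level [genus_count_table()]; library sizes preserved.
#' @export
agglomerate_to_genus <- function(table, tax, sentinel = "unassigned") {
  stopifnot(inherits(table, "genus_count_table"))
  if (is.data.frame(tax)) tax <- setNames(as.character(tax[[2]]), tax[[1]])
  missing <- setdiff(table$genus_names, names(tax))
  if (length(missing))
    stop("unmapped feature id(s): ", paste(missing, collapse = ", "))
  lab <- unname(tax[table$genus_names])
  lab[lab == sentinel] <- "unclassified"
  m <- t(rowsum(t(table$counts), group = lab))
  out <- genus_count_table(m)
  attr(out, "unclassified") <- "unclassified" %in% colnames(m)
  stopifnot(identical(out$library_size, table$library_size))
  out
}

#' Prevalence filter
#'
#' Retains a genus iff it is detected (count > 0) in at least
#' `threshold` of the samples; genera detected in strictly *less* than
#' the threshold fraction are excluded, so a genus at exactly the
#' threshold is kept.
#'
#' @param table a [genus_count_table()].
#' @param threshold fraction in (0, 1]; default 0.20.
#' @return Filtered [genus_count_table()].
#' @export
prevalence_filter <- function(table, threshold = 0.20) {
  stopifnot(inherits(table, "genus_count_table"),
            threshold > 0, threshold <= 1)
  if (nrow(table$counts) == 0 || ncol(table$counts) == 0)
    stop("empty count table")
  prev <- colMeans(table$counts > 0)
  keep <- prev >= threshold
  out <- genus_count_table(table$counts[, keep, drop = FALSE])
  attr(out, "dropped") <- table$genus_names[!keep]
  out
}

#' Rarefy counts to even depth
#'
#' Subsamples each sample's reads without replacement to a common depth.
#' Samples with fewer reads than `depth` are dropped with a warning
#' rather than up-sampled.
#'
#' @param table a [genus_count_table()].
#' @param depth positive integer target depth; default = minimum library
#'   size (no samples dropped).
#' @param seed optional integer seed for reproducibility.
#' @return Rarefied [genus_count_table()]; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = min(table$library_size), seed = NULL) {
  stopifnot(inherits(table, "genus_count_table"))
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  keep <- table$library_size >= depth
  if (!all(keep))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(table$sample_ids[!keep], collapse = ", ")))
  m <- table$counts[keep, , drop = FALSE]
  G <- ncol(m)
  out <- t(apply(m, 1, function(row) {
    tot <- sum(row)
    if (tot == depth) return(as.integer(row))
    picked <- sample.int(tot, depth)  # reads are exchangeable
    tabulate(findInterval(picked - 1L, cumsum(c(0L, row))[seq_len(G)]),
             nbins = G)
  }))
  dimnames(out) <- dimnames(m)
  genus_count_table(out)
}

#' Centred log-ratio transform
#'
#' `x_ij = log((c_ij + pc) / g_i)` with `g_i` the geometric mean of the
#' pseudocounted row; every row sums to zero. A pseudocount is required
#' because zeros are ubiquitous in genus tables.
#'
#' @param table a [genus_count_table()].
#' @param pseudocount positive real added to every count; default 0.5.
#' @return An object of class `clr_matrix`: list with `x` (real matrix),
#'   `pseudocount`, `genus_names`, `sample_ids`.
#' @export
clr_transform <- function(table, pseudocount = 0.5) {
  stopifnot(inherits(table, "genus_count_table"), pseudocount > 0)
  lx <- log(table$counts + pseudocount)
  x <- lx - rowMeans(lx)
  structure(list(x = x, pseudocount = pseudocount,
                 genus_names = table$genus_names,
                 sample_ids = table$sample_ids),
            class = "clr_matrix")
}

#' @export
print.clr_matrix <- function(x, ...) {
  cat(sprintf("clr_matrix: %d samples x %d genera (pseudocount %g)\n",
              nrow(x$x), ncol(x$x), x$pseudocount))
  invisible(x)
}
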