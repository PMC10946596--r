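#' Shannon diversity index
#'
#' `H = -sum(p * log(p))` over the non-zero proportions of one sample,
#' natural logarithm. Permutation-invariant in taxa, maximal (`log(S)`)
#' at uniformity.
#'
#' @param counts_row non-negative numeric vector with positive sum.
#' @return Shannon index (real scalar).
#' @examples
#' shannon_index(c(10, 10, 10, 10))  # log(4)
#' @export
shannon_index <- function(counts_row) {
  if (any(counts_row < 0)) stop("negative counts")
  tot <- sum(counts_row)
  if (tot <= 0) stop("all-zero sample: Shannon undefined")
  p <- counts_row[counts_row > 0] / tot
  -sum(p * log(p))
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum(|x - y|) / sum(x + y)`, bounded in `[0, 1]`. Note the
#' statistic is scale-dependent: equal compositions at different library
#' sizes have non-zero distance, so callers typically pass proportions.
#'
#' @param table a [genus_count_table()] or numeric matrix (samples x taxa).
#' @return Object of class `distance_matrix`: list with `d` (symmetric
#'   matrix, zero diagonal) and `sample_ids`.
#' @export
bray_curtis <- function(table) {
  m <- if (inherits(table, "genus_count_table")) table$counts else as.matrix(table)
  n <- nrow(m)
  if (n < 2) stop("need at least two samples")
  rs <- rowSums(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    denom <- rs[i] + rs[j]
    if (denom == 0) stop("two all-zero samples: distance undefined")
    d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
  }
  structure(list(d = d, sample_ids = rownames(m)), class = "distance_matrix")
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: Gower double-centring of `-D^2/2` followed by
#' eigendecomposition. All eigenvalues (including negative ones, which
#' arise for non-Euclidean dissimilarities such as Bray-Curtis) are
#' reported; coordinates are returned only for axes with positive
#' eigenvalues and the proportion explained is relative to the sum of the
#' positive eigenvalues. No Lingoes/Cailliez correction is applied.
#'
#' @param dist a `distance_matrix` (from [bray_curtis()]) or symmetric
#'   numeric matrix with zero diagonal.
#' @return Object of class `ordination`: list with `coordinates`
#'   (samples x positive axes, centred), `eigenvalues` (descending, all),
#'   `prop_explained` (per positive axis).
#' @export
pcoa <- function(dist) {
  d <- if (inherits(dist, "distance_matrix")) dist$d else as.matrix(dist)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  a <- -0.5 * d^2
  b <- a - matrix(rowMeans(a), n, n) -
    matrix(colMeans(a), n, n, byrow = TRUE) + mean(a)
  e <- eigen(b, symmetric = TRUE)
  pos <- e$values > max(1e-10, 1e-8 * abs(e$values[1]))
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = e$values,
                 prop_explained = e$values[pos] / sum(e$values[pos])),
            class = "ordination")
}

#' Kruskal-Wallis omnibus with Dunn's post hoc test
#'
#' Tie-corrected Kruskal-Wallis test across groups followed by all
#' pairwise Dunn z-tests (mid-rank convention, shared tie correction),
#' with Benjamini-Hochberg adjustment over the pairwise family.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return Object of class `group_test`: list with `statistic`, `df`,
#'   `p_value` (omnibus), `pairwise` data.frame (`group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`) and `adjust_method = "BH"`.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  ok <- !is.na(values)
  values <- values[ok]; groups <- groups[ok]
  k <- nlevels(groups)
  if (k < 2) stop("need at least two groups")
  N <- length(values)
  r <- rank(values)
  n_g <- tabulate(groups)
  rbar <- tapply(r, groups, mean)
  ties <- table(values)
  tie_sum <- sum(ties^3 - ties)
  H <- (12 / (N * (N + 1))) * sum(n_g * (rbar - (N + 1) / 2)^2)
  C <- 1 - tie_sum / (N^3 - N)
  H <- if (C > 0) H / C else NA_real_
  p_omni <- pchisq(H, df = k - 1, lower.tail = FALSE)
  ## Dunn: pooled variance of mean-rank differences with tie correction
  s2 <- (N * (N + 1) / 12) - tie_sum / (12 * (N - 1))
  pairs <- combn(levels(groups), 2)
  z <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    (rbar[i] - rbar[j]) /
      sqrt(s2 * (1 / n_g[match(i, levels(groups))] +
                 1 / n_g[match(j, levels(groups))]))
  })
  p_raw <- 2 * pnorm(abs(z), lower.tail = FALSE)
  structure(list(statistic = H, df = k - 1, p_value = p_omni,
                 pairwise = data.frame(group1 = pairs[1, ],
                                       group2 = pairs[2, ],
                                       z = unname(z), p_raw = p_raw,
                                       p_adj = bh_fdr(p_raw)),
                 adjust_method = "BH"),
            class = "group_test")
}

#' Within-group beta-diversity comparison
#'
#' Collects all within-group pairwise distances per group (a group of
#' `n` samples contributes `choose(n, 2)` distances) and compares those
#' sets with [kruskal_dunn()]. Pairwise distances are not independent
#' observations; the rank test is applied to them regardless, mirroring
#' common field practice, and this caveat is documented.
#'
#' @param dist a `distance_matrix`.
#' @param groups group labels per sample.
#' @return A `group_test` as in [kruskal_dunn()], with an extra element
#'   `distances`: data.frame(`group`, `distance`).
#' @export
within_group_beta <- function(dist, groups) {
  stopifnot(inherits(dist, "distance_matrix"))
  groups <- factor(groups)
  out <- lapply(levels(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2) return(NULL)
    sub <- dist$d[idx, idx]
    data.frame(group = g, distance = sub[lower.tri(sub)])
  })
  dropped <- levels(groups)[vapply(out, is.null, TRUE)]
  if (length(dropped))
    warning("excluding group(s) of size 1: ", paste(dropped, collapse = ", "))
  df <- do.call(rbind, out)
  res <- kruskal_dunn(df$distance, df$group)
  res$distances <- df
  res
}
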