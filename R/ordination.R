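#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' `n / rank`, a running minimum is taken from the largest down, and the
#' result is clipped at 1.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(n / (n:1) * p[o]))[order(o)]
}

## ---- internal least-squares machinery ------------------------------------

## centred dummy-coded design block for one explanatory variable
design_block <- function(v, name) {
  if (is.numeric(v)) {
    x <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, name))
  } else {
    f <- droplevels(factor(v))
    if (nlevels(f) < 2) stop(sprintf("variable '%s' is constant", name))
    x <- model.matrix(~f)[, -1, drop = FALSE]
    colnames(x) <- paste0(name, ".", levels(f)[-1])
  }
  sweep(x, 2, colMeans(x))
}

## fitted sum of squares of Y on design X (both centred); also rank
fit_ss <- function(X, Y) {
  q <- qr(X)
  if (q$rank == 0) return(list(ss = 0, rank = 0L))
  list(ss = sum(qr.fitted(q, Y)^2), rank = q$rank)
}

## ---- operations ----------------------------------------------------------

#' Redundancy-analysis effect size of one variable on CLR data
#'
#' Euclidean RDA on centred log-ratio data is multivariate least squares:
#' the CLR matrix is column-centred and projected onto the (dummy-coded,
#' centred) design columns of the variable. `R^2` is the fraction of
#' total sum of squares captured by the projection; significance comes
#' from a permutation test of the pseudo-F statistic under row
#' permutation of the variable, with
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm)`.
#'
#' @param clr a `clr_matrix` (see [clr_transform()]) or numeric matrix.
#' @param variable numeric vector or factor of length `nrow(clr)`.
#' @param n_perm number of permutations (default 999; a warning is
#'   emitted below 99).
#' @param seed optional integer seed.
#' @param name label for the variable in the result.
#' @return Object of class `rda_result`: list with `variable`, `r2`,
#'   `adj_r2`, `f`, `p_value`, `n_perm`, `rank`.
#' @export
rda_effect_size <- function(clr, variable, n_perm = 999, seed = NULL,
                            name = deparse(substitute(variable))) {
  Y <- if (inherits(clr, "clr_matrix")) clr$x else as.matrix(clr)
  Y <- sweep(Y, 2, colMeans(Y))
  n <- nrow(Y)
  if (length(variable) != n) stop("variable length must match samples")
  if (length(unique(variable)) < 2) stop("variable is constant")
  if (n_perm < 99) warning("fewer than 99 permutations: p-values are coarse")
  if (!is.null(seed)) set.seed(seed)
  X <- design_block(variable, name)
  m <- qr(X)$rank
  ss_tot <- sum(Y^2)
  obs <- fit_ss(X, Y)$ss
  r2 <- obs / ss_tot
  fstat <- (obs / m) / ((ss_tot - obs) / (n - 1 - m))
  if (ncol(X) == 1L) {
    ## vectorised permutation for the single-column case
    XP <- replicate(n_perm, X[sample.int(n), 1L])
    ss_p <- colSums(crossprod(Y, XP)^2) / colSums(XP^2)
  } else {
    ss_p <- vapply(seq_len(n_perm), function(b)
      fit_ss(X[sample.int(n), , drop = FALSE], Y)$ss, 0)
  }
  f_p <- (ss_p / m) / ((ss_tot - ss_p) / (n - 1 - m))
  p <- (1 + sum(f_p >= fstat)) / (1 + n_perm)
  structure(list(variable = name, r2 = r2,
                 adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 1 - m),
                 f = fstat, p_value = p, n_perm = n_perm, rank = m),
            class = "rda_result")
}

#' Screen many metadata variables by independent RDA effect size
#'
#' Runs [rda_effect_size()] per column and appends BH-adjusted q-values,
#' to be thresholded at the study-wide FDR (default significance
#' convention: q < 0.1).
#'
#' @param clr a `clr_matrix` or matrix.
#' @param variables data.frame of candidate explanatory variables.
#' @inheritParams rda_effect_size
#' @return data.frame with one row per variable: `variable`, `r2`,
#'   `adj_r2`, `p_value`, `q_value`.
#' @export
rda_screen <- function(clr, variables, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(names(variables), function(nm) {
    r <- rda_effect_size(clr, variables[[nm]], n_perm = n_perm, name = nm)
    data.frame(variable = nm, r2 = r$r2, adj_r2 = r$adj_r2,
               p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out
}

#' Forced-feature forward selection of RDA variables
#'
#' Two-step stepwise procedure: first the `forced` variables are entered
#' unconditionally in the given order (each recorded with its at-entry
#' partial permutation p and cumulative R^2); then greedy forward
#' selection proceeds among the remaining variables by best adjusted-R^2
#' gain, admitting a variable only if its partial permutation p is below
#' `alpha` *and* the cumulative adjusted R^2 does not exceed the adjusted
#' R^2 of the all-variables model (the scope rule). The two traces are
#' merged.
#'
#' @param clr a `clr_matrix` or matrix.
#' @param variables data.frame of candidate variables (columns named).
#' @param forced character vector of column names to force first.
#' @param alpha entry threshold on the partial permutation p (default
#'   0.05, the usual stepwise default).
#' @param n_perm permutations per entry test.
#' @param seed optional integer seed.
#' @return Object of class `selection_trace`: list with `trace`
#'   (data.frame: `variable`, `cum_r2`, `cum_adj_r2`, `p_entry`,
#'   `forced`), `stopping_reason`, `scope_adj_r2`, `skipped` (collinear
#'   candidates, if any).
#' @export
forward_select_forced <- function(clr, variables, forced = character(),
                                  alpha = 0.05, n_perm = 199, seed = NULL) {
  Y <- if (inherits(clr, "clr_matrix")) clr$x else as.matrix(clr)
  Y <- sweep(Y, 2, colMeans(Y))
  n <- nrow(Y)
  stopifnot(is.data.frame(variables), all(forced %in% names(variables)))
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(names(variables), function(nm)
    design_block(variables[[nm]], nm))
  names(blocks) <- names(variables)
  ss_tot <- sum(Y^2)
  adj <- function(ss, m) 1 - (1 - ss / ss_tot) * (n - 1) / (n - 1 - m)
  full <- fit_ss(do.call(cbind, blocks), Y)
  scope <- adj(full$ss, full$rank)

  X <- matrix(nrow = n, ncol = 0)
  cur <- list(ss = 0, rank = 0L)
  trace <- list(); skipped <- character()

  ## partial permutation test for adding block B to the current design
  entry_test <- function(B) {
    cand <- fit_ss(cbind(X, B), Y)
    dm <- cand$rank - cur$rank
    if (dm == 0) return(NULL)  # collinear with current design
    fobs <- ((cand$ss - cur$ss) / dm) /
      ((ss_tot - cand$ss) / (n - 1 - cand$rank))
    fp <- vapply(seq_len(n_perm), function(b) {
      cb <- fit_ss(cbind(X, B[sample.int(n), , drop = FALSE]), Y)
      ((cb$ss - cur$ss) / dm) / ((ss_tot - cb$ss) / (n - 1 - cb$rank))
    }, 0)
    list(fit = cand, p = (1 + sum(fp >= fobs)) / (1 + n_perm))
  }

  add_row <- function(nm, fit, p, forced_flag) {
    trace[[length(trace) + 1L]] <<- data.frame(
      variable = nm, cum_r2 = fit$ss / ss_tot,
      cum_adj_r2 = adj(fit$ss, fit$rank), p_entry = p,
      forced = forced_flag)
    X <<- cbind(X, blocks[[nm]]); cur <<- fit
  }

  for (nm in forced) {                       # step 1: forced entries
    et <- entry_test(blocks[[nm]])
    if (is.null(et)) { skipped <- c(skipped, nm); next }
    add_row(nm, et$fit, et$p, TRUE)
  }

  free <- setdiff(names(variables), forced)
  reason <- "no candidates left"
  while (length(free)) {                     # step 2: greedy free entries
    gains <- vapply(free, function(nm) {
      cand <- fit_ss(cbind(X, blocks[[nm]]), Y)
      if (cand$rank == cur$rank) NA_real_ else adj(cand$ss, cand$rank)
    }, 0)
    if (all(is.na(gains))) {
      skipped <- c(skipped, free); reason <- "all remaining collinear"; break
    }
    best <- free[which.max(gains)]
    et <- entry_test(blocks[[best]])
    if (et$p >= alpha) { reason <- "no significant gain"; break }
    if (adj(et$fit$ss, et$fit$rank) > scope) {
      reason <- "exceeded scope adjusted R2"; break
    }
    add_row(best, et$fit, et$p, FALSE)
    free <- setdiff(free, best)
  }
  structure(list(trace = if (length(trace)) do.call(rbind, trace) else
                   data.frame(variable = character(), cum_r2 = numeric(),
                              cum_adj_r2 = numeric(), p_entry = numeric(),
                              forced = logical()),
                 stopping_reason = reason, scope_adj_r2 = scope,
                 skipped = skipped),
            class = "selection_trace")
}
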