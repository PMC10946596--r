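#' The five nested binomial abundance models
#'
#' Model probabilities are additive on the probability scale:
#' `p = p_base + m_hiv*hiv + m_id*id + m_interaction*hiv*id`, with the
#' feature set growing with `model_id`:
#' 1 = `{p_base}`; 2 adds `m_hiv`; 3 adds `m_id`; 4 = both main effects;
#' 5 adds `m_interaction`. The genus count `k_i` out of library size
#' `N_i` follows `Binomial(N_i, p_i)`.
#'
#' @param model_id integer 1..5.
#' @return A `model_spec` list with `model_id` and `features` (character
#'   vector; always starts with `"p_base"`).
#' @export
model_spec <- function(model_id) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stop("model_id must be 1..5")
  features <- switch(model_id,
                     "p_base",
                     c("p_base", "m_hiv"),
                     c("p_base", "m_id"),
                     c("p_base", "m_hiv", "m_id"),
                     c("p_base", "m_hiv", "m_id", "m_interaction"))
  structure(list(model_id = model_id, features = features),
            class = "model_spec")
}

#' Per-genus design data
#'
#' Bundles the genus count, library size and factor indicators for one
#' genus across all samples.
#'
#' @param k integer genus counts.
#' @param N integer library sizes (`k <= N`).
#' @param hiv,id 0/1 indicators.
#' @return An `abundance_data` list; `group` is derived (1 = both
#'   exposures .. 4 = neither, the reference).
#' @export
abundance_data <- function(k, N, hiv, id) {
  k <- as.integer(k); N <- as.integer(N)
  hiv <- as.integer(hiv); id <- as.integer(id)
  n <- length(k)
  stopifnot(length(N) == n, length(hiv) == n, length(id) == n)
  if (any(k < 0) || any(N <= 0)) stop("counts must be >= 0, sizes > 0")
  if (any(k > N)) stop("genus count exceeds library size")
  if (!all(hiv %in% 0:1) || !all(id %in% 0:1))
    stop("indicators must be 0/1")
  structure(list(k = k, N = N, hiv = hiv, id = id,
                 group = 4L - 2L * hiv - id),
            class = "abundance_data")
}

## design columns for the m features of a spec (samples x features-1)
feature_design <- function(spec, data) {
  cols <- list(m_hiv = data$hiv, m_id = data$id,
               m_interaction = data$hiv * data$id)
  m <- spec$features[-1]
  if (!length(m)) return(matrix(0, length(data$k), 0))
  do.call(cbind, cols[m])
}

#' Log posterior (or log likelihood) of an abundance model
#'
#' Sum of binomial log-pmf terms at the model's per-sample probabilities,
#' plus (by default) the flat-prior log densities: `p_base ~ Uniform(0,1)`
#' and each `m ~ Uniform(-1,1)`, with the joint support truncated so that
#' every sample's probability lies in (0, 1). Returns `-Inf` outside the
#' support.
#'
#' @param spec a [model_spec()].
#' @param params named numeric vector covering `spec$features`.
#' @param data an [abundance_data()].
#' @param include_prior include the log-prior terms (default `TRUE`).
#' @return Log density (scalar, possibly `-Inf`).
#' @export
model_logp <- function(spec, params, data, include_prior = TRUE) {
  params <- unlist(params)
  if (!all(spec$features %in% names(params)))
    stop("params must cover the model's active features")
  th <- params[spec$features]
  X <- feature_design(spec, data)
  p <- th[["p_base"]] + if (ncol(X)) drop(X %*% th[-1]) else 0
  if (any(p <= 0) || any(p >= 1)) return(-Inf)
  if (th[["p_base"]] <= 0 || th[["p_base"]] >= 1) return(-Inf)
  if (length(th) > 1 && any(abs(th[-1]) >= 1)) return(-Inf)
  ll <- sum(dbinom(data$k, data$N, p, log = TRUE))
  if (include_prior) ll <- ll + (length(th) - 1) * log(0.5)
  ll
}

#' Fit an abundance model by adaptive MCMC
#'
#' Samples the posterior of the model's features with the package's
#' adaptive Metropolis engine (see [sampler_config()]; defaults 4,000
#' draws, 2,000 tuning steps, 4 chains). Chains are initialised at
#' jittered empirical cell proportions. A fit with any split R-hat at or
#' above 1.01 is returned flagged, never silently.
#'
#' @param spec a [model_spec()].
#' @param data an [abundance_data()].
#' @param cfg a [sampler_config()].
#' @return Object of class `abundance_fit`: list with `draws` (matrix,
#'   total draws x features), `draws_array` (iterations x chains x
#'   features), `rhat`, `ess`, `accept_rate`, `flagged`, `spec`, `data`,
#'   `cfg`.
#' @export
fit_abundance_model <- function(spec, data, cfg = sampler_config()) {
  stopifnot(inherits(spec, "model_spec"), inherits(data, "abundance_data"))
  feats <- spec$features
  d <- length(feats)
  X <- feature_design(spec, data)
  lch <- lchoose(data$N, data$k)
  k <- data$k; N <- data$N
  prior_const <- (d - 1) * log(0.5)
  logp <- function(th) {
    p <- th[1] + if (d > 1) drop(X %*% th[-1]) else 0
    if (th[1] <= 0 || th[1] >= 1 || any(p <= 0) || any(p >= 1)) return(-Inf)
    if (d > 1 && any(abs(th[-1]) >= 1)) return(-Inf)
    sum(lch + k * log(p) + (N - k) * log1p(-p)) + prior_const
  }
  ## empirical cell proportions -> method-of-moments start values
  phat <- function(h, i) {
    sel <- data$hiv == h & data$id == i
    if (!any(sel)) return(NA_real_)
    sum(k[sel]) / sum(N[sel])
  }
  p00 <- phat(0, 0); if (is.na(p00)) p00 <- sum(k) / sum(N)
  p00 <- min(max(p00, 1e-6), 1 - 1e-6)
  start <- c(p_base = p00,
             m_hiv = if (!is.na(phat(1, 0))) phat(1, 0) - p00 else 0,
             m_id = if (!is.na(phat(0, 1))) phat(0, 1) - p00 else 0,
             m_interaction = 0)[feats]
  sd0 <- sqrt(p00 * (1 - p00) / sum(N))
  init <- function(ch) start * (1 + 0.05 * rnorm(d)) + sd0 * rnorm(d)
  res <- run_adaptive_mh(logp, init, d, prop_sd = rep(sd0 * 3, d), cfg)
  dimnames(res$draws)[[3]] <- feats
  diag <- mcmc_diagnostics(res$draws, feats)
  flat <- apply(res$draws, 3, rbind)
  colnames(flat) <- feats
  flagged <- any(diag$rhat >= 1.01)
  if (flagged)
    warning(sprintf("model %d fit flagged: max split R-hat %.3f",
                    spec$model_id, max(diag$rhat)))
  structure(list(draws = flat, draws_array = res$draws,
                 rhat = diag$rhat, ess = diag$ess,
                 accept_rate = res$accept_rate, flagged = flagged,
                 spec = spec, data = data, cfg = cfg),
            class = "abundance_fit")
}

#' @export
print.abundance_fit <- function(x, ...) {
  cat(sprintf("abundance_fit: model %d (%s), %d draws, max R-hat %.3f%s\n",
              x$spec$model_id, paste(x$spec$features, collapse = ", "),
              nrow(x$draws), max(x$rhat),
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

## pointwise log-likelihood matrix: draws x samples
pointwise_loglik <- function(fit) {
  data <- fit$data
  X <- feature_design(fit$spec, data)
  th <- fit$draws
  P <- matrix(th[, "p_base"], nrow(th), length(data$k))
  if (ncol(X))
    P <- P + th[, -1, drop = FALSE] %*% t(X)
  lch <- lchoose(data$N, data$k)
  t(lch + data$k * log(t(P)) + (data$N - data$k) * log1p(-t(P)))
}

#' Widely applicable information criterion
#'
#' `elpd_waic = lppd - p_waic` computed pointwise from a draws x
#' observations log-likelihood matrix, with its standard error.
#'
#' @param ll log-likelihood matrix (posterior draws in rows).
#' @return list with `elpd`, `p_waic`, `se`, `pointwise`.
#' @export
waic <- function(ll) {
  S <- nrow(ll)
  lppd_i <- apply(ll, 2, function(v) {
    m <- max(v); m + log(mean(exp(v - m)))
  })
  p_i <- apply(ll, 2, var)
  pw <- lppd_i - p_i
  list(elpd = sum(pw), p_waic = sum(p_i),
       se = sqrt(length(pw) * var(pw)), pointwise = pw)
}

#' Compare the nested model fits and select the simplest adequate one
#'
#' Computes WAIC for each fit and applies a one-standard-error parsimony
#' rule (the automated stand-in for visual inspection of a model
#' comparison plot): among all models whose elpd lies within one SE of
#' the pairwise elpd *difference* from the best model, the one with the
#' fewest features (lowest model id on ties) is selected.
#'
#' @param fits list of `abundance_fit` objects (e.g. models 1..5 on the
#'   same genus).
#' @return Object of class `model_comparison`: list with `table`
#'   (data.frame: `model_id`, `n_features`, `elpd`, `se`,
#'   `elpd_diff`, `se_diff`, `rank`), `selected` (model id),
#'   `rule = "one-SE parsimony"`.
#' @export
compare_and_select <- function(fits) {
  stopifnot(length(fits) >= 2)
  if (any(vapply(fits, `[[`, TRUE, "flagged")))
    warning("comparing fits that include flagged (non-converged) models")
  lls <- lapply(fits, pointwise_loglik)
  ws <- lapply(lls, waic)
  ids <- vapply(fits, function(f) f$spec$model_id, 0L)
  nf <- vapply(fits, function(f) length(f$spec$features), 0L)
  elpd <- vapply(ws, `[[`, 0, "elpd")
  best <- which.max(elpd)
  se_diff <- vapply(seq_along(ws), function(j) {
    if (j == best) return(0)
    dpw <- ws[[best]]$pointwise - ws[[j]]$pointwise
    sqrt(length(dpw) * var(dpw))
  }, 0)
  tbl <- data.frame(model_id = ids, n_features = nf, elpd = elpd,
                    se = vapply(ws, `[[`, 0, "se"),
                    elpd_diff = elpd[best] - elpd, se_diff = se_diff,
                    rank = rank(-elpd, ties.method = "first"))
  structure(list(table = tbl, selected = select_parsimonious(tbl),
                 rule = "one-SE parsimony"),
            class = "model_comparison")
}

#' Parsimony selection rule on a comparison table
#'
#' @param tbl data.frame with columns `model_id`, `n_features`,
#'   `elpd_diff` (gap to the best model) and `se_diff`.
#' @return Selected model id (simplest model whose gap to the best is
#'   within one SE of that difference).
#' @export
select_parsimonious <- function(tbl) {
  cand <- tbl[tbl$elpd_diff <= tbl$se_diff + 1e-12, ]
  cand <- cand[order(cand$n_features, cand$model_id), ]
  cand$model_id[1]
}

#' Highest density interval of posterior draws
#'
#' The shortest contiguous window of the sorted draws containing
#' `ceiling(prob * n)` points (ties broken toward the earliest window).
#'
#' @param draws numeric vector (at least 10 values).
#' @param prob interval mass in (0, 1); default 0.94.
#' @return Named numeric `c(lower, upper)`.
#' @export
hdi <- function(draws, prob = 0.94) {
  stopifnot(prob > 0, prob < 1)
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws for an HDI")
  m <- ceiling(prob * n)
  widths <- draws[m:n] - draws[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(lower = draws[i], upper = draws[i + m - 1])
}

#' Percent-change effect summary
#'
#' Per posterior draw the percent change attributable to a feature is
#' `100 * m / p_base`; the summary reports the posterior mean, SD and
#' 94% HDI of that transform plus a direction label from the sign of the
#' mean. Draws with `p_base` numerically at zero would overflow and
#' flag the summary.
#'
#' @param fit an `abundance_fit`.
#' @param feature one of the fit's m features (e.g. `"m_hiv"`).
#' @param prob HDI mass; default 0.94.
#' @return Object of class `effect_summary`: list with `feature`,
#'   `mean`, `sd`, `hdi_lower`, `hdi_upper`, `direction`, `flagged`.
#' @export
summarize_percent_change <- function(fit, feature, prob = 0.94) {
  if (!feature %in% fit$spec$features[-1])
    stop(sprintf("feature '%s' not active in this fit", feature))
  pb <- fit$draws[, "p_base"]
  flagged <- any(abs(pb) < 1e-12)
  pct <- 100 * fit$draws[, feature] / pb
  h <- hdi(pct[is.finite(pct)], prob)
  structure(list(feature = feature, mean = mean(pct[is.finite(pct)]),
                 sd = sd(pct[is.finite(pct)]),
                 hdi_lower = unname(h[1]), hdi_upper = unname(h[2]),
                 direction = if (mean(pct[is.finite(pct)]) >= 0)
                   "increase" else "decrease",
                 flagged = flagged || any(!is.finite(pct))),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s: %s of %.1f%% +/- %.1f (94%% HDI %.1f to %.1f)%s\n",
              x$feature, x$direction, abs(x$mean), x$sd,
              x$hdi_lower, x$hdi_upper,
              if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}
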