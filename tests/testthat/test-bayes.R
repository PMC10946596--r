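test_that("model_spec encodes the nesting structure", {
  expect_equal(model_spec(1)$features, "p_base")
  expect_equal(model_spec(4)$features, c("p_base", "m_hiv", "m_id"))
  expect_equal(model_spec(5)$features,
               c("p_base", "m_hiv", "m_id", "m_interaction"))
  expect_error(model_spec(6), "1..5")
})

test_that("model_logp equals a direct binomial-summation oracle", {
  d1 <- abundance_data(3, 10, 0, 0)
  expect_equal(model_logp(model_spec(1), c(p_base = 0.3), d1,
                          include_prior = FALSE),
               log(choose(10, 3)) + 3 * log(0.3) + 7 * log(0.7))

  ## 20 random parameter/data points vs an explicit loop, tol 1e-8
  set.seed(6)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    g <- list(hiv = rbinom(n, 1, 0.5), id = rbinom(n, 1, 0.5))
    N <- sample(500:2000, n, replace = TRUE)
    k <- rbinom(n, N, 0.02)
    dat <- abundance_data(k, N, g$hiv, g$id)
    th <- c(p_base = runif(1, 0.005, 0.05),
            m_hiv = runif(1, -0.004, 0.004),
            m_id = runif(1, -0.004, 0.004),
            m_interaction = runif(1, -0.002, 0.002))
    spec <- model_spec(sample(1:5, 1))
    p <- th["p_base"] + th["m_hiv"] * g$hiv * ("m_hiv" %in% spec$features) +
      th["m_id"] * g$id * ("m_id" %in% spec$features) +
      th["m_interaction"] * g$hiv * g$id *
        ("m_interaction" %in% spec$features)
    oracle <- sum(vapply(seq_len(n), function(j)
      lchoose(N[j], k[j]) + k[j] * log(p[j]) + (N[j] - k[j]) * log(1 - p[j]),
      0))
    expect_equal(model_logp(spec, th, dat, include_prior = FALSE), oracle,
                 tolerance = 1e-8)
  }

  ## nesting identity: model 5 with all m = 0 equals model 1
  dat <- simulate_abundance(0.01)
  th0 <- c(p_base = 0.013, m_hiv = 0, m_id = 0, m_interaction = 0)
  expect_equal(model_logp(model_spec(5), th0, dat, include_prior = FALSE),
               model_logp(model_spec(1), th0["p_base"], dat,
                          include_prior = FALSE))

  ## support violation
  expect_identical(model_logp(model_spec(3),
                              c(p_base = 0.01, m_id = -0.02), dat), -Inf)
  expect_error(abundance_data(11, 10, 0, 0), "exceeds")
})

test_that("maximum likelihood respects the nesting order", {
  set.seed(21)
  dat <- simulate_abundance(0.01, m_hiv = 0.004, m_id = -0.003,
                            sizes = c(10, 10, 10, 10), depth = 2000)
  mle <- vapply(1:5, function(m) {
    spec <- model_spec(m)
    d <- length(spec$features)
    opt <- optim(c(0.01, rep(0, d - 1))[seq_len(d)], function(th) {
      names(th) <- spec$features
      -model_logp(spec, th, dat, include_prior = FALSE)
    }, method = if (d == 1) "Brent" else "Nelder-Mead",
    lower = if (d == 1) 1e-6 else -Inf,
    upper = if (d == 1) 0.5 else Inf)
    -opt$value
  }, 0)
  expect_gte(mle[5] + 1e-6, mle[4])
  expect_gte(mle[4] + 1e-6, max(mle[2], mle[3]))
  expect_gte(mle[2] + 1e-6, mle[1])
  expect_gte(mle[3] + 1e-6, mle[1])
})

test_that("hdi matches exhaustive window search and handles edge cases", {
  x <- 1:100
  expect_equal(unname(hdi(x, 0.94)), c(1, 94))
  ## brute force over all windows on a skewed sample
  set.seed(4)
  y <- rgamma(500, 2)
  h <- hdi(y, 0.94)
  ys <- sort(y)
  m <- ceiling(0.94 * 500)
  widths <- vapply(seq_len(500 - m + 1), function(i) ys[i + m - 1] - ys[i], 0)
  i <- which.min(widths)
  expect_equal(unname(h), c(ys[i], ys[i + m - 1]))

  expect_equal(unname(hdi(rep(3.3, 50))), c(3.3, 3.3))
  ## symmetric unimodal: close to the central interval
  set.seed(5)
  z <- rnorm(4000)
  h2 <- hdi(z, 0.94)
  q <- quantile(z, c(0.03, 0.97))
  expect_lt(abs(h2[1] - q[1]), 0.15)
  expect_lt(abs(h2[2] - q[2]), 0.15)
  expect_error(hdi(1:5), "10 draws")
})

test_that("parameter recovery and information scaling", {
  set.seed(31)
  dat <- simulate_abundance(0.03)           # model 1 truth, depth 10^4
  fit <- fit_abundance_model(model_spec(1), dat, fast_cfg(1))
  pb <- fit$draws[, "p_base"]
  expect_lt(max(fit$rhat), 1.01)
  h <- hdi(pb)
  expect_true(mean(pb) >= h[1] && mean(pb) <= h[2])
  expect_lt(abs(mean(pb) - 0.03), 3 * sd(pb))

  ## depth x100 shrinks the posterior SD by ~ x10
  set.seed(31)
  dat2 <- simulate_abundance(0.03, depth = 1000000L)
  fit2 <- fit_abundance_model(model_spec(1), dat2, fast_cfg(2))
  ratio <- sd(pb) / sd(fit2$draws[, "p_base"])
  expect_gt(ratio, 6); expect_lt(ratio, 15)
})

test_that("percent-change summaries are exact transforms of the draws", {
  set.seed(41)
  dat <- simulate_abundance(0.01, m_id = -0.003)
  fit <- fit_abundance_model(model_spec(3), dat, fast_cfg(3))
  s <- summarize_percent_change(fit, "m_id")
  pct <- 100 * fit$draws[, "m_id"] / fit$draws[, "p_base"]
  expect_equal(s$mean, mean(pct))          # oracle on the shared draws
  expect_equal(s$sd, sd(pct))
  expect_equal(c(s$hdi_lower, s$hdi_upper), unname(hdi(pct)))
  expect_equal(s$direction, "decrease")
  ## HDI contains 94% of draws (+/- 1 draw)
  inside <- mean(pct >= s$hdi_lower & pct <= s$hdi_upper)
  expect_gte(inside, 0.94 - 1 / length(pct))

  ## degenerate deterministic transform
  fit0 <- fit
  fit0$draws <- cbind(p_base = rep(0.01, 50), m_id = rep(-0.0045, 50))
  s0 <- summarize_percent_change(fit0, "m_id")
  expect_equal(s0$mean, -45)
  expect_equal(s0$sd, 0)
  expect_error(summarize_percent_change(fit, "m_hiv"), "not active")
})

test_that("waic + one-SE parsimony selection behave on crafted input", {
  ## ties within SE -> simplest model wins
  tbl <- data.frame(model_id = 1:5, n_features = c(1, 2, 2, 3, 4),
                    elpd_diff = c(0.4, 0.2, 0.3, 0, 0.1),
                    se_diff = c(0.5, 0.5, 0.5, 0, 0.5))
  expect_equal(select_parsimonious(tbl), 1)
  ## a clear winner outside SE of the rest
  tbl2 <- data.frame(model_id = 1:3, n_features = 1:3,
                     elpd_diff = c(40, 20, 0), se_diff = c(4, 3, 0))
  expect_equal(select_parsimonious(tbl2), 3)
  ## waic pointwise identity on a tiny crafted matrix
  ll <- matrix(c(-1, -1.2, -0.9, -2, -2.1, -1.9), nrow = 3)
  w <- waic(ll)
  lppd <- sum(log(colMeans(exp(ll))))
  expect_equal(w$elpd, lppd - sum(apply(ll, 2, var)))
})

test_that("model selection is consistent under simulation", {
  ## criterion-style runs, scaled to 12 reps here for suite runtime; the
  ## full 50-rep version lives in the acceptance suite
  set.seed(55)
  pick <- replicate(12, {
    dat <- simulate_abundance(0.01, sizes = c(12, 12, 12, 12), depth = 5000)
    fits <- lapply(1:5, function(m) suppressWarnings(
      fit_abundance_model(model_spec(m), dat,
                          sampler_config(draws = 400, tune = 400, chains = 2,
                                         seed = sample.int(1e6, 1)))))
    suppressWarnings(compare_and_select(fits))$selected
  })
  expect_gte(mean(pick == 1), 0.8)

  set.seed(56)
  pick_h <- replicate(8, {
    dat <- simulate_abundance(0.01, m_hiv = 0.012,
                              sizes = c(12, 12, 12, 12), depth = 5000)
    fits <- lapply(1:5, function(m) suppressWarnings(
      fit_abundance_model(model_spec(m), dat,
                          sampler_config(draws = 400, tune = 400, chains = 2,
                                         seed = sample.int(1e6, 1)))))
    sel <- suppressWarnings(compare_and_select(fits))$selected
    "m_hiv" %in% model_spec(sel)$features
  })
  expect_gte(mean(pick_h), 0.95)
})
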