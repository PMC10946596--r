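test_that("brinda_adjust_ferritin: identity, hand value, monotonicity", {
  ## at/below both references the correction is the identity
  prm <- list(beta1 = 0.2, beta2 = 0.3, crp_ref = 1, agp_ref = 0.5)
  expect_equal(brinda_adjust_ferritin(c(30, 50), c(1, 0.4), c(0.5, 0.3), prm),
               c(30, 50))
  ## hand computation: ln-excesses (1, 1), PF 100 -> 100 e^-0.5
  pf_adj <- brinda_adjust_ferritin(100, exp(1) * 1, 0.5 * exp(1), prm)
  expect_equal(pf_adj, 100 * exp(-0.5))
  ## inflamed sample with positive betas is adjusted downwards
  expect_lt(brinda_adjust_ferritin(100, 10, 2, prm), 100)

  ## internal fit reproduces a known log-linear relationship
  set.seed(1)
  crp <- rlnorm(300, -1, 1); agp <- rlnorm(300, -0.5, 0.3)
  pf <- exp(3 + 0.25 * log(crp) + 0.4 * log(agp) + rnorm(300, 0, 0.1))
  adj <- brinda_adjust_ferritin(pf, crp, agp, "fit")
  below <- crp <= quantile(crp, 0.1) & agp <= quantile(agp, 0.1)
  expect_equal(adj[below], pf[below])          # reference decile untouched
  expect_true(all(adj[crp > quantile(crp, 0.1)] <
                    pf[crp > quantile(crp, 0.1)]))
  expect_error(brinda_adjust_ferritin(-1, 1, 1, prm), "positive")
})

test_that("classify_iron_status partitions per the enrolment rules", {
  res <- classify_iron_status(
    ferritin_unadjusted = c(40, 45, 45, 45, 30, 30),
    hb = c(120, 116, 75, 110, 120, 120),
    bmi_z = c(0, 0, 0, 0, 2.5, -3.5))
  expect_equal(as.character(res$label),
               c("ID", "sufficient_nonanaemic", "ineligible", "ineligible",
                 "ineligible", "ineligible"))
  expect_equal(res$reason[3:6],
               c("severe_anaemia", "anaemic_sufficient",
                 "bmi_exclusion", "bmi_exclusion"))
  ## exactly one label per input (partition)
  expect_false(any(is.na(res$label)))
  expect_error(classify_iron_status(NA, 120, 0), "missing")
})

test_that("classify_calprotectin bins with inclusive middle boundaries", {
  expect_equal(as.character(classify_calprotectin(c(6, 49.9, 50, 150, 200,
                                                    200.1, 250))),
               c("normal", "normal", "intermediate", "intermediate",
                 "intermediate", "elevated", "elevated"))
  expect_error(classify_calprotectin(-1), "non-negative")
})

test_that("two-way factorial F matches a closed-form balanced oracle", {
  ## balanced 2x2 with additive effects; type-III == classical two-way SS
  set.seed(12)
  n_cell <- 10
  hiv <- rep(c(1, 1, 0, 0), each = n_cell)
  iron <- rep(c(1, 0, 1, 0), each = n_cell)
  y <- 10 + 2 * hiv - 1.5 * iron + rnorm(40, sd = 1)
  res <- two_way_factorial_test(y, hiv, iron, log_transform = FALSE)

  ## closed-form sums-of-squares oracle for the balanced design
  gm <- mean(y)
  ss_a <- 2 * n_cell * sum((tapply(y, hiv, mean) - gm)^2)
  ss_b <- 2 * n_cell * sum((tapply(y, iron, mean) - gm)^2)
  cell <- tapply(y, interaction(hiv, iron), mean)
  ss_cells <- n_cell * sum((cell - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - ave(y, interaction(hiv, iron)))^2)
  f_ab <- (ss_ab / 1) / (ss_e / 36)
  p_ab <- pf(f_ab, 1, 36, lower.tail = FALSE)
  expect_equal(res$p_interaction, p_ab, tolerance = 1e-8)
  if (res$interaction_dropped) {
    ss_e_red <- ss_e + ss_ab
    f_a <- ss_a / (ss_e_red / 37)
    expect_equal(res$p_hiv, pf(f_a, 1, 37, lower.tail = FALSE),
                 tolerance = 1e-8)
  }

  ## crossover interaction is retained
  set.seed(13)
  y2 <- c(rep(0, 10), rep(1, 10), rep(1, 10), rep(0, 10)) + rnorm(40, sd = 0.05)
  res2 <- two_way_factorial_test(y2, hiv, iron, log_transform = FALSE)
  expect_false(res2$interaction_dropped)
  expect_lt(res2$p_interaction, 0.001)

  ## constant outcome: flagged note, p = 1
  res3 <- two_way_factorial_test(rep(5, 40), hiv, iron)
  expect_equal(res3$p_hiv, 1)
  expect_match(res3$note, "constant")

  expect_error(two_way_factorial_test(y[1:20], hiv[1:20], iron[1:20]),
               "empty")
})

test_that("log-transform screening and covariate adjustment work", {
  set.seed(14)
  g <- study_groups(c(20, 20, 20, 20))
  age <- runif(80, 8, 13)
  y <- exp(1 + 0.9 * g$hiv + 0.1 * age + rnorm(80, 0, 0.8))
  res <- two_way_factorial_test(y, g$hiv, g$id,
                                covariates = data.frame(age = age))
  expect_equal(res$transform, "log")
  expect_lt(res$p_hiv, 0.01)
  expect_true(res$interaction_dropped)   # generative model is additive
  ## an aliased covariate triggers a named singularity error
  expect_error(
    two_way_factorial_test(y, g$hiv, g$id,
                           covariates = data.frame(h2 = g$hiv)),
    "aliased")
})

test_that("two-way factorial keeps nominal type-I error under the null", {
  set.seed(15)
  reps <- 400
  g <- study_groups(c(12, 11, 12, 11))
  rej <- replicate(reps, {
    r <- two_way_factorial_test(rnorm(46), g$hiv, g$id,
                                log_transform = FALSE)
    r$p_hiv < 0.05
  })
  ## binomial 3 SE band around 0.05 at 400 reps is about +/- 0.033
  expect_lt(abs(mean(rej) - 0.05), 0.035)
  ## drop rule: without a generative interaction the reduced model is used
  drop_rate <- mean(replicate(200, two_way_factorial_test(
    rnorm(46), g$hiv, g$id, log_transform = FALSE)$interaction_dropped))
  expect_gte(drop_rate, 0.90)
})

test_that("two_way_logistic_test: drop rule, null calibration, separation", {
  set.seed(16)
  g <- study_groups()
  ## additive-logit outcome: interaction dropped in most replicates
  dropped <- replicate(60, {
    p <- plogis(-0.5 + 0.8 * g$hiv + 0.5 * g$id)
    two_way_logistic_test(rbinom(166, 1, p), g$hiv, g$id)$interaction_dropped
  })
  expect_gte(mean(dropped), 0.90)

  ## null calibration at alpha 0.05 (Wald)
  set.seed(17)
  rej <- replicate(400, {
    two_way_logistic_test(rbinom(166, 1, 0.4), g$hiv, g$id)$p_hiv < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.035)

  ## outcome equal to hiv: separation flag
  res <- two_way_logistic_test(g$hiv, g$hiv, g$id)
  expect_true(res$flagged)
  expect_error(two_way_logistic_test(rep(1, 166), g$hiv, g$id), "classes")
})

test_that("bonferroni_chisq_posthoc: letters, cap, hand statistic", {
  ## identical compositions: all adjusted p = 1, single shared letter
  t_same <- rbind(c(10, 10, 10, 10), c(20, 20, 20, 20))
  ph <- bonferroni_chisq_posthoc(t_same)
  expect_true(all(ph$pairwise$p_adj == 1))
  expect_true(all(ph$letters == "a"))

  ## one extreme group receives its own letter
  t_ext <- rbind(c(18, 27, 23, 3), c(25, 14, 21, 35))
  ph2 <- bonferroni_chisq_posthoc(t_ext)
  expect_equal(unname(ph2$letters),  c("a", "a", "a", "b"))

  ## pairwise statistic equals the closed-form 2x2 chi-squared
  t2 <- rbind(c(12, 5), c(8, 15))
  ph3 <- bonferroni_chisq_posthoc(cbind(t2, c(10, 10), c(10, 10)))
  a <- 12; b <- 5; cc <- 8; d <- 15; n <- a + b + cc + d
  hand <- n * (a * d - b * cc)^2 / ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(ph3$pairwise$statistic[1], hand)
  expect_true(all(ph3$pairwise$p_adj >= ph3$pairwise$p_raw))

  ## zero-margin group excluded with warning
  expect_warning(
    ph4 <- bonferroni_chisq_posthoc(rbind(c(5, 5, 0, 5), c(5, 5, 0, 5))),
    "zero-margin")
  expect_equal(nrow(ph4$pairwise), 3)
})
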