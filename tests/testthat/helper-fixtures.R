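# Shared fixtures, built in code at test time.

## small deterministic count table
toy_table <- function() {
  m <- matrix(c(5L, 0L, 3L,
                2L, 2L, 2L,
                0L, 0L, 10L,
                1L, 3L, 0L), 4, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  genus_count_table(m)
}

## factorial cohort skeleton at the study's group sizes
study_groups <- function(sizes = c(43L, 41L, 44L, 38L)) {
  grp <- rep(1:4, sizes)
  list(group = grp,
       hiv = as.integer(grp %in% c(1L, 2L)),
       id = as.integer(grp %in% c(1L, 3L)))
}

## single-genus binomial simulation under an abundance model spec
## (additive on the probability scale, exactly the fitted model family)
simulate_abundance <- function(p_base, m_hiv = 0, m_id = 0, m_int = 0,
                               depth = 10000L,
                               sizes = c(43L, 41L, 44L, 38L)) {
  g <- study_groups(sizes)
  p <- p_base + m_hiv * g$hiv + m_id * g$id + m_int * g$hiv * g$id
  stopifnot(all(p > 0), all(p < 1))
  n <- length(g$hiv)
  abundance_data(rbinom(n, depth, p), rep(depth, n), g$hiv, g$id)
}

## short sampler settings for simulation-heavy tests (documented scaling:
## posteriors here are 2-5 dimensional and near-Gaussian, so 2 chains x
## 750 draws are ample for point summaries while keeping the suite fast)
fast_cfg <- function(seed, target_accept = 0.8) {
  sampler_config(draws = 750, tune = 600, chains = 2,
                 target_accept = target_accept, seed = seed)
}

## the 5-parameter mixture needs a longer warmup than the 2-3 parameter
## abundance models to stay inside the R-hat contract
mix_cfg <- function(seed) {
  sampler_config(draws = 1200, tune = 1800, chains = 2,
                 target_accept = 0.9, seed = seed)
}
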