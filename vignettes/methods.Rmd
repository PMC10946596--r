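---
title: "Models and methods in mbfact"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mbfact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mbfact` analyses 2×2 factorial case–control microbiome studies: every
participant carries two binary exposures (called `hiv` and `id_status`
throughout, after the motivating HIV × iron-deficiency design), giving
four groups whose fourth (neither exposure) is the reference. This
vignette is the package's own account of its models, the choices made
where the design was genuinely open, and what the tests do and do not
establish.

## The abundance models

For one genus, the count `k_i` out of library size `N_i` in sample `i`
is modelled as

$$k_i \sim \mathrm{Binomial}(N_i, p_i), \qquad
  p_i = p_{base} + m_{hiv}\,h_i + m_{id}\,d_i + m_{int}\,h_i d_i,$$

with `h`, `d` the 0/1 exposure indicators. Five nested models grow the
feature set: {`p_base`}, +`m_hiv`, +`m_id`, both main effects, and both
plus the interaction. Effects are **additive on the probability scale**,
not on a logit scale, deliberately: the reported effect is the posterior
of `100·m/p_base`, a percent change in relative abundance, and that
transform is exact only under the additive parameterisation.

A binomial likelihood treats reads within a sample as exchangeable
draws, which ignores overdispersion between biological replicates; the
per-genus, per-group percent-change scale absorbs most of this in
practice, and the synthetic generator (below) reproduces exactly this
sampling mechanism, so recovery tests are internally consistent. The
likelihood sits behind a single function (`model_logp()`), which is the
extension point if a beta-binomial variant is ever needed.

**Priors.** "Noninformative" is made concrete as `p_base ~ Uniform(0,1)`
and each `m ~ Uniform(−1,1)`, with the joint support truncated so every
sample's `p_i` stays in (0,1). These are flat, proper, and
support-respecting; with `N_i ≈ 10^4` the likelihood dominates and the
prior's only visible action is the support truncation.

## Sampling

No gradient-based (NUTS-style) engine is available in this environment,
so the package ships its own sampler: adaptive random-walk Metropolis
with Haario covariance adaptation, plus an independence-proposal
component whose mean and covariance are learned during warmup (the two
kernels are mixed 50/50 after warmup; each leaves the posterior
invariant). The posteriors here are 2–5 dimensional and close to
Gaussian, so the independence component delivers near-iid draws;
observed effective sample sizes exceed 2,000 per fit at the default
settings (4 chains × 4,000 draws after 2,000 warmup steps).

Two conventions are worth recording:

* `sampler_config()$target_accept` keeps the familiar defaults (0.8;
  0.9 for the mixture), but those values carry step-size-adaptation
  semantics from Hamiltonian samplers. For a random-walk kernel the
  efficient acceptance band is ≈0.23–0.45, and forcing 0.9 makes step
  sizes collapse (we observed split-R̂ of 1.2–1.6 on the mixture). The
  Robbins–Monro target is therefore capped internally at 0.40.
* Convergence is a contract, not a hope: every fit computes split-R̂
  and ESS, and any parameter with split-R̂ ≥ 1.01 flags the fit — it is
  returned with a warning, and `run_pipeline()` refuses to continue
  unless `allow_flagged = TRUE`.

## Model selection

The study design this package follows selected "the simplest model with
the best fit" by visual inspection of a model-comparison plot. The
automated stand-in is WAIC with a one-standard-error parsimony rule:
compute pointwise WAIC per model, the SE of each model's pairwise elpd
*difference* from the best model, and select the fewest-feature model
whose gap to the best is within that SE. On data simulated from model 1
this chooses model 1 in well over 80% of replicates; a real main effect
of plausible size is picked up essentially always.

## Effect summaries

Per draw, the percent change for feature `m` is `100·m/p_base`; the
summary reports its posterior mean, SD and 94% highest-density interval.
The HDI is the shortest contiguous window of the sorted draws holding
`ceiling(0.94·n)` points — checked in the tests against an exhaustive
window search. Note the HDI of a transform need not contain the
transform of the posterior means, and multiplicity across genera is
handled by reporting intervals, not p-values.

## The prevalence mixture

For a sparse genus the interesting quantity may be who carries it at
all. Each group `g` gets a carrier weight `w_g` with a flat Dirichlet
prior on `(w_g, 1−w_g)`; a sample's count is a structural zero with
probability `1−w_g`, otherwise `Binomial(N_i, p_base)` with one carrier
abundance shared across groups, `p_base ~ HalfNormal(σ = 0.001)` — the
scale keeps the carrier component in the rare-genus regime. The carrier
label cannot switch: the non-carrier component has success probability
exactly zero. A carrier may still show `k = 0` (probability
`(1−p_base)^N`), and the likelihood allows that without correction.

Contrasts are **absolute prevalence differences in percentage points**,
`100·(w_g − w_ref)`. The alternative relative-change reading of a
"higher prevalence" statement is available by post-processing the draw
matrix, but percentage points are the default and the documented
interpretation.

## The synthetic cohort

`generate_cohort()`/`generate_counts()` state a world and stick to it:

* **Design**: 166 participants in groups 43/41/44/38 by default.
* **Counts**: one multinomial per sample over the panel genera plus a
  dominant `Prevotella`-like background filler that absorbs the
  remaining reads. Row sums equal library sizes exactly, and each genus
  is marginally `Binomial(N_i, p_cell)` — the same family the abundance
  models assume.
* **Effects** combine multiplicatively:
  `p_cell = baseline·(1+pct_hiv/100·h)·(1+pct_id/100·d)·(1+pct_int/100·hd)`.
  A multiplicative world with two main effects implies a small negative
  additive interaction; to simulate exactly under the additive model 4,
  set `pct_interaction = 100·((1+h+d)/((1+h)(1+d)) − 1)` (the acceptance
  script does this for the joint-effect target).
* **Zero inflation**: per-group carrier probabilities, drawn per sample.
* **Library sizes**: the source design never states sequencing depth;
  depths are negative-binomial around `depth_mean` (default 10,000,
  dispersion 10), floored at 1,000, or exactly `depth_mean` when
  `depth_dispersion = NULL`.
* **Clinical markers** are log-normal (haemoglobin: normal) with
  additive factorial effects on the log scale — a generative convenience
  chosen only to exercise the clinical tests, not a claim about marker
  biology. Baselines sit at values typical for a school-age cohort of
  this kind.
* **Metadata width**: 31 noise covariates plus age, sex, ethnicity and
  deworming emulate a ~35-variable metadata screen.

The default panel encodes every published effect the package targets
(per-10,000 baselines with signed HIV percent changes; three genera with
iron effects; a zero-inflated genus with carrier prevalences
0.80/0.50/0.50/0.38). Baselines for the three iron-effect genera are not
published and are stand-ins (50, 20, 100 per 10,000). What a green
recovery test establishes is that *the pipeline recovers effects from
data generated under its own assumed sampling mechanism at realistic
depth and size* — it says nothing about taxonomic misassignment,
compositional coupling between many large simultaneous effects, or
overdispersion beyond the multinomial.

## Preprocessing conventions

* Prevalence filter: a genus is kept iff detected in ≥ 20% of samples —
  "less than 20%" is excluded, so exactly-at-threshold survives.
* CLR: `x = log((c+0.5)/g)` with the pseudocount applied uniformly
  before the geometric mean; 0.5 is a convention (the source is silent)
  and configurable.
* Rarefaction: sampling without replacement; samples below the target
  depth are dropped with a warning, never up-sampled; default depth is
  the minimum library size.
* Bray–Curtis in the pipeline runs on proportions (the statistic is
  scale-dependent); whether to rarefy first is exposed, not imposed.
* PCoA reports negative eigenvalues unapologetically (no
  Lingoes/Cailliez correction) and excludes their axes from coordinates.

## Constrained ordination

Euclidean RDA on CLR data is multivariate least squares, so
`rda_effect_size()` projects the column-centred CLR matrix on the
(dummy-coded, centred) design block of one variable: `R²` is explained
sum of squares over total, the permutation p uses the pseudo-F under row
permutation with the `(1+exceedances)/(1+n_perm)` convention, and
categorical variables pool their dummy columns. The per-variable screen
is BH-adjusted with the study-wide FDR < 0.1 convention.

Forward selection is the two-step forced-feature procedure: forced
variables enter unconditionally first (logged with their at-entry
partial permutation p), then free variables enter greedily by best
adjusted-R² gain, subject to partial permutation p < 0.05 (the common
stepwise default; the source is silent) and the scope rule — cumulative
adjusted R² may not exceed the all-variables model's. One documented
sharp edge: when the remaining candidates are pure noise, a noise
column's expected R² gain exactly offsets the adjustment penalty, so the
scope comparison becomes a coin flip; the rule is kept as stated, and
the property tests use designs where the scope model has genuine signal
margin.

## Clinical statistics

* Two-way factorial ANCOVA uses sum contrasts with partial (type-III)
  F tests — the default cell sizes 43/41/44/38 are unbalanced, where
  sequential sums of squares would depend on term order.
* Interaction-drop rule: if the interaction's p ≥ 0.05 the model is
  refitted without it and main effects are reported from the reduced
  model.
* The log-transform decision ("non-normally distributed outcomes were
  log-transformed") is operationalised as Shapiro–Wilk on the
  full-model residuals at α = 0.05, positive outcomes only, overridable
  per outcome.
* Calprotectin bins put both boundary values (50 and 200 µg/g) in the
  middle bin; only ">200" is strict.
* BRINDA ferritin adjustment uses the internal-regression form (slopes
  of ln PF on ln CRP and ln AGP; references at each marker's lowest
  decile); external coefficients can be supplied for cross-cohort
  exactness.
* The compact letter display is built by insert-and-absorb over the
  significant pairs of the Bonferroni-adjusted pairwise χ² tests
  (no continuity correction, so the statistic matches the closed-form
  2×2 formula).
* Within-group β-diversity compares sets of pairwise distances with
  rank tests although pairwise distances are not independent
  observations; the package reproduces that field convention and
  records the caveat here.

## Known limitations

* The binomial likelihood has no overdispersion term; between-subject
  variance beyond the binomial shows up in the posterior SD only through
  sample-to-sample variation in `k_i/N_i`.
* The sampler is tuned for the low-dimensional posteriors in this
  package; it is not a general-purpose MCMC engine.
* Wald p-values in the logistic test are first-order; separation is
  flagged, not penalised (no Firth correction).
* A power calculation is deliberately not implemented: the effect-size
  metric behind the motivating design's power statement is ambiguous,
  so any implementation would be a guess presented as a check.
* File interchange is TSV/JSON only; HDF5-based containers (e.g. BIOM
  2.1) are out of scope for a text-only deliverable.
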