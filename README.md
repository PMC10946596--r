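# mbfact

Two-way factorial analysis of gut-microbiome genus counts and clinical
markers, built for 2×2 case–control designs in which every participant
carries two binary exposures — the motivating setting is HIV status ×
iron-deficiency (ID) status in school-age children, with four groups
(HIV+/ID, HIV+/iron-sufficient, HIV−/ID, HIV−/iron-sufficient; the last
is the reference).

Study cohorts of this kind are rarely deposited, so the package pairs
every analysis stage with a ground-truth synthetic cohort generator:
you can state per-genus effect sizes, zero-inflation patterns and
clinical-marker effects, generate a cohort, and verify that the whole
pipeline recovers what you put in.

## What it computes

**Bayesian differential abundance.** For a genus with count `k_i` out of
library size `N_i`, five nested binomial models are fitted:

    k_i ~ Binomial(N_i, p_i)
    p_i = p_base + m_hiv·hiv_i + m_id·id_i + m_int·hiv_i·id_i

Model 1 has only `p_base`; models 2/3 add one main effect; model 4 both;
model 5 the interaction. Features carry flat priors (`p_base ~ U(0,1)`,
`m ~ U(−1,1)`, jointly truncated to keep every `p_i` in (0,1)) and are
sampled by an adaptive MCMC engine (4 chains, 2,000 warmup, 4,000 draws;
split-R̂ < 1.01 contract). The simplest model within one standard error
of the best WAIC is selected, and effects are reported as the posterior
of `100·m/p_base`: a percent change in relative abundance with its 94%
highest-density interval (HDI).

**Zero-inflated prevalence mixture.** For a sparse genus, each group `g`
gets a carrier weight `w_g` (flat Dirichlet prior) and carriers share one
abundance `p_base ~ HalfNormal(0.001)`; the likelihood mixes a
structural-zero component with `Binomial(N_i, p_base)`. Prevalence
contrasts `w_g − w_ref` are reported in percentage points with 94% HDIs.

**Everything around it.** 20% prevalence filtering, rarefaction, CLR
transform; Shannon α-diversity and Bray–Curtis β-diversity with
Kruskal–Wallis + Dunn (BH-adjusted) group tests and PCoA; per-variable
RDA effect sizes on CLR data (permutation-tested, BH/FDR screened) with
forced-feature forward selection; BRINDA ferritin adjustment, enrolment
iron-status and calprotectin classification; unbalanced two-way
factorial ANCOVA (type-III, interaction-drop rule) and two-way logistic
tests with Bonferroni χ² post hoc letters.

## Worked example

Simulate one genus at a baseline of 309.7 reads per 10,000 with a +112%
HIV effect in a 166-child cohort (groups 43/41/44/38, 10,000 reads per
sample), then let the package find and quantify the effect:

```r
library(mbfact)
cfg  <- cohort_config(seed = 2024, depth_dispersion = NULL)
meta <- generate_cohort(cfg)
tab  <- generate_counts(meta, default_genus_panel()["Bacteroides"], cfg)
dat  <- abundance_data(tab$counts[, "Bacteroides"], tab$library_size,
                       meta$hiv, meta$id_status)
fits <- lapply(1:5, function(m)
  fit_abundance_model(model_spec(m), dat, sampler_config(seed = 2024 + m)))
cmp  <- compare_and_select(fits)
sel  <- fits[[cmp$selected]]
cat("selected model:", cmp$selected, "\n")
cat("baseline per 10k:", round(mean(sel$draws[, "p_base"]) * 1e4, 1), "\n")
summarize_percent_change(sel, "m_hiv")
```

Output:

```
selected model: 2
baseline per 10k: 309.1
m_hiv: increase of 111.1% +/- 1.5 (94% HDI 108.2 to 114.0)
```

The HIV-only model is selected over both the simpler and the more
complex alternatives, the reference-cell baseline is recovered (309.1 vs
309.7 per 10,000), and the posterior percent change brackets the
generative +112%.

The full pipeline (filtering → diversity → RDA → abundance models →
prevalence mixture → clinical tests, with TSV/JSON outputs and a run
manifest) runs via `run_pipeline()`, or from the shell:

```sh
Rscript inst/scripts/mbfact-cli.R simulate --seed 1 --out sim/
Rscript inst/scripts/mbfact-cli.R run --counts sim/counts.tsv \
    --metadata sim/metadata.tsv --seed 1 --out out/ --genera Bacteroides
```

## Vignette

`vignettes/methods.Rmd` documents the models and their assumptions, the
synthetic-cohort generator's design choices, the sampler, numerical
conventions and known limitations.
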