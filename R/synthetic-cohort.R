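#' Per-genus generative parameters
#'
#' Describes one genus of the synthetic panel. Expected relative abundance
#' in a factorial cell is
#' `(baseline_per_10k / 1e4) * (1 + pct_hiv/100 * hiv) *
#'  (1 + pct_id/100 * id) * (1 + pct_interaction/100 * hiv * id)`,
#' i.e. percent effects combine multiplicatively. `carrier_prev` gives the
#' per-group probability that an individual carries the genus at all
#' (group order: HIV+/ID, HIV+/suff, HIV-/ID, HIV-/suff); `c(1,1,1,1)`
#' means no zero inflation.
#'
#' @param name genus label.
#' @param baseline_per_10k expected reads per 10,000 in the unexposed
#'   (HIV-/iron-sufficient) cell; non-negative.
#' @param pct_hiv,pct_id percent change in relative abundance attributable
#'   to each factor (> -100).
#' @param pct_interaction extra percent change when both factors present.
#' @param carrier_prev numeric length 4 in `[0, 1]`.
#' @return A `genus_params` list.
#' @export
genus_params <- function(name, baseline_per_10k, pct_hiv = 0, pct_id = 0,
                         pct_interaction = 0, carrier_prev = rep(1, 4)) {
  stopifnot(is.character(name), length(name) == 1L,
            baseline_per_10k >= 0,
            pct_hiv > -100, pct_id > -100,
            length(carrier_prev) == 4L)
  if (any(carrier_prev < 0 | carrier_prev > 1))
    stop("carrier_prev entries must lie in [0, 1]")
  gp <- structure(list(name = name, baseline_per_10k = baseline_per_10k,
                       pct_hiv = pct_hiv, pct_id = pct_id,
                       pct_interaction = pct_interaction,
                       carrier_prev = carrier_prev),
                  class = "genus_params")
  p <- cell_proportions(gp)
  if (any(p < 0) || any(p >= 1))
    stop(sprintf("genus '%s': expected proportion outside (0,1) in some cell",
                 name))
  gp
}

## expected relative abundance in the four cells, group order 1..4
cell_proportions <- function(gp) {
  base <- gp$baseline_per_10k / 1e4
  h <- c(1, 1, 0, 0); d <- c(1, 0, 1, 0)
  base * (1 + gp$pct_hiv / 100 * h) * (1 + gp$pct_id / 100 * d) *
    (1 + gp$pct_interaction / 100 * h * d)
}

#' Cohort configuration for the synthetic generator
#'
#' Defaults mirror the study design the package targets: 166 children in
#' four groups of 43/41/44/38 and sequencing depth around 10,000 reads.
#' The paper underlying the design does not state a depth; library sizes
#' are negative-binomially distributed around `depth_mean` (dispersion =
#' NB `size`), floored at 1,000 reads, or exactly `depth_mean` when
#' `depth_dispersion` is `NULL`.
#'
#' @param group_sizes four non-negative integers (HIV+/ID, HIV+/suff,
#'   HIV-/ID, HIV-/suff).
#' @param depth_mean,depth_dispersion library-size model; `depth_mean > 0`.
#' @param seed integer master seed or `NULL`.
#' @param n_nuisance number of pure-noise metadata covariates appended to
#'   emulate a wide (35-variable) metadata screen.
#' @param marker_spec named list of clinical-marker generators; see
#'   [default_marker_spec()].
#' @param background_genus name of the compositional filler genus that
#'   absorbs all reads not assigned to the panel.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(group_sizes = c(43L, 41L, 44L, 38L),
                          depth_mean = 10000, depth_dispersion = 10,
                          seed = NULL, n_nuisance = 31L,
                          marker_spec = default_marker_spec(),
                          background_genus = "Prevotella") {
  stopifnot(length(group_sizes) == 4L, all(group_sizes >= 0),
            sum(group_sizes) > 0, depth_mean > 0)
  if (!is.null(depth_dispersion) && depth_dispersion <= 0)
    stop("depth_dispersion must be positive or NULL")
  if (!is.list(marker_spec) || is.null(names(marker_spec)) ||
      any(names(marker_spec) == ""))
    stop("marker_spec must be a fully named list")
  structure(list(group_sizes = as.integer(group_sizes),
                 depth_mean = depth_mean,
                 depth_dispersion = depth_dispersion,
                 seed = seed, n_nuisance = as.integer(n_nuisance),
                 marker_spec = marker_spec,
                 background_genus = background_genus),
            class = "cohort_config")
}

#' Default clinical-marker generators
#'
#' Each marker is drawn log-normally (haemoglobin: normally) with additive
#' factorial effects on the log (resp. raw) scale. Baselines are set to
#' the medians/means a comparable cohort would show; effects reproduce the
#' qualitative factorial pattern (ID lowers haemoglobin and ferritin and
#' raises calprotectin; HIV raises sTfR, CRP and AGP).
#'
#' @return Named list; each element has fields `dist` ("lognormal" or
#'   "normal"), `baseline`, `hiv`, `iron` (multiplicative fold effects for
#'   lognormal, additive for normal) and `sdlog`/`sd`.
#' @export
default_marker_spec <- function() {
  list(
    hb           = list(dist = "normal",    baseline = 124, hiv = -1,
                        iron = -5,  sd = 9),
    ferritin     = list(dist = "lognormal", baseline = 38,  hiv = 1.0,
                        iron = 0.47, sdlog = 0.35),
    stfr         = list(dist = "lognormal", baseline = 6.2, hiv = 1.12,
                        iron = 1.05, sdlog = 0.25),
    crp          = list(dist = "lognormal", baseline = 0.06, hiv = 2.2,
                        iron = 1.0,  sdlog = 1.5),
    agp          = list(dist = "lognormal", baseline = 0.52, hiv = 1.18,
                        iron = 1.0,  sdlog = 0.30),
    calprotectin = list(dist = "lognormal", baseline = 7,   hiv = 1.0,
                        iron = 3.3,  sdlog = 1.3),
    ifabp        = list(dist = "lognormal", baseline = 800, hiv = 1.0,
                        iron = 1.0,  sdlog = 0.45))
}

#' Generate per-sample cohort metadata
#'
#' Produces one record per participant with group indicators, covariates
#' (age, sex, ethnicity, deworming plus `n_nuisance` noise covariates) and
#' clinical markers drawn from `config$marker_spec`. Identical seeds give
#' identical output.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `sample_id`, `hiv`, `id_status`,
#'   `group` (factor g1..g4), covariates and markers.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  gs <- config$group_sizes
  n <- sum(gs)
  group <- rep(1:4, gs)
  hiv <- as.integer(group %in% c(1, 2))
  id  <- as.integer(group %in% c(1, 3))
  ## ethnicity fractions differ by group on purpose (exercises the
  ## chi-square post hoc); deworming near-universal
  eth_p <- c(0.42, 0.66, 0.52, 0.08)[group]
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    hiv = hiv, id_status = id,
    group = factor(paste0("g", group), levels = paste0("g", 1:4)),
    age = round(runif(n, 8, 13), 1),
    sex = factor(ifelse(rbinom(n, 1, 0.5) == 1, "male", "female")),
    ethnicity = factor(ifelse(rbinom(n, 1, eth_p) == 1, "ethA", "ethB")),
    deworming = factor(ifelse(rbinom(n, 1, 0.96) == 1, "yes", "no")),
    stringsAsFactors = FALSE)
  for (mk in names(config$marker_spec)) {
    sp <- config$marker_spec[[mk]]
    if (identical(sp$dist, "normal")) {
      mu <- sp$baseline + sp$hiv * hiv + sp$iron * id
      meta[[mk]] <- pmax(round(rnorm(n, mu, sp$sd), 1), 0)
    } else if (identical(sp$dist, "lognormal")) {
      mu <- log(sp$baseline) + log(sp$hiv) * hiv + log(sp$iron) * id
      meta[[mk]] <- round(rlnorm(n, mu, sp$sdlog), 3)
    } else stop(sprintf("marker '%s': unknown dist '%s'", mk, sp$dist))
  }
  if (config$n_nuisance > 0) {
    for (j in seq_len(config$n_nuisance))
      meta[[sprintf("nuis%02d", j)]] <- round(rnorm(n), 4)
  }
  meta
}

#' Generate a compositional genus count table
#'
#' For each sample a library size is drawn (see [cohort_config()]), each
#' panel genus draws a carrier state from its group's `carrier_prev`, and
#' reads are then allocated by a single multinomial over the carried panel
#' genera plus a dominant background filler, so row sums equal the drawn
#' depths exactly and each genus count is marginally
#' `Binomial(N_i, p_cell)`.
#'
#' @param meta metadata from [generate_cohort()].
#' @param panel list of [genus_params()].
#' @param config a [cohort_config()]; its `seed` (offset by 1) controls
#'   this step.
#' @return A [genus_count_table()] with ground-truth attributes `panel`
#'   and `carrier` (logical samples x genera carrier states).
#' @export
generate_counts <- function(meta, panel, config) {
  stopifnot(inherits(config, "cohort_config"), is.list(panel))
  if (length(panel) == 0) stop("empty genus panel")
  if (!all(vapply(panel, inherits, TRUE, "genus_params")))
    stop("panel must be a list of genus_params")
  nms <- vapply(panel, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicated genus names in panel")
  if (config$background_genus %in% nms)
    stop("background genus must not also be a panel genus")
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  n <- nrow(meta)
  G <- length(panel)
  group <- as.integer(meta$group)
  pcell <- vapply(panel, cell_proportions, numeric(4))   # 4 x G
  if (any(rowSums(pcell) >= 1))
    stop("panel expected proportions sum to >= 1 in some cell")
  if (is.null(config$depth_dispersion)) {
    depth <- rep(as.integer(round(config$depth_mean)), n)
  } else {
    depth <- pmax(rnbinom(n, mu = config$depth_mean,
                          size = config$depth_dispersion), 1000L)
  }
  prev <- vapply(panel, `[[`, numeric(4), "carrier_prev")  # 4 x G
  carrier <- matrix(rbinom(n * G, 1, prev[group, , drop = FALSE]) == 1, n, G)
  counts <- matrix(0L, n, G + 1L,
                   dimnames = list(meta$sample_id,
                                   c(nms, config$background_genus)))
  for (i in seq_len(n)) {
    p <- pcell[group[i], ] * carrier[i, ]
    counts[i, ] <- as.integer(rmultinom(1, depth[i], c(p, 1 - sum(p))))
  }
  tab <- genus_count_table(counts)
  attr(tab, "panel") <- panel
  attr(tab, "carrier") <- `dimnames<-`(carrier, list(meta$sample_id, nms))
  tab
}

#' Default genus panel
#'
#' The built-in generative panel: every genus whose relative abundance is
#' confidently linked to the HIV factor, with its baseline reads per
#' 10,000 in the unexposed cell and signed percent change under HIV;
#' three genera with iron (and HIV) effects (`Anaerostipes` -45% ID,
#' `Anaerotruncus` -56% ID, `Fusicatenibacter` -29% HIV and -35% ID); and
#' a zero-inflated `Megamonas`-like genus (carrier abundance 20/10,000,
#' carrier prevalences 0.80/0.50/0.50/0.38 across the four groups). The
#' dominant `Prevotella` background is supplied by [generate_counts()] as
#' the compositional filler, not as a panel entry. Baselines for the three
#' iron-effect genera are stand-ins (50, 20 and 100 per 10,000).
#'
#' @return list of [genus_params()].
#' @export
default_genus_panel <- function() {
  up <- list(  # more abundant under HIV
    c("Butyricimonas", 9.5, 67), c("Sutterella", 13.2, 102),
    c("Desulfomicrobium", 7.2, 105), c("Bacteroides", 309.7, 112),
    c("Alistipes", 42.7, 130), c("Clostridium_XlVb", 8.5, 144),
    c("Barnesiella", 14.3, 150), c("Desulfovibrio", 19.0, 154),
    c("Parabacteroides", 52.0, 160), c("Clostridium_XVIII", 16.2, 180),
    c("Bilophila", 4.5, 202), c("Phascolarctobacterium", 12.8, 236),
    c("Subdoligranulum", 1.5, 253), c("Odoribacter", 8.4, 263),
    c("Fusobacterium", 0.6, 10993))
  dn <- list(  # less abundant under HIV (percent decreases)
    c("Turicibacter", 25.6, -81), c("Romboutsia", 37.3, -71),
    c("Intestinibacter", 18.2, -63), c("Clostridium_sensu_stricto", 58.0, -57),
    c("Terrisporobacter", 7.4, -56), c("Olsenella", 55.0, -56),
    c("Dialister", 208.2, -55), c("Bifidobacterium", 615.9, -49),
    c("Roseburia", 694.1, -25), c("Dorea", 264.2, -17),
    c("Faecalibacterium", 1437.8, -16))
  panel <- lapply(c(up, dn), function(x)
    genus_params(x[1], as.numeric(x[2]), pct_hiv = as.numeric(x[3])))
  panel <- c(panel, list(
    genus_params("Anaerostipes", 50, pct_id = -45),
    genus_params("Anaerotruncus", 20, pct_id = -56),
    genus_params("Fusicatenibacter", 100, pct_hiv = -29, pct_id = -35),
    genus_params("Megamonas", 20,
                 carrier_prev = c(0.80, 0.50, 0.50, 0.38))))
  names(panel) <- vapply(panel, `[[`, "", "name")
  panel
}

#' Write a simulated cohort to disk
#'
#' Writes `counts.tsv` (samples x genera), `metadata.tsv` and a
#' `truth.json` sidecar recording all generative parameters and the seed.
#'
#' @param meta,table,config as produced by the generator functions.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_cohort <- function(meta, table, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("counts.tsv", "metadata.tsv", "truth.json"))
  write_count_tsv(table, paths[1])
  write.table(meta, paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- attr(table, "panel")
  names(panel) <- vapply(panel, `[[`, "", "name")
  truth <- list(
    seed = config$seed, group_sizes = config$group_sizes,
    depth_mean = config$depth_mean,
    depth_dispersion = config$depth_dispersion,
    background_genus = config$background_genus,
    panel = lapply(panel, unclass))
  jsonlite::write_json(truth, paths[3], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(paths)
}
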