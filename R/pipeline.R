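#' Pipeline configuration
#'
#' One declarative object holding every stage's parameters. All
#' randomness flows from `seed` via fixed per-stage offsets, so a config
#' plus its seed reproduces every output bit-for-bit for the
#' deterministic stages and draw-for-draw for the samplers.
#'
#' @param seed master integer seed.
#' @param prevalence_threshold genus prevalence filter fraction.
#' @param clr_pseudocount pseudocount for [clr_transform()].
#' @param rarefaction_depth rarefaction depth or `NULL` (= min library
#'   size).
#' @param rda_n_perm permutations for the RDA screen and selection.
#' @param rda_alpha stepwise entry threshold.
#' @param forced variables forced first in [forward_select_forced()].
#' @param sampler a [sampler_config()] for the abundance models.
#' @param mixture_sampler a [sampler_config()] for the prevalence
#'   mixture (default `target_accept = 0.9`).
#' @param genera genus names for the Bayesian stage, or `NULL` = all
#'   filtered genera except the background/"unclassified" columns.
#' @param mixture_genus genus for the prevalence mixture, or `NULL` to
#'   skip.
#' @param markers clinical marker columns to test.
#' @param rda_vars metadata columns screened by RDA, or `NULL` = every
#'   column except ids/indicators/markers.
#' @param background_genus excluded from per-genus model fits.
#' @param stages character subset of
#'   `c("preprocess", "diversity", "rda", "bayes", "mixture", "clinical")`.
#' @param allow_flagged if `FALSE` (default), [run_pipeline()] stops when
#'   a sampler fit fails its convergence contract.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            prevalence_threshold = 0.20,
                            clr_pseudocount = 0.5,
                            rarefaction_depth = NULL,
                            rda_n_perm = 999, rda_alpha = 0.05,
                            forced = "hiv",
                            sampler = sampler_config(seed = seed + 101L),
                            mixture_sampler =
                              sampler_config(target_accept = 0.9,
                                             seed = seed + 202L),
                            genera = NULL, mixture_genus = "Megamonas",
                            markers = c("calprotectin", "ifabp"),
                            rda_vars = NULL,
                            background_genus = "Prevotella",
                            stages = c("preprocess", "diversity", "rda",
                                       "bayes", "mixture", "clinical"),
                            allow_flagged = FALSE) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full factorial microbiome analysis
#'
#' Executes preprocess -> diversity -> constrained ordination ->
#' Bayesian abundance models -> prevalence mixture -> clinical factorial
#' statistics on the selected stages, writing TSV/JSON outputs and a run
#' manifest (package version, seed, parameters, convergence flags,
#' filter counts) under `out_dir`.
#'
#' @param counts a [genus_count_table()] or path to a counts TSV.
#' @param metadata data.frame or path to a metadata TSV; must contain
#'   `sample_id`, `hiv`, `id_status`.
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or `NULL` to skip file output.
#' @return Invisibly, a list with the per-stage results and `manifest`.
#' @export
run_pipeline <- function(counts, metadata, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(counts)) counts <- read_count_tsv(counts)
  if (is.character(metadata))
    metadata <- read.table(metadata, sep = "\t", header = TRUE)
  stopifnot(inherits(counts, "genus_count_table"))
  miss_meta <- setdiff(counts$sample_ids, metadata$sample_id)
  miss_cnt <- setdiff(metadata$sample_id, counts$sample_ids)
  if (length(miss_meta) || length(miss_cnt))
    stop("sample id mismatch; missing from metadata: [",
         paste(miss_meta, collapse = ", "), "]; missing from counts: [",
         paste(miss_cnt, collapse = ", "), "]")
  metadata <- metadata[match(counts$sample_ids, metadata$sample_id), ]
  res <- list()
  flags <- character()
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write.table(df, file.path(out_dir, name), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  group <- factor(paste0("g", 4L - 2L * metadata$hiv - metadata$id_status),
                  levels = paste0("g", 1:4))

  ## --- preprocess ---------------------------------------------------------
  filt <- prevalence_filter(counts, config$prevalence_threshold)
  res$filtered <- filt
  res$n_dropped_genera <- length(attr(filt, "dropped"))
  clr <- clr_transform(filt, config$clr_pseudocount)
  if ("preprocess" %in% config$stages && !is.null(out_dir)) {
    write_count_tsv(filt, file.path(out_dir, "filtered_counts.tsv"))
    emit(data.frame(sample_id = clr$sample_ids, clr$x, check.names = FALSE),
         "clr_matrix.tsv")
  }

  ## --- diversity ----------------------------------------------------------
  if ("diversity" %in% config$stages) {
    depth <- config$rarefaction_depth
    if (is.null(depth)) depth <- min(filt$library_size)
    rar <- rarefy(filt, depth, seed = config$seed + 11L)
    shannon <- apply(rar$counts, 1, shannon_index)
    grp_r <- group[match(rar$sample_ids, counts$sample_ids)]
    res$alpha <- kruskal_dunn(shannon, grp_r)
    props <- filt$counts / filt$library_size
    bc <- bray_curtis(props)
    res$pcoa <- pcoa(bc)
    res$beta <- within_group_beta(bc, group)
    emit(data.frame(sample_id = rar$sample_ids, shannon = shannon,
                    group = grp_r), "alpha_diversity.tsv")
    emit(data.frame(sample_id = rownames(res$pcoa$coordinates),
                    res$pcoa$coordinates[, seq_len(min(4,
                      ncol(res$pcoa$coordinates))), drop = FALSE]),
         "pcoa_coordinates.tsv")
    emit(res$beta$pairwise, "beta_dunn.tsv")
  }

  ## --- constrained ordination ---------------------------------------------
  if ("rda" %in% config$stages) {
    vars <- config$rda_vars
    if (is.null(vars))
      vars <- setdiff(names(metadata),
                      c("sample_id", "group", "id_status", config$markers))
    vdf <- metadata[, vars, drop = FALSE]
    vdf$hiv <- metadata$hiv
    res$rda_screen <- rda_screen(clr, vdf, n_perm = config$rda_n_perm,
                                 seed = config$seed + 21L)
    res$selection <- forward_select_forced(
      clr, vdf, forced = intersect(config$forced, names(vdf)),
      alpha = config$rda_alpha, n_perm = config$rda_n_perm,
      seed = config$seed + 22L)
    emit(res$rda_screen, "rda_screen.tsv")
    emit(res$selection$trace, "rda_selection.tsv")
  }

  ## --- Bayesian abundance models ------------------------------------------
  if ("bayes" %in% config$stages) {
    genera <- config$genera
    if (is.null(genera))
      genera <- setdiff(filt$genus_names,
                        c(config$background_genus, "unclassified"))
    rows <- list()
    for (g in genera) {
      dat <- abundance_data(filt$counts[, g], filt$library_size,
                            metadata$hiv, metadata$id_status)
      fits <- lapply(1:5, function(m) {
        cfg <- config$sampler
        cfg$seed <- cfg$seed + 10L * match(g, genera) + m
        fit_abundance_model(model_spec(m), dat, cfg)
      })
      if (any(vapply(fits, `[[`, TRUE, "flagged")))
        flags <- c(flags, sprintf("bayes:%s", g))
      cmp <- compare_and_select(fits)
      sel <- fits[[cmp$selected]]
      p00 <- mean(sel$draws[, "p_base"]) * 1e4
      row <- data.frame(genus = g, selected_model = cmp$selected,
                        baseline_per_10k = p00,
                        pct_hiv = NA, sd_hiv = NA, hdi_hiv = NA,
                        pct_id = NA, sd_id = NA, hdi_id = NA)
      for (f in intersect(sel$spec$features, c("m_hiv", "m_id"))) {
        s <- summarize_percent_change(sel, f)
        suf <- if (f == "m_hiv") "hiv" else "id"
        row[[paste0("pct_", suf)]] <- s$mean
        row[[paste0("sd_", suf)]] <- s$sd
        row[[paste0("hdi_", suf)]] <-
          sprintf("%.1f to %.1f", s$hdi_lower, s$hdi_upper)
      }
      rows[[g]] <- row
    }
    res$effects <- do.call(rbind, rows)
    emit(res$effects, "abundance_effects.tsv")
  }

  ## --- prevalence mixture ---------------------------------------------------
  if ("mixture" %in% config$stages && !is.null(config$mixture_genus) &&
      config$mixture_genus %in% filt$genus_names) {
    dat <- abundance_data(filt$counts[, config$mixture_genus],
                          filt$library_size,
                          metadata$hiv, metadata$id_status)
    res$mixture <- fit_prevalence_mixture(dat, config$mixture_sampler)
    if (res$mixture$flagged)
      flags <- c(flags, sprintf("mixture:%s", config$mixture_genus))
    emit(res$mixture$contrasts, "prevalence_contrasts.tsv")
  }

  ## --- clinical -------------------------------------------------------------
  if ("clinical" %in% config$stages) {
    covs <- metadata[, intersect(c("age", "sex", "ethnicity", "deworming"),
                                 names(metadata)), drop = FALSE]
    if (!ncol(covs)) covs <- NULL
    tests <- lapply(intersect(config$markers, names(metadata)), function(mk)
      two_way_factorial_test(metadata[[mk]], metadata$hiv,
                             metadata$id_status, covariates = covs,
                             outcome_name = mk))
    res$clinical <- data.frame(
      outcome = vapply(tests, `[[`, "", "outcome_name"),
      transform = vapply(tests, `[[`, "", "transform"),
      p_hiv = vapply(tests, `[[`, 0, "p_hiv"),
      p_iron = vapply(tests, `[[`, 0, "p_iron"),
      p_interaction = vapply(tests, `[[`, 0, "p_interaction"),
      interaction_dropped = vapply(tests, `[[`, TRUE,
                                   "interaction_dropped"))
    emit(res$clinical, "clinical_tests.tsv")
  }

  manifest <- list(package = "mbfact",
                   version = as.character(utils::packageVersion("mbfact")),
                   seed = config$seed, stages = config$stages,
                   parameters = list(
                     prevalence_threshold = config$prevalence_threshold,
                     clr_pseudocount = config$clr_pseudocount,
                     rarefaction_depth = config$rarefaction_depth,
                     rda_n_perm = config$rda_n_perm,
                     sampler = unclass(config$sampler)[
                       c("draws", "tune", "chains", "target_accept")]),
                   n_samples = nrow(counts$counts),
                   n_genera_in = ncol(counts$counts),
                   n_genera_filtered = ncol(filt$counts),
                   convergence_flags = flags)
  res$manifest <- manifest
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  if (length(flags) && !config$allow_flagged)
    stop("non-converged fits: ", paste(flags, collapse = ", "),
         " (set allow_flagged = TRUE to continue)")
  invisible(res)
}

#' Simulate a cohort and write it to disk
#'
#' Generates metadata and counts under a ground-truth panel and writes
#' `counts.tsv`, `metadata.tsv` and `truth.json` to `out_dir`.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory.
#' @param panel generative panel; default [default_genus_panel()].
#' @return Invisibly, list with `meta`, `table`, `paths`.
#' @export
simulate_command <- function(config, out_dir,
                             panel = default_genus_panel()) {
  meta <- generate_cohort(config)
  tab <- generate_counts(meta, panel, config)
  paths <- write_cohort(meta, tab, config, out_dir)
  invisible(list(meta = meta, table = tab, paths = paths))
}
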