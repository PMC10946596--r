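#' BRINDA inflammation adjustment of plasma ferritin
#'
#' Regression-based correction:
#' `ln PF_adj = ln PF - b1 * max(0, ln CRP - ln CRP_ref)
#'            - b2 * max(0, ln AGP - ln AGP_ref)`.
#' With `params = "fit"` the slopes come from an internal multivariable
#' regression of `ln PF` on `ln CRP` and `ln AGP` and the references are
#' the lowest decile of each marker (the usual convention); externally
#' estimated coefficients can be supplied instead for exactness with
#' other cohorts.
#'
#' @param pf,crp,agp positive numeric vectors (plasma ferritin ug/L,
#'   C-reactive protein mg/L, alpha-1-acid glycoprotein g/L).
#' @param params `"fit"` or a list with `beta1`, `beta2`, `crp_ref`,
#'   `agp_ref`.
#' @return Adjusted ferritin vector; samples at/below both references are
#'   returned unchanged.
#' @export
brinda_adjust_ferritin <- function(pf, crp, agp, params = "fit") {
  if (any(pf <= 0) || any(crp <= 0) || any(agp <= 0))
    stop("all markers must be strictly positive")
  if (identical(params, "fit")) {
    fit <- lm(log(pf) ~ log(crp) + log(agp))
    params <- list(beta1 = unname(coef(fit)[2]),
                   beta2 = unname(coef(fit)[3]),
                   crp_ref = unname(quantile(crp, 0.1)),
                   agp_ref = unname(quantile(agp, 0.1)))
  }
  stopifnot(params$crp_ref > 0, params$agp_ref > 0)
  ln_adj <- log(pf) -
    params$beta1 * pmax(0, log(crp) - log(params$crp_ref)) -
    params$beta2 * pmax(0, log(agp) - log(params$agp_ref))
  exp(ln_adj)
}

#' Enrolment iron-status classification
#'
#' Classification mirrors the enrolment rules of the targeted design:
#' severe anaemia (Hb < 80 g/L) or a body-mass-index-for-age Z-score
#' outside `[-3, 2]` makes a child ineligible; otherwise
#' inflammation-unadjusted ferritin <= 40 ug/L defines iron deficiency
#' (ID); ferritin > 40 with Hb >= 115 g/L defines iron-sufficient
#' nonanaemic; ferritin > 40 with Hb < 115 is ineligible
#' (anaemic-but-sufficient).
#'
#' @param ferritin_unadjusted ug/L.
#' @param hb haemoglobin g/L.
#' @param bmi_z BMI-for-age Z-score.
#' @return data.frame with `label` (factor: `ID`,
#'   `sufficient_nonanaemic`, `ineligible`) and `reason` (`NA`,
#'   `severe_anaemia`, `bmi_exclusion`, `anaemic_sufficient`).
#' @export
classify_iron_status <- function(ferritin_unadjusted, hb, bmi_z) {
  n <- length(ferritin_unadjusted)
  stopifnot(length(hb) == n, length(bmi_z) == n)
  if (any(is.na(ferritin_unadjusted)) || any(is.na(hb)) || any(is.na(bmi_z)))
    stop("missing input")
  label <- rep("ineligible", n)
  reason <- rep(NA_character_, n)
  excl_bmi <- bmi_z < -3 | bmi_z > 2
  excl_hb <- hb < 80
  reason[excl_bmi] <- "bmi_exclusion"
  reason[excl_hb] <- "severe_anaemia"   # anaemia exclusion takes precedence
  ok <- !excl_bmi & !excl_hb
  id <- ok & ferritin_unadjusted <= 40
  suff <- ok & ferritin_unadjusted > 40 & hb >= 115
  anae <- ok & ferritin_unadjusted > 40 & hb < 115
  label[id] <- "ID"
  label[suff] <- "sufficient_nonanaemic"
  reason[anae] <- "anaemic_sufficient"
  data.frame(label = factor(label, levels = c("ID", "sufficient_nonanaemic",
                                              "ineligible")),
             reason = reason)
}

#' Faecal calprotectin category
#'
#' `< 50` ug/g normal, `[50, 200]` intermediate (boundary values fall in
#' the middle bin), `> 200` elevated gut inflammation.
#'
#' @param value calprotectin in ug/g (non-negative).
#' @return factor with levels `normal`, `intermediate`, `elevated`.
#' @export
classify_calprotectin <- function(value) {
  if (any(value < 0)) stop("calprotectin must be non-negative")
  factor(ifelse(value > 200, "elevated",
                ifelse(value >= 50, "intermediate", "normal")),
         levels = c("normal", "intermediate", "elevated"))
}

## ---- two-way factorial machinery -----------------------------------------

## type-III F test for each named term: drop the term's columns from the
## full sum-contrast model matrix and compare residual sums of squares
type3_f <- function(y, mm, assign, term_ids) {
  qf <- qr(mm)
  if (qf$rank < ncol(mm)) {
    aliased <- colnames(mm)[qf$pivot[(qf$rank + 1):ncol(mm)]]
    stop("singular design; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  rss_full <- sum(qr.resid(qf, y)^2)
  df_res <- length(y) - qf$rank
  out <- lapply(term_ids, function(tid) {
    keep <- assign != tid
    q0 <- qr(mm[, keep, drop = FALSE])
    rss0 <- sum(qr.resid(q0, y)^2)
    df <- sum(!keep)
    f <- ((rss0 - rss_full) / df) / (rss_full / df_res)
    data.frame(df = df, f = f, p = pf(f, df, df_res, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

## build the sum-contrast model frame used by both factorial tests
factorial_frame <- function(outcome, hiv, iron, covariates) {
  df <- data.frame(.y = outcome,
                   hiv = factor(hiv, levels = c(0, 1)),
                   iron = factor(iron, levels = c(0, 1)))
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == length(outcome))
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      df[[nm]] <- if (is.numeric(v)) v else factor(v)
    }
  }
  cells <- table(df$hiv, df$iron)
  if (any(cells == 0)) stop("empty factorial cell")
  if (any(cells < 2)) warning("factorial cell with fewer than 2 observations")
  df
}

#' Two-way factorial ANOVA/ANCOVA with interaction-drop rule
#'
#' Fits `outcome ~ covariates + hiv * iron` by least squares with sum
#' contrasts and partial (type-III) F tests, appropriate for unbalanced
#' cells. Non-normal outcomes (Shapiro-Wilk on the full-model residuals,
#' alpha = 0.05, positive outcomes only) are log-transformed first when
#' `log_transform = "auto"`. If the interaction is not significant at
#' 0.05 the model is refitted without it and the main-effect p-values are
#' reported from the reduced model, mirroring the interaction-drop
#' convention.
#'
#' @param outcome numeric vector.
#' @param hiv,iron 0/1 indicators.
#' @param covariates optional data.frame of adjustment covariates (e.g.
#'   age, sex, ethnicity, deworming).
#' @param log_transform `"auto"`, `TRUE` or `FALSE`.
#' @return Object of class `factorial_test`: list with `outcome_name`,
#'   `transform`, `p_hiv`, `p_iron`, `p_interaction`,
#'   `interaction_dropped`, `covariates`, `table` (per-term df/F/p),
#'   `note`.
#' @export
two_way_factorial_test <- function(outcome, hiv, iron, covariates = NULL,
                                   log_transform = "auto",
                                   outcome_name = deparse(substitute(outcome))) {
  df <- factorial_frame(outcome, hiv, iron, covariates)
  note <- NULL
  if (var(df$.y) == 0) {
    return(structure(list(outcome_name = outcome_name, transform = "none",
                          p_hiv = 1, p_iron = 1, p_interaction = 1,
                          interaction_dropped = FALSE,
                          covariates = names(covariates), table = NULL,
                          note = "constant outcome: no effects estimable"),
                     class = "factorial_test"))
  }
  transform <- "none"
  do_log <- isTRUE(log_transform)
  if (identical(log_transform, "auto")) {
    mm0 <- factorial_mm(df, interaction = TRUE)
    r <- qr.resid(qr(mm0$mm), df$.y)
    swp <- tryCatch(shapiro.test(r)$p.value, error = function(e) 1)
    do_log <- swp < 0.05 && all(df$.y > 0)
  }
  if (do_log) { df$.y <- log(df$.y); transform <- "log" }

  full <- factorial_mm(df, interaction = TRUE)
  ft_full <- type3_f(df$.y, full$mm, full$assign, full$term_ids)
  p_int <- ft_full$p[match("hiv:iron", full$term_names)]
  dropped <- FALSE
  if (is.na(p_int)) p_int <- 1
  if (p_int >= 0.05) {
    red <- factorial_mm(df, interaction = FALSE)
    ft <- type3_f(df$.y, red$mm, red$assign, red$term_ids)
    p_hiv <- ft$p[match("hiv", red$term_names)]
    p_iron <- ft$p[match("iron", red$term_names)]
    dropped <- TRUE
    tab <- cbind(term = red$term_names, ft)
  } else {
    p_hiv <- ft_full$p[match("hiv", full$term_names)]
    p_iron <- ft_full$p[match("iron", full$term_names)]
    tab <- cbind(term = full$term_names, ft_full)
  }
  structure(list(outcome_name = outcome_name, transform = transform,
                 p_hiv = p_hiv, p_iron = p_iron, p_interaction = p_int,
                 interaction_dropped = dropped,
                 covariates = names(covariates), table = tab, note = note),
            class = "factorial_test")
}

## model matrix with sum contrasts; returns per-term column assignment
factorial_mm <- function(df, interaction = TRUE) {
  covs <- setdiff(names(df), c(".y", "hiv", "iron"))
  rhs <- c(covs, "hiv", "iron", if (interaction) "hiv:iron")
  form <- as.formula(paste("~", paste(rhs, collapse = " + ")))
  fcts <- names(Filter(is.factor, df))
  ctr <- lapply(fcts, function(x) "contr.sum")
  names(ctr) <- fcts
  mm <- model.matrix(form, df, contrasts.arg = ctr)
  assign <- attr(mm, "assign")
  term_names <- attr(terms(form), "term.labels")
  list(mm = mm, assign = assign,
       term_ids = seq_along(term_names), term_names = term_names)
}

#' Two-way binary logistic regression with interaction-drop rule
#'
#' Logistic model `outcome ~ covariates + hiv * iron` with Wald p-values;
#' the interaction is dropped when non-significant at 0.05 and main
#' effects are then reported from the reduced model. Perfect or
#' quasi-perfect separation flags the result (it is returned, never
#' silently discarded). When the interaction *is* significant, a
#' Bonferroni chi-squared post hoc comparison of the four groups is
#' attached.
#'
#' @param outcome binary (0/1 or logical or two-level factor).
#' @param hiv,iron 0/1 indicators.
#' @param covariates optional data.frame.
#' @return A `factorial_test` with additional fields `flagged`
#'   (separation) and `posthoc` (see [bonferroni_chisq_posthoc()];
#'   `NULL` unless the interaction is significant).
#' @export
two_way_logistic_test <- function(outcome, hiv, iron, covariates = NULL,
                                  outcome_name = deparse(substitute(outcome))) {
  y <- if (is.factor(outcome)) as.integer(outcome) - 1L else as.integer(outcome)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  df <- factorial_frame(y, hiv, iron, covariates)
  flagged <- FALSE
  fit_glm <- function(interaction) {
    m <- factorial_mm(df, interaction = interaction)
    fit <- withCallingHandlers(
      glm(df$.y ~ m$mm - 1, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          flagged <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) flagged <<- TRUE
    cf <- summary(fit)$coefficients
    ## Wald p per term: binary factors with sum contrasts have one column
    p_of <- function(term) {
      idx <- which(m$assign == match(term, m$term_names))
      if (!length(idx)) return(NA_real_)
      cf[idx + 0, 4][1]  # columns of mm map 1:1 to coef rows (no intercept drop)
    }
    list(m = m, cf = cf, p_of = p_of)
  }
  full <- fit_glm(TRUE)
  p_int <- full$p_of("hiv:iron")
  dropped <- FALSE
  posthoc <- NULL
  if (is.na(p_int)) p_int <- 1
  if (p_int >= 0.05) {
    red <- fit_glm(FALSE)
    p_hiv <- red$p_of("hiv"); p_iron <- red$p_of("iron")
    dropped <- TRUE
  } else {
    p_hiv <- full$p_of("hiv"); p_iron <- full$p_of("iron")
    grp <- 4L - 2L * as.integer(as.character(df$hiv)) -
      as.integer(as.character(df$iron))
    tab <- rbind(`0` = tapply(y == 0, grp, sum)[as.character(1:4)],
                 `1` = tapply(y == 1, grp, sum)[as.character(1:4)])
    colnames(tab) <- paste0("g", 1:4)
    tab[is.na(tab)] <- 0
    posthoc <- bonferroni_chisq_posthoc(tab)
  }
  structure(list(outcome_name = outcome_name, transform = "none",
                 p_hiv = p_hiv, p_iron = p_iron, p_interaction = p_int,
                 interaction_dropped = dropped,
                 covariates = names(covariates), flagged = flagged,
                 posthoc = posthoc, note = NULL),
            class = "factorial_test")
}

#' @export
print.factorial_test <- function(x, ...) {
  cat(sprintf(
    "%s (%s): p_hiv = %.3g, p_iron = %.3g, p_interaction = %.3g%s%s\n",
    x$outcome_name, x$transform, x$p_hiv, x$p_iron, x$p_interaction,
    if (x$interaction_dropped) " [interaction dropped]" else "",
    if (isTRUE(x$flagged)) " [FLAGGED]" else ""))
  invisible(x)
}

#' Pairwise chi-squared post hoc comparison with Bonferroni letters
#'
#' All pairwise 2x2 chi-squared tests (no continuity correction) between
#' the four groups of a 2x4 contingency table; raw p-values are
#' multiplied by the number of pairs (capped at 1) and groups are
#' labelled with a compact letter display in which groups sharing a
#' letter do not differ significantly at 0.05.
#'
#' @param table 2 x 4 matrix of counts (rows = outcome categories,
#'   columns = groups).
#' @return list with `pairwise` (data.frame: `group1`, `group2`,
#'   `statistic`, `p_raw`, `p_adj`) and `letters` (named character).
#' @export
bonferroni_chisq_posthoc <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 2, all(table >= 0))
  if (is.null(colnames(table))) colnames(table) <- paste0("g", seq_len(ncol(table)))
  ok <- colSums(table) > 0
  if (!all(ok)) {
    warning("excluding zero-margin group(s): ",
            paste(colnames(table)[!ok], collapse = ", "))
    table <- table[, ok, drop = FALSE]
  }
  k <- ncol(table)
  if (k < 2) stop("need at least two groups with observations")
  prs <- combn(k, 2)
  n_pairs <- ncol(prs)
  rows <- apply(prs, 2, function(pr) {
    t2 <- table[, pr]
    a <- t2[1, 1]; b <- t2[1, 2]; c <- t2[2, 1]; d <- t2[2, 2]
    n <- a + b + c + d
    stat <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    if (!is.finite(stat)) stat <- 0
    p <- pchisq(stat, 1, lower.tail = FALSE)
    data.frame(group1 = colnames(table)[pr[1]],
               group2 = colnames(table)[pr[2]],
               statistic = stat, p_raw = p,
               p_adj = min(1, n_pairs * p))
  })
  pw <- do.call(rbind, rows)
  sig <- pw[pw$p_adj < 0.05, c("group1", "group2"), drop = FALSE]
  list(pairwise = pw,
       letters = compact_letters(colnames(table), sig))
}

## insert-and-absorb compact letter display: start with one class holding
## every group; each significant pair splits the classes containing both
compact_letters <- function(groups, sig_pairs) {
  classes <- list(groups)
  for (r in seq_len(nrow(sig_pairs))) {
    g1 <- sig_pairs$group1[r]; g2 <- sig_pairs$group2[r]
    new <- list()
    for (cl in classes) {
      if (g1 %in% cl && g2 %in% cl) {
        new <- c(new, list(setdiff(cl, g1)), list(setdiff(cl, g2)))
      } else new <- c(new, list(cl))
    }
    ## absorb: drop classes that are subsets of another
    keep <- rep(TRUE, length(new))
    for (i in seq_along(new)) for (j in seq_along(new)) {
      if (i != j && keep[j] && all(new[[i]] %in% new[[j]]) &&
          !identical(sort(new[[i]]), sort(new[[j]])))
        keep[i] <- FALSE
    }
    if (any(duplicated(lapply(new, sort)))) {
      keep[duplicated(lapply(new, sort))] <- FALSE
    }
    classes <- new[keep]
  }
  ## letter order follows group order: class containing the earliest
  ## group gets "a"
  classes <- classes[order(vapply(classes, function(cl)
    min(match(cl, groups)), 0))]
  letters_out <- setNames(rep("", length(groups)), groups)
  for (i in seq_along(classes)) {
    for (g in classes[[i]])
      letters_out[g] <- paste0(letters_out[g], letters[i])
  }
  letters_out
}
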