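#' Covariate-adjusted association models
#'
#' The analysis cohort is a single tibble with one row per participant
#' carrying covariates (`age`, `female`, `smoking`, `activity`, `education`),
#' the weighted genetic risk score `grs`, energy-adjusted exposure residuals
#' (`z_gi`, `z_gl`, `z_fib`, `z_prot`) with their tertiles (`tert_gi`, ...),
#' outcomes (`fpg_mmol_l`, `hba1c_pct`, `insulin_uiu_ml`, `homa_ir`,
#' `homa_beta_pct`), the `prediabetes` indicator and `bf_pct`.
#'
#' Outcomes are right-skewed and modelled on the log scale; reported adjusted
#' means are least-squares means (continuous covariates held at their sample
#' means, binary covariates at their observed proportions) back-transformed by
#' exponentiation. Nested adjustment tiers: 1 = age + sex; 2 = + smoking,
#' physical activity, education; 3 = + cereal-fiber and protein residuals;
#' 4 = + body fatness. The genetic risk score is carried as a covariate in
#' all tiers so that means correspond to models "adjusting for GRS only",
#' without interaction terms.
#'
#' @name association-models
NULL

#' Model specification
#'
#' @param outcome Column name of the outcome (e.g. `"fpg_mmol_l"`).
#' @param exposure Exposure stem: `"gi"`, `"gl"` or any stem with `z_<stem>`
#'   and `tert_<stem>` columns present.
#' @param tier Adjustment tier, 1-4 (nested covariate sets).
#' @param log_transform Model the outcome on the log scale (default `TRUE`).
#' @param interaction_with Optional modifier for an interaction p-value:
#'   `"grs"` or `"cereal_fiber"`.
#' @param include_grs Keep the genetic risk score as a covariate.
#' @param covariates Optional explicit covariate set overriding the tier
#'   (use `character(0)` for an unadjusted model).
#' @return A `glycohort_spec` list.
#' @export
model_spec <- function(outcome, exposure = "gi", tier = 3,
                       log_transform = TRUE, interaction_with = NULL,
                       include_grs = TRUE, covariates = NULL) {
  stopifnot(tier %in% 1:4)
  structure(
    list(outcome = outcome, exposure = exposure, tier = tier,
         log_transform = log_transform, interaction_with = interaction_with,
         include_grs = include_grs, covariates = covariates),
    class = "glycohort_spec"
  )
}

spec_covariates <- function(spec, drop = character(0)) {
  if (!is.null(spec$covariates)) return(setdiff(spec$covariates, drop))
  tier_covariates(spec$tier, spec$include_grs, drop)
}

model_formula <- function(lhs, terms, covs) {
  as.formula(paste(lhs, "~", paste(c(terms, covs), collapse = " + ")))
}

tier_covariates <- function(tier, include_grs = TRUE, drop = character(0)) {
  covs <- c("age", "female")
  if (tier >= 2) covs <- c(covs, "smoking", "activity", "education")
  if (tier >= 3) covs <- c(covs, "z_fib", "z_prot")
  if (tier >= 4) covs <- c(covs, "bf_pct")
  if (include_grs) covs <- c(covs, "grs")
  setdiff(covs, drop)
}

outcome_vector <- function(cohort, spec) {
  y <- cohort[[spec$outcome]]
  if (spec$log_transform) {
    if (any(y <= 0, na.rm = TRUE)) {
      abort(paste0("outcome ", spec$outcome,
                   " must be positive for log transformation"))
    }
    y <- log(y)
  }
  y
}

check_full_rank <- function(fit) {
  bad <- names(coef(fit))[is.na(coef(fit))]
  if (length(bad) > 0) {
    abort(paste0("rank-deficient design; collinear terms: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(fit)
}

fit_tertile_model <- function(cohort, spec, drop_covariates = character(0)) {
  covs <- spec_covariates(spec, drop_covariates)
  d <- cohort
  d$.y <- outcome_vector(cohort, spec)
  d$.tert <- factor(cohort[[paste0("tert_", spec$exposure)]], levels = 1:3)
  check_full_rank(lm(model_formula(".y", ".tert", covs), data = d))
}

#' Adjusted (least-squares) means by exposure tertile
#'
#' Fits an ordinary least-squares model of the (log) outcome on the exposure
#' tertile factor plus the tier's covariates, and reports the least-squares
#' mean per tertile with a 95 percent Wald interval, back-transformed when the
#' outcome was logged. A trend p-value from the continuous-exposure model and,
#' if requested, an interaction p-value are attached.
#'
#' @param cohort Analysis cohort tibble.
#' @param spec A [model_spec()].
#' @return A `glycohort_modelresult` list: `means` (tibble with tertile,
#'   n, mean, lcl, ucl), `p_trend`, `slope`, `p_interaction`, `spec`.
#' @export
fit_adjusted_means <- function(cohort, spec) {
  fit <- fit_tertile_model(cohort, spec)
  em <- emmeans::emmeans(fit, ".tert", weights = "proportional")
  s <- as.data.frame(summary(em, level = 0.95))
  bt <- if (spec$log_transform) exp else identity
  means <- tibble::tibble(
    tertile = as.integer(as.character(s$.tert)),
    n = as.integer(table(cohort[[paste0("tert_", spec$exposure)]])[as.character(s$.tert)]),
    mean = bt(s$emmean),
    lcl = bt(s$lower.CL),
    ucl = bt(s$upper.CL)
  )
  tr <- trend_test(cohort, spec)
  p_int <- if (!is.null(spec$interaction_with)) {
    interaction_scan(cohort, spec)$p_interaction
  } else {
    NA_real_
  }
  structure(
    list(means = means, p_trend = tr$p_value, slope = tr$slope,
         p_interaction = p_int, spec = spec),
    class = "glycohort_modelresult"
  )
}

#' @export
print.glycohort_modelresult <- function(x, ...) {
  cat("Adjusted means for", x$spec$outcome, "by", x$spec$exposure,
      "tertile (tier", x$spec$tier, ")\n")
  print(x$means)
  cat(sprintf("p_trend = %.3g", x$p_trend))
  if (!is.na(x$p_interaction)) cat(sprintf(", p_interaction = %.3g", x$p_interaction))
  cat("\n")
  invisible(x)
}

#' Trend test with the continuous exposure residual
#'
#' Replaces the tertile factor by the continuous energy-adjusted residual in
#' the same adjusted model; returns the slope (per residual unit, log-outcome
#' scale when logged) and its p-value.
#'
#' @inheritParams fit_adjusted_means
#' @return A list with `slope` and `p_value`.
#' @export
trend_test <- function(cohort, spec) {
  covs <- spec_covariates(spec)
  d <- cohort
  d$.y <- outcome_vector(cohort, spec)
  d$.z <- cohort[[paste0("z_", spec$exposure)]]
  fit <- check_full_rank(lm(model_formula(".y", ".z", covs), data = d))
  list(slope = coef(fit)[[".z"]], p_value = wald_p(fit, ".z"))
}

#' Adjusted odds ratios for pre-diabetes by exposure tertile
#'
#' Maximum-likelihood logistic regression of the pre-diabetes indicator on
#' the exposure tertile factor plus the tier's covariates; tertile 1 is the
#' reference (OR 1). The trend p-value comes from the continuous-residual
#' logistic model.
#'
#' @inheritParams fit_adjusted_means
#' @return A list with `or` (tibble: tertile, n, or, lcl, ucl), `p_trend`,
#'   `spec`.
#' @export
fit_prediabetes_or <- function(cohort, spec) {
  covs <- spec_covariates(spec)
  d <- cohort
  d$.tert <- factor(cohort[[paste0("tert_", spec$exposure)]], levels = 1:3)
  fit <- glm(model_formula("prediabetes", ".tert", covs), data = d,
             family = binomial())
  check_full_rank(fit)
  if (!fit$converged || any(abs(coef(fit)) > 15)) {
    abort("apparent separation in logistic model; penalised estimation is out of scope")
  }
  est <- unname(coef(fit)[c(".tert2", ".tert3")])
  se <- unname(sqrt(diag(vcov(fit)))[c(".tert2", ".tert3")])
  or <- tibble::tibble(
    tertile = 1:3,
    n = as.integer(table(d$.tert)),
    or = c(1, exp(est)),
    lcl = c(NA, exp(est - 1.96 * se)),
    ucl = c(NA, exp(est + 1.96 * se))
  )
  d$.z <- cohort[[paste0("z_", spec$exposure)]]
  fitz <- glm(model_formula("prediabetes", ".z", covs), data = d,
              family = binomial())
  list(or = or, p_trend = wald_p(fitz, ".z"), spec = spec)
}

modifier_column <- function(cohort, modifier) {
  col <- switch(modifier,
    grs = "grs",
    cereal_fiber = "z_fib",
    modifier
  )
  if (!col %in% names(cohort)) abort(paste0("modifier column missing: ", col))
  cohort[[col]]
}

#' Interaction p-value for exposure x modifier
#'
#' Adds the product of the continuous exposure residual and a centred
#' continuous modifier (genetic risk score or cereal-fiber residual) to the
#' adjusted model and returns the Wald p-value of the product term. The
#' pre-registered significance threshold for interactions (0.1) is recorded
#' in the output.
#'
#' @inheritParams fit_adjusted_means
#' @param modifier Overrides `spec$interaction_with`.
#' @return A list with `p_interaction`, `coefficient`, `threshold`.
#' @export
interaction_scan <- function(cohort, spec, modifier = NULL) {
  modifier <- modifier %||% spec$interaction_with
  if (is.null(modifier)) abort("no interaction modifier specified")
  m <- modifier_column(cohort, modifier)
  if (stats::var(m, na.rm = TRUE) == 0) {
    abort(paste0("degenerate modifier (constant): ", modifier))
  }
  # the centred modifier carries the main effect; its covariate duplicate
  # would be perfectly collinear and is removed
  col <- switch(modifier, grs = "grs", cereal_fiber = "z_fib", modifier)
  spec2 <- spec
  spec2$include_grs <- spec$include_grs && col != "grs"
  covs <- spec_covariates(spec2, drop = col)
  d <- cohort
  d$.z <- cohort[[paste0("z_", spec$exposure)]]
  d$.m <- m - mean(m, na.rm = TRUE)
  binary <- identical(spec$outcome, "prediabetes")
  lhs <- if (binary) "prediabetes" else ".y"
  if (!binary) d$.y <- outcome_vector(cohort, spec)
  f <- model_formula(lhs, ".z * .m", covs)
  fit <- if (binary) glm(f, data = d, family = binomial()) else lm(f, data = d)
  check_full_rank(fit)
  list(
    p_interaction = wald_p(fit, ".z:.m"),
    coefficient = coef(fit)[[".z:.m"]],
    threshold = 0.1
  )
}

#' 3x3 cross-classification by exposure and modifier tertiles
#'
#' Participants are jointly classified by exposure tertile and modifier
#' tertile (9 cells). For continuous outcomes the cell-adjusted means use the
#' least-squares-mean machinery with the cell factor; for pre-diabetes a
#' logistic model reports per-cell odds ratios against a reference cell
#' (by default the lowest exposure, lowest modifier cell, which has OR 1
#' exactly).
#'
#' @param cohort Analysis cohort tibble.
#' @param exposure Exposure stem (`"gi"`, `"gl"`).
#' @param modifier Modifier stem with a `tert_<stem>` column (`"grs"`,
#'   `"fib"`).
#' @param outcome Outcome column, or `"prediabetes"`.
#' @param tier Adjustment tier (covariates as in [model_spec()]); the
#'   modifier's own residual is removed from the covariate set when it is
#'   part of the classification.
#' @param reference Integer pair `c(exposure_tertile, modifier_tertile)`.
#' @param log_transform Model continuous outcomes on the log scale.
#' @return A `glycohort_crossclass` list with a 9-row `cells` tibble
#'   (`exposure_tertile`, `modifier_tertile`, `n`, and `mean`/`lcl`/`ucl` or
#'   `or`/`lcl`/`ucl`).
#' @export
cross_classify <- function(cohort, exposure = "gi", modifier = "grs",
                           outcome = "prediabetes", tier = 3,
                           reference = c(1, 1), log_transform = TRUE) {
  te <- cohort[[paste0("tert_", exposure)]]
  tm <- cohort[[paste0("tert_", modifier)]]
  cell <- factor(paste0("e", te, "m", tm),
                 levels = as.vector(t(outer(1:3, 1:3, function(a, b)
                   paste0("e", a, "m", b)))))
  counts <- table(cell)
  if (any(counts == 0)) {
    abort(paste0("empty cross-classification cell(s): ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  drop <- if (modifier == "fib") "z_fib" else if (modifier == "grs") "grs" else character(0)
  covs <- tier_covariates(tier, include_grs = modifier != "grs", drop = drop)
  d <- cohort
  ref_level <- paste0("e", reference[1], "m", reference[2])
  d$.cell <- stats::relevel(cell, ref = ref_level)
  cell_levels <- levels(cell)
  grid <- tibble::tibble(
    cell = cell_levels,
    exposure_tertile = rep(1:3, each = 3),
    modifier_tertile = rep(1:3, times = 3),
    n = as.integer(counts[cell_levels])
  )
  binary <- identical(outcome, "prediabetes")
  if (binary) {
    f <- model_formula("prediabetes", ".cell", covs)
    fit <- glm(f, data = d, family = binomial())
    check_full_rank(fit)
    cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
    nm <- paste0(".cell", grid$cell)
    est <- ifelse(grid$cell == ref_level, 0, cf[nm])
    ses <- ifelse(grid$cell == ref_level, NA, se[nm])
    grid$or <- exp(est)
    grid$lcl <- exp(est - 1.96 * ses)
    grid$ucl <- exp(est + 1.96 * ses)
  } else {
    spec <- model_spec(outcome, tier = tier, log_transform = log_transform,
                       include_grs = modifier != "grs")
    d$.y <- outcome_vector(cohort, spec)
    fit <- check_full_rank(lm(model_formula(".y", ".cell", covs), data = d))
    em <- as.data.frame(summary(emmeans::emmeans(fit, ".cell",
                                                 weights = "proportional")))
    i <- match(grid$cell, as.character(em$.cell))
    bt <- if (log_transform) exp else identity
    grid$mean <- bt(em$emmean[i])
    grid$lcl <- bt(em$lower.CL[i])
    grid$ucl <- bt(em$upper.CL[i])
  }
  structure(list(cells = grid, reference = reference, outcome = outcome,
                 exposure = exposure, modifier = modifier, tier = tier),
            class = "glycohort_crossclass")
}

#' Energy partition model
#'
#' Enters the daily energy from each named food source and the remaining
#' energy as separate model terms, plus the tier's covariates. Coefficients
#' are per kcal/day of the respective source.
#'
#' @param cohort Analysis cohort tibble with an `energy_kcal_d` column.
#' @param components Data frame of per-source energies (kcal/d), rows aligned
#'   with `cohort`.
#' @param outcome Outcome column name, or `"prediabetes"`.
#' @param tier Adjustment tier.
#' @param log_transform Model continuous outcomes on the log scale.
#' @return A tibble of per-component coefficients with standard errors and
#'   p-values (the remaining-energy term included).
#' @export
energy_partition_fit <- function(cohort, components, outcome, tier = 3,
                                 log_transform = TRUE) {
  comp <- as.data.frame(components)
  total_comp <- rowSums(comp)
  remaining <- cohort$energy_kcal_d - total_comp
  if (any(remaining < -1e-6)) {
    abort("component energies exceed total energy for some participants")
  }
  covs <- tier_covariates(tier)
  d <- cohort
  for (nm in names(comp)) d[[paste0(".e_", nm)]] <- comp[[nm]]
  d$.e_remaining <- remaining
  terms <- c(paste0(".e_", names(comp)), ".e_remaining")
  binary <- identical(outcome, "prediabetes")
  if (binary) {
    fit <- glm(model_formula("prediabetes", terms, covs), data = d,
               family = binomial())
  } else {
    spec <- model_spec(outcome, tier = tier, log_transform = log_transform)
    d$.y <- outcome_vector(cohort, spec)
    fit <- lm(model_formula(".y", terms, covs), data = d)
  }
  check_full_rank(fit)
  est <- coef(fit)[terms]
  se <- sqrt(diag(vcov(fit)))[terms]
  tibble::tibble(
    component = sub("^\\.e_", "", terms),
    coefficient = est,
    se = se,
    p_value = vapply(terms, function(t) wald_p(fit, t), numeric(1))
  )
}

#' Percent contrast between two tertile means
#'
#' @param result A `glycohort_modelresult`.
#' @param from Reference tertile (default 1).
#' @param to Comparison tertile (default 3).
#' @return Percent difference 100 * (mean_to - mean_from) / mean_from.
#' @export
percent_contrast <- function(result, from = 1, to = 3) {
  m <- result$means
  m_from <- m$mean[m$tertile == from]
  m_to <- m$mean[m$tertile == to]
  if (length(m_from) == 0 || length(m_to) == 0) {
    abort("requested tertile means not present")
  }
  if (m_from <= 0) abort("undefined contrast: reference mean is not positive")
  100 * (m_to - m_from) / m_from
}
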