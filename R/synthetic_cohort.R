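#' Synthetic cohort generation
#'
#' Generates cohorts with the statistical structure the association analyses
#' assume: repeated 24-hour recalls built from a real food catalog, genotypes
#' in Hardy-Weinberg equilibrium, and log-scale glucose-homeostasis outcomes
#' whose coefficients are calibrated so that the full pipeline reproduces a
#' stated set of adjusted tertile contrasts. Everything downstream of the
#' recall records is computed by the same scoring and modelling code the
#' analyses use, so the generator exercises the entire pipeline.
#'
#' @name synthetic-cohort
NULL

#' Cohort configuration
#'
#' Defaults describe a South-Chinese adult cohort: n = 3918, 52.9 percent
#' female, ages 23-69 (mean 46), mean energy ~1670 kcal/d, carbohydrates
#' ~56 percent of energy, latent dietary GI 42 + 46 x Beta(1.73, 1.19)
#' (mean ~69, pooled tertile cuts near 65/76), recall mix 80/16/4 percent
#' with 3/2/1 recall days, and a 12-SNP diabetes risk panel whose weighted
#' score averages 0.80. Outcome coefficients default to `NULL` and are then
#' solved by [calibrate_outcomes()] on the generated diet design so that the
#' tier-3 adjusted tertile means hit `ls_mean_targets`; gene-diet and
#' fiber-diet interaction coefficients are sized to give 80 percent power at
#' the 0.1 interaction threshold at the configured n.
#'
#' @param n Number of participants.
#' @param female_frac Fraction female.
#' @param recall_mix Probabilities of 1, 2 and 3 recall days (named "1","2","3").
#' @param coefficients Optional pre-computed outcome coefficients (as returned
#'   by [calibrate_outcomes()]); `NULL` means calibrate at generation time.
#' @param make_ffq Also emit food-frequency items per participant.
#' @param ... Override any default listed below.
#' @return A `glycohort_config` list.
#' @export
cohort_config <- function(n = 3918, female_frac = 0.529,
                          recall_mix = c("1" = 0.04, "2" = 0.16, "3" = 0.80),
                          coefficients = NULL, make_ffq = TRUE, ...) {
  cfg <- list(
    n = n,
    female_frac = female_frac,
    recall_mix = recall_mix,
    age = c(mean = 46, sd = 14, lo = 23, hi = 69),
    smoking_prob = c(male = 0.50, female = 0.04),
    activity = c(shape = 1.5, scale = 9.8),      # MET-h/wk, mean ~14.7
    education_frac = 0.112,
    urban_frac = 0.288,
    height = c(male = 1.68, female = 1.57, sd = 0.06),
    bmi = c(mean = 23.6, sd = 3.2, lo = 15, hi = 40),
    wc = c(intercept = 44, slope = 1.55, female = -3, sd = 4.5),
    gi_beta = c(a = 1.73, b = 1.19),
    gi_scale = c(lo = 42, span = 46, cap = 85),
    gi_day_sd = 2.5,
    energy = c(mean = 1670, sd = 550),
    energy_margin = c(lo = 1.10, hi = 0.90),     # keep inside plausibility bounds
    energy_day_sd = 0.08,
    pct_cho = c(mean = 56.2, sd = 9, lo = 35, hi = 75),
    pct_protein = c(mean = 14.2, sd = 3.0, lo = 9, hi = 24),
    side_dishes = c(vegetables = 150, egg = 30, tofu = 50),
    side_jitter_sd = 0.25,
    snp_panel = default_snp_panel(),
    obesity_grs = c(mean = 0.27, sd = 0.12),
    sigma = c(fpg = 0.28, hba1c = 0.22, insulin = 0.42),
    error_cor = matrix(c(1, 0.2, 0.45,
                         0.2, 1, 0.2,
                         0.45, 0.2, 1), 3, 3,
                       dimnames = list(c("fpg", "hba1c", "insulin"),
                                       c("fpg", "hba1c", "insulin"))),
    # adjusted (tier 3) LS-mean targets: GI tertiles 1-3, GL tertiles 1 and 3
    ls_mean_targets = list(
      fpg = c(gi_t1 = 5.19, gi_t2 = 5.39, gi_t3 = 5.67, gl_t1 = 5.35, gl_t3 = 5.63),
      hba1c = c(gi_t1 = 5.26, gi_t2 = 5.68, gi_t3 = 5.82, gl_t1 = 5.55, gl_t3 = 5.69),
      insulin = c(gi_t1 = 6.73, gi_t2 = 6.89, gi_t3 = 7.53, gl_t1 = 6.78, gl_t3 = 7.25)
    ),
    covariate_effects = list(
      fpg = c(age = 0.0015, female = -0.010, smoking = 0.010,
              activity = -0.0004, education = -0.005, grs = 0.10,
              z_fib = -0.0015, z_prot = 0),
      hba1c = c(age = 0.0020, female = -0.005, smoking = 0.008,
                activity = -0.0003, education = -0.004, grs = 0.08,
                z_fib = -0.0010, z_prot = 0),
      insulin = c(age = 0.0010, female = 0.030, smoking = 0.010,
                  activity = -0.0008, education = -0.005, grs = 0.15,
                  z_fib = -0.0030, z_prot = 0)
    ),
    interaction_power = 0.80,
    interaction_alpha = 0.10,
    coefficient_cap = 0.5,
    coefficients = coefficients,
    make_ffq = make_ffq,
    ffq_noise_sd = 0.35,
    serving_sizes = c(
      rice_sticky = 150, rice_jasmine = 150, rice_longhi = 150,
      rice_local = 150, rice_indica = 150, rice_parboil = 150,
      steamed_bread = 80, rice_porridge = 300, black_porridge = 300,
      wheat_noodles = 200, mung_noodles = 150, mixed_congee = 300,
      apple = 120, vegetables = 100, pork = 75, egg = 50, tofu = 100, oil = 10
    ),
    catalog = demo_food_catalog(),
    high_pool = c(rice_sticky = 0.30, rice_jasmine = 0.20, rice_local = 0.10,
                  steamed_bread = 0.20, rice_porridge = 0.10, rice_longhi = 0.10),
    low_pool = c(rice_indica = 0.25, rice_parboil = 0.20, wheat_noodles = 0.20,
                 mung_noodles = 0.10, black_porridge = 0.10, apple = 0.10,
                 mixed_congee = 0.05)
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  stopifnot(cfg$n >= 30, abs(sum(cfg$recall_mix) - 1) < 1e-8,
            all(cfg$sigma > 0), cfg$female_frac >= 0, cfg$female_frac <= 1)
  structure(cfg, class = "glycohort_config")
}

draw_participants <- function(cfg, seed) {
  set.seed(substream_seed(seed, "participants"))
  n <- cfg$n
  female <- as.numeric(runif(n) < cfg$female_frac)
  age <- rnorm_trunc(n, cfg$age[["mean"]], cfg$age[["sd"]],
                     cfg$age[["lo"]], cfg$age[["hi"]])
  smoking <- as.numeric(runif(n) < ifelse(female == 1,
                                          cfg$smoking_prob[["female"]],
                                          cfg$smoking_prob[["male"]]))
  activity <- stats::rgamma(n, shape = cfg$activity[["shape"]],
                            scale = cfg$activity[["scale"]])
  education <- as.numeric(runif(n) < cfg$education_frac)
  urban <- as.numeric(runif(n) < cfg$urban_frac)
  height <- rnorm(n, ifelse(female == 1, cfg$height[["female"]],
                            cfg$height[["male"]]), cfg$height[["sd"]])
  bmi <- rnorm_trunc(n, cfg$bmi[["mean"]], cfg$bmi[["sd"]],
                     cfg$bmi[["lo"]], cfg$bmi[["hi"]])
  wc <- cfg$wc[["intercept"]] + cfg$wc[["slope"]] * bmi +
    cfg$wc[["female"]] * female + rnorm(n, 0, cfg$wc[["sd"]])
  grs_obesity <- rnorm_trunc(n, cfg$obesity_grs[["mean"]],
                             cfg$obesity_grs[["sd"]], 0, 1)
  tibble::tibble(
    participant_id = sprintf("p%05d", seq_len(n)),
    female = female, age = age, smoking = smoking, activity = activity,
    education = education, urban = urban,
    height_m = height, weight_kg = bmi * height^2, wc_cm = wc,
    grs_obesity = grs_obesity
  )
}

# Per-day food composition. The latent dietary GI is realised exactly by
# blending a high-GI and a low-GI carbohydrate pool (extending to pure
# steamed bread above the high pool and towards apple below the low pool),
# after compensating for the GI-zero carbohydrate of the side dishes.
draw_recalls <- function(cfg, participants, seed) {
  set.seed(substream_seed(seed, "diet"))
  n <- cfg$n
  nut <- resolve_food_nutrients(cfg$catalog)
  gi_of <- setNames(nut$gi, nut$food_id)
  cho_of <- setNames(nut$cho_per_100g, nut$food_id)
  prot_of <- setNames(nut$protein_per_100g, nut$food_id)
  fat_of <- setNames(nut$fat_per_100g, nut$food_id)

  gi_latent <- cfg$gi_scale[["lo"]] + cfg$gi_scale[["span"]] *
    rbeta(n, cfg$gi_beta[["a"]], cfg$gi_beta[["b"]])
  gi_latent <- pmin(gi_latent, cfg$gi_scale[["cap"]])
  lo <- ifelse(participants$female == 1, 500, 800) * cfg$energy_margin[["lo"]]
  hi <- ifelse(participants$female == 1, 3500, 4200) * cfg$energy_margin[["hi"]]
  energy <- rnorm_trunc(n, cfg$energy[["mean"]], cfg$energy[["sd"]], lo, hi)
  pct_cho <- rnorm_trunc(n, cfg$pct_cho[["mean"]], cfg$pct_cho[["sd"]],
                         cfg$pct_cho[["lo"]], cfg$pct_cho[["hi"]])
  pct_prot <- rnorm_trunc(n, cfg$pct_protein[["mean"]], cfg$pct_protein[["sd"]],
                          cfg$pct_protein[["lo"]], cfg$pct_protein[["hi"]])
  n_recalls <- sample(as.integer(names(cfg$recall_mix)), n, replace = TRUE,
                      prob = cfg$recall_mix)

  set.seed(substream_seed(seed, "recalls"))
  day <- tibble::tibble(
    row = rep(seq_len(n), n_recalls),
    day_index = unlist(lapply(n_recalls, seq_len), use.names = FALSE)
  )
  nd <- nrow(day)
  day$participant_id <- participants$participant_id[day$row]
  day$energy <- energy[day$row] * exp(rnorm(nd, 0, cfg$energy_day_sd))
  day$gi_target <- pmin(pmax(gi_latent[day$row] + rnorm(nd, 0, cfg$gi_day_sd),
                             30), cfg$gi_scale[["cap"]])
  day$cho_total <- pct_cho[day$row] / 100 * day$energy / 4

  sides <- names(cfg$side_dishes)
  side_g <- sapply(sides, function(s) {
    cfg$side_dishes[[s]] * exp(rnorm(nd, 0, cfg$side_jitter_sd))
  })
  cho_side <- as.numeric(side_g %*% (cho_of[sides] / 100))
  cho_pool <- pmax(day$cho_total - cho_side, 5)
  g_star <- day$gi_target * day$cho_total / cho_pool

  high <- cfg$high_pool; low <- cfg$low_pool
  gi_high <- sum(high * gi_of[names(high)])
  gi_low <- sum(low * gi_of[names(low)])
  gi_top <- gi_of[["steamed_bread"]]
  gi_bottom <- gi_of[["apple"]]
  g_star <- pmin(pmax(g_star, gi_bottom + 0.5), gi_top - 0.5)

  carb_foods <- union(names(high), names(low))
  W <- matrix(0, nd, length(carb_foods), dimnames = list(NULL, carb_foods))
  mid <- g_star >= gi_low & g_star <= gi_high
  f <- (g_star - gi_low) / (gi_high - gi_low)
  for (nm in names(high)) W[mid, nm] <- f[mid] * high[[nm]]
  for (nm in names(low)) W[mid, nm] <- W[mid, nm] + (1 - f[mid]) * low[[nm]]
  up <- g_star > gi_high
  lam_up <- (g_star - gi_high) / (gi_top - gi_high)
  for (nm in names(high)) W[up, nm] <- (1 - lam_up[up]) * high[[nm]]
  W[up, "steamed_bread"] <- W[up, "steamed_bread"] + lam_up[up]
  dn <- g_star < gi_low
  lam_dn <- (gi_low - g_star) / (gi_low - gi_bottom)
  for (nm in names(low)) W[dn, nm] <- (1 - lam_dn[dn]) * low[[nm]]
  W[dn, "apple"] <- W[dn, "apple"] + lam_dn[dn]

  grams_carb <- sweep(W * cho_pool, 2, cho_of[carb_foods] / 100, "/")

  prot_target <- pct_prot[day$row] / 100 * day$energy / 4
  prot_so_far <- as.numeric(grams_carb %*% (prot_of[carb_foods] / 100)) +
    as.numeric(side_g %*% (prot_of[sides] / 100))
  pork_g <- pmax(prot_target - prot_so_far, 0) / (prot_of[["pork"]] / 100)
  pct_fat <- pmax(100 - pct_cho[day$row] - pct_prot[day$row], 10)
  fat_target <- pct_fat / 100 * day$energy / 9
  fat_so_far <- as.numeric(grams_carb %*% (fat_of[carb_foods] / 100)) +
    as.numeric(side_g %*% (fat_of[sides] / 100)) +
    pork_g * fat_of[["pork"]] / 100
  oil_g <- pmax(fat_target - fat_so_far, 0) / (fat_of[["oil"]] / 100)

  grams <- cbind(grams_carb, side_g, pork = pork_g, oil = oil_g)
  long <- tibble::tibble(
    participant_id = rep(day$participant_id, ncol(grams)),
    day_index = rep(day$day_index, ncol(grams)),
    food_id = rep(colnames(grams), each = nd),
    grams = as.numeric(grams)
  )
  long <- long[long$grams >= 0.5, ]
  long <- long[order(long$participant_id, long$day_index, long$food_id), ]
  list(recalls = long, gi_latent = gi_latent, energy_latent = energy)
}

draw_genotypes <- function(cfg, participants, seed) {
  set.seed(substream_seed(seed, "genotypes"))
  panel <- cfg$snp_panel
  n <- cfg$n
  m <- vapply(seq_len(nrow(panel)), function(j) {
    rbinom(n, 2, panel$risk_allele_freq[j])
  }, numeric(n))
  colnames(m) <- panel$snp_id
  rownames(m) <- participants$participant_id
  m
}

# LS means of an arbitrary working response under a tertile scheme with the
# tier-3 covariate set; linear in the response, which is what makes the
# coefficient solve below exact.
ls_means_of <- function(design, scheme, y, tier = 3) {
  d <- design
  d$.y <- y
  d$.tert <- factor(design[[paste0("tert_", scheme)]], levels = 1:3)
  covs <- tier_covariates(tier, include_grs = TRUE)
  fit <- lm(as.formula(paste(".y ~ .tert +", paste(covs, collapse = " + "))),
            data = d)
  em <- as.data.frame(summary(emmeans::emmeans(fit, ".tert",
                                               weights = "proportional")))
  setNames(em$emmean, paste0("tert", em$.tert))
}

interaction_beta <- function(design, modifier_col, sigma, power, alpha) {
  d <- design
  d$.z <- design$z_gi
  d$.m <- design[[modifier_col]] - mean(design[[modifier_col]])
  covs <- tier_covariates(3, include_grs = modifier_col != "grs",
                          drop = modifier_col)
  X <- stats::model.matrix(
    as.formula(paste("~ .z * .m +", paste(covs, collapse = " + "))), data = d)
  j <- which(colnames(X) == ".z:.m")
  se_unit <- sqrt(solve(crossprod(X))[j, j])
  (qnorm(1 - alpha / 2) + qnorm(power)) * sigma * se_unit
}

# Standardised quadratic basis in the GI residual; gives the generator one
# degree of freedom of curvature so the tertile-mean *shape*, not only the
# extreme contrast, can be pinned.
gi_quad <- function(z) {
  q <- z^2
  (q - mean(q)) / sd(q)
}

#' Calibrate outcome coefficients against adjusted tertile-mean targets
#'
#' Solves, for each outcome, log-scale coefficients on the GI energy
#' residual, a standardised quadratic in it, and the GL residual - plus the
#' intercept - such that four tier-3 adjusted (least-squares) tertile means
#' of the noise-free linear predictor land exactly on their targets, on the
#' realised diet design itself: the three GI-tertile means and the top
#' GL-tertile mean. Because the proportionally-weighted LS mean is a linear
#' functional of the response, evaluating it at the basis vectors gives an
#' exact 4x4 linear system; covariate, genetic-score and interaction
#' contributions enter as offsets. The remaining GL-tertile means are not
#' free: tertile schemes share one overall level, so the published GI and GL
#' rows cannot hold jointly, and the lower GL cells float (reported in the
#' pilot report). Interaction coefficients are sized from the design so the
#' interaction scan has the configured power at its 0.1 threshold.
#'
#' @param design An analysis-design tibble (covariates, `grs`, residuals and
#'   tertiles present; outcomes not needed).
#' @param cfg A [cohort_config()].
#' @return A list with one element per outcome (`intercept`, `b_gi`,
#'   `b_gi_quad`, `b_gl`, `beta_gi_grs`, `beta_gi_fib`, `covariates`,
#'   `sigma`) plus a `pilot_report` tibble of achieved versus requested
#'   means.
#' @export
calibrate_outcomes <- function(design, cfg = cohort_config()) {
  if (stats::var(design$z_gi) == 0 || stats::var(design$z_gl) == 0) {
    abort("calibration error: zero exposure spread in the design")
  }
  grs_c <- design$grs - mean(design$grs)
  fib_c <- design$z_fib - mean(design$z_fib)
  basis <- list(b_gi = design$z_gi, b_gi_quad = gi_quad(design$z_gi))
  # rows: LS-mean functionals GI T1/T2/T3; columns: intercept + basis.
  # The GL cells are deliberately not in the system: tertile schemes share
  # one overall level, so the GI and GL rows cannot both be pinned; the GL
  # gradient arises through the GI-GL correlation instead.
  functionals <- function(y) {
    lsm_gi <- ls_means_of(design, "gi", y)
    c(gi_t1 = lsm_gi[["tert1"]], gi_t2 = lsm_gi[["tert2"]],
      gi_t3 = lsm_gi[["tert3"]])
  }
  A <- cbind(intercept = c(1, 1, 1),
             vapply(basis, functionals, numeric(3)))
  if (rcond(A) < 1e-10) {
    abort("calibration error: basis functionals are collinear on this design")
  }
  out <- list()
  report <- NULL
  for (o in names(cfg$ls_mean_targets)) {
    tg <- cfg$ls_mean_targets[[o]]
    eff <- cfg$covariate_effects[[o]]
    sigma <- cfg$sigma[[o]]
    b_grs_int <- interaction_beta(design, "grs", sigma,
                                  cfg$interaction_power, cfg$interaction_alpha)
    b_fib_int <- interaction_beta(design, "z_fib", sigma,
                                  cfg$interaction_power, cfg$interaction_alpha)
    eta_base <- eff[["age"]] * design$age + eff[["female"]] * design$female +
      eff[["smoking"]] * design$smoking + eff[["activity"]] * design$activity +
      eff[["education"]] * design$education + eff[["grs"]] * design$grs +
      eff[["z_fib"]] * design$z_fib + eff[["z_prot"]] * design$z_prot +
      b_grs_int * design$z_gi * grs_c + b_fib_int * design$z_gi * fib_c
    targets <- log(c(tg[["gi_t1"]], tg[["gi_t2"]], tg[["gi_t3"]]))
    b <- solve(A, targets - functionals(eta_base))
    scale_per_sd <- abs(b[-1]) * vapply(basis, sd, numeric(1))
    if (any(scale_per_sd > cfg$coefficient_cap)) {
      abort(paste0("calibration error: infeasible mean targets for ", o,
                   " (effect per exposure SD ", round(max(scale_per_sd), 3),
                   " exceeds cap ", cfg$coefficient_cap,
                   "; exposure spread too small for the requested ratios)"))
    }
    eta <- eta_base + b[["intercept"]] +
      b[["b_gi"]] * basis$b_gi + b[["b_gi_quad"]] * basis$b_gi_quad
    lsm_gi <- exp(ls_means_of(design, "gi", eta))
    lsm_gl <- exp(ls_means_of(design, "gl", eta))
    out[[o]] <- list(
      intercept = b[["intercept"]], b_gi = b[["b_gi"]],
      b_gi_quad = b[["b_gi_quad"]], b_gl = 0,
      beta_gi_grs = b_grs_int, beta_gi_fib = b_fib_int,
      covariates = eff, sigma = sigma
    )
    report <- dplyr::bind_rows(report, tibble::tibble(
      outcome = o,
      cell = c("gi_t1", "gi_t2", "gi_t3", "gl_t1", "gl_t2", "gl_t3"),
      requested = c(tg[["gi_t1"]], tg[["gi_t2"]], tg[["gi_t3"]],
                    tg[["gl_t1"]], NA, tg[["gl_t3"]]),
      achieved = c(lsm_gi[["tert1"]], lsm_gi[["tert2"]], lsm_gi[["tert3"]],
                   lsm_gl[["tert1"]], lsm_gl[["tert2"]], lsm_gl[["tert3"]]),
      pinned = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    ))
  }
  out$pilot_report <- report
  out
}

outcome_eta <- function(design, co) {
  eff <- co$covariates
  grs_c <- design$grs - mean(design$grs)
  fib_c <- design$z_fib - mean(design$z_fib)
  co$intercept + co$b_gi * design$z_gi +
    co$b_gi_quad * gi_quad(design$z_gi) + co$b_gl * design$z_gl +
    eff[["age"]] * design$age + eff[["female"]] * design$female +
    eff[["smoking"]] * design$smoking + eff[["activity"]] * design$activity +
    eff[["education"]] * design$education + eff[["grs"]] * design$grs +
    eff[["z_fib"]] * design$z_fib + eff[["z_prot"]] * design$z_prot +
    co$beta_gi_grs * design$z_gi * grs_c + co$beta_gi_fib * design$z_gi * fib_c
}

draw_ffq <- function(cfg, recalls, seed) {
  set.seed(substream_seed(seed, "ffq"))
  mean_intake <- dplyr::summarise(
    dplyr::group_by(recalls, .data$participant_id, .data$food_id),
    grams_d = sum(.data$grams) / max(.data$day_index), .groups = "drop"
  )
  serving <- cfg$serving_sizes[mean_intake$food_id]
  noise <- exp(rnorm(nrow(mean_intake), -cfg$ffq_noise_sd^2 / 2,
                     cfg$ffq_noise_sd))
  tibble::tibble(
    participant_id = mean_intake$participant_id,
    item_id = mean_intake$food_id,
    servings_per_day = mean_intake$grams_d / serving * noise
  )
}

#' Generate a synthetic cohort
#'
#' Runs the full generative procedure: participants and covariates, latent
#' diet preference realised as recall records over the food catalog,
#' genotypes in HWE, diet scoring and energy-residualisation through the
#' package's own scoring code, coefficient calibration (unless supplied), and
#' correlated log-normal outcome draws. Pre-diabetes is always obtained by
#' classifying the generated FPG/HbA1c, and HOMA indices are always derived
#' downstream, so that the classification and index code sit on the tested
#' path. Bit-identical for a fixed (config, seed).
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; per-component substreams are derived
#'   deterministically from it.
#' @return A `glycohort_cohort` list: `participants` (observable table with
#'   biomarkers), `recalls`, `genotypes`, `snp_info`, `ffq` (or `NULL`),
#'   `analysis` (ready-to-model table), `truth` (latent values, calibrated
#'   coefficients, noise-free predictors), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1) {
  cfg <- config
  participants <- draw_participants(cfg, seed)
  diet <- draw_recalls(cfg, participants, seed)
  genotypes <- draw_genotypes(cfg, participants, seed)

  design <- build_analysis_table(participants, diet$recalls, cfg$catalog,
                                 genotypes, cfg$snp_panel)
  co <- cfg$coefficients %||% calibrate_outcomes(design, cfg)

  set.seed(substream_seed(seed, "outcomes"))
  n <- cfg$n
  L <- chol(cfg$error_cor)
  eps <- matrix(rnorm(n * 3), n, 3) %*% L
  eta <- list(
    fpg = outcome_eta(design, co$fpg),
    hba1c = outcome_eta(design, co$hba1c),
    insulin = outcome_eta(design, co$insulin)
  )
  participants$fpg_mmol_l <- exp(eta$fpg + co$fpg$sigma * eps[, 1])
  participants$hba1c_pct <- exp(eta$hba1c + co$hba1c$sigma * eps[, 2])
  participants$insulin_uiu_ml <- exp(eta$insulin + co$insulin$sigma * eps[, 3])

  ffq <- if (isTRUE(cfg$make_ffq)) draw_ffq(cfg, diet$recalls, seed) else NULL

  analysis <- build_analysis_table(participants, diet$recalls, cfg$catalog,
                                   genotypes, cfg$snp_panel)
  structure(list(
    participants = participants,
    recalls = diet$recalls,
    genotypes = genotypes,
    snp_info = cfg$snp_panel,
    ffq = ffq,
    analysis = analysis,
    truth = list(
      gi_latent = diet$gi_latent,
      energy_latent = diet$energy_latent,
      coefficients = co,
      eta = eta,
      design = design
    ),
    config = cfg,
    seed = seed
  ), class = "glycohort_cohort")
}

#' @export
print.glycohort_cohort <- function(x, ...) {
  cat("Synthetic cohort: n =", nrow(x$participants),
      "| recall rows:", nrow(x$recalls),
      "| SNPs:", ncol(x$genotypes),
      "| seed:", x$seed, "\n")
  invisible(x)
}

#' Assemble the analysis table from raw cohort parts
#'
#' Scores the recalls, computes sex-specific energy-adjusted residuals of
#' dietary GI, GL, cereal fiber and protein with their tertiles, attaches the
#' weighted genetic risk score (with tertiles), and derives biomarker columns
#' where biomarker inputs are present.
#'
#' @param participants Participant table (covariates, anthropometry, and
#'   biomarkers when available).
#' @param recalls Long recall records.
#' @param db Food table.
#' @param genotypes Dosage matrix (participants x SNPs).
#' @param snp_info SNP metadata.
#' @param summaries Optional pre-computed diet summaries (used for FFQ-mode
#'   sensitivity analyses); defaults to scoring `recalls`.
#' @return The analysis tibble used by the modelling functions.
#' @export
build_analysis_table <- function(participants, recalls, db, genotypes,
                                 snp_info, summaries = NULL) {
  summaries <- summaries %||% summarize_diet(recalls, db)
  d <- dplyr::inner_join(participants, summaries, by = "participant_id")
  res <- energy_residuals(
    d, vars = c("gi", "gl_g_d", "cereal_fiber_g_d", "protein_g_d")
  )
  zmap <- c(gi = "gi", gl_g_d = "gl", cereal_fiber_g_d = "fib",
            protein_g_d = "prot")
  for (v in names(zmap)) {
    sub <- res[res$variable == v, ]
    idx <- match(d$participant_id, sub$participant_id)
    d[[paste0("z_", zmap[[v]])]] <- sub$residual[idx]
    d[[paste0("tert_", zmap[[v]])]] <- sub$tertile[idx]
  }
  grs <- weighted_grs(genotypes, snp_info)
  idx <- match(d$participant_id, grs$participant_id)
  d$grs <- grs$grs_weighted[idx]
  d$tert_grs <- assign_tertiles(d$grs)
  if ("fpg_mmol_l" %in% names(d)) d <- derive_biomarkers(d)
  d
}
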