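test_that("generation is bit-identical for a fixed config and seed", {
  cfg <- cohort_config(n = 150)
  a <- suppressWarnings(generate_cohort(cfg, seed = 7))
  b <- suppressWarnings(generate_cohort(cfg, seed = 7))
  expect_identical(a$participants, b$participants)
  expect_identical(a$recalls, b$recalls)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$ffq, b$ffq)
  c <- suppressWarnings(generate_cohort(cfg, seed = 8))
  expect_false(identical(a$participants$fpg_mmol_l, c$participants$fpg_mmol_l))
})

test_that("substreams are independent: the FFQ toggle does not move outcomes", {
  on <- suppressWarnings(generate_cohort(cohort_config(n = 150), seed = 9))
  off <- suppressWarnings(
    generate_cohort(cohort_config(n = 150, make_ffq = FALSE), seed = 9)
  )
  expect_null(off$ffq)
  expect_identical(on$participants$fpg_mmol_l, off$participants$fpg_mmol_l)
  expect_identical(on$recalls, off$recalls)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n = 10), "n >= 30")
  expect_error(cohort_config(recall_mix = c("1" = 0.5, "2" = 0.2, "3" = 0.2)))
  expect_error(cohort_config(sigma = c(fpg = -1, hba1c = 0.2, insulin = 0.4)))
})

test_that("the diet scored by the pipeline equals the generator's internal diet", {
  ch <- small_cohort()
  rescored <- summarize_diet(ch$recalls, ch$config$catalog)
  idx <- match(ch$analysis$participant_id, rescored$participant_id)
  expect_identical(ch$analysis$gl_g_d, rescored$gl_g_d[idx])
  expect_identical(ch$analysis$gi, rescored$gi[idx])
  expect_identical(ch$truth$design$gl_g_d, rescored$gl_g_d[idx])
})

test_that("realised dietary GI tracks the latent preference closely", {
  ch <- small_cohort()
  idx <- match(ch$analysis$participant_id, ch$participants$participant_id)
  expect_gt(cor(ch$analysis$gi, ch$truth$gi_latent[idx]), 0.95)
  expect_lt(mean(abs(ch$analysis$gi - ch$truth$gi_latent[idx])), 3)
})

test_that("generated genotypes sit in HWE at the configured frequencies", {
  ch <- small_cohort()
  qc <- genotype_qc(ch$genotypes, ch$snp_info)
  expect_equal(nrow(qc), 12)
  expect_true(all(qc$call_rate == 1))
  # 12 SNPs at the 1% flag level: more than 2 flags is wildly unlikely
  expect_lte(sum(qc$hwe_flagged), 2)
  freq_hat <- colMeans(ch$genotypes) / 2
  se <- sqrt(ch$snp_info$risk_allele_freq * (1 - ch$snp_info$risk_allele_freq) /
               (2 * nrow(ch$genotypes)))
  expect_true(all(abs(freq_hat - ch$snp_info$risk_allele_freq) < 4 * se))
})

test_that("the weighted GRS of a generated cohort centres on 0.80", {
  ch <- small_cohort()
  expect_lt(abs(mean(ch$analysis$grs) - 0.80), 0.012)
})

test_that("calibration solves known targets on the realised design", {
  ch <- small_cohort()
  pr <- ch$truth$coefficients$pilot_report
  pinned <- pr[pr$pinned, ]
  expect_lt(max(abs(pinned$achieved - pinned$requested)), 1e-6)
})

test_that("null targets with null effects give null coefficients", {
  ch <- small_cohort()
  cfg <- cohort_config(
    n = 500,
    ls_mean_targets = list(
      fpg = c(gi_t1 = 5.4, gi_t2 = 5.4, gi_t3 = 5.4, gl_t1 = 5.4, gl_t3 = 5.4),
      hba1c = c(gi_t1 = 5.6, gi_t2 = 5.6, gi_t3 = 5.6, gl_t1 = 5.6, gl_t3 = 5.6),
      insulin = c(gi_t1 = 7, gi_t2 = 7, gi_t3 = 7, gl_t1 = 7, gl_t3 = 7)
    ),
    covariate_effects = lapply(cohort_config()$covariate_effects, function(x) x * 0),
    interaction_power = 0.05  # cancels the 0.1-threshold sizing exactly
  )
  co <- suppressWarnings(calibrate_outcomes(ch$truth$design, cfg))
  expect_lt(abs(co$fpg$b_gi), 1e-8)
  expect_lt(abs(co$fpg$b_gi_quad), 1e-8)
  expect_equal(co$fpg$intercept, log(5.4))
})

test_that("infeasible calibration targets raise a diagnostic error", {
  ch <- small_cohort()
  cfg <- cohort_config(ls_mean_targets = list(
    fpg = c(gi_t1 = 0.5, gi_t2 = 5.4, gi_t3 = 50, gl_t1 = 5.4, gl_t3 = 5.4),
    hba1c = cohort_config()$ls_mean_targets$hba1c,
    insulin = cohort_config()$ls_mean_targets$insulin
  ))
  expect_error(calibrate_outcomes(ch$truth$design, cfg), "calibration error")
  flat <- ch$truth$design
  flat$z_gi <- 0
  expect_error(calibrate_outcomes(flat, cohort_config()),
               "zero exposure spread")
})

test_that("association fits recover known generator coefficients", {
  eff0 <- c(age = 0, female = 0, smoking = 0, activity = 0, education = 0,
            grs = 0, z_fib = 0, z_prot = 0)
  known <- function(b_gi, sigma) {
    list(intercept = log(5.4), b_gi = b_gi, b_gi_quad = 0, b_gl = 0,
         beta_gi_grs = 0, beta_gi_fib = 0, covariates = eff0, sigma = sigma)
  }
  co <- list(fpg = known(0.004, 0.15), hba1c = known(0.003, 0.12),
             insulin = known(0.006, 0.3))
  cfg <- cohort_config(n = 1000, coefficients = co)
  slopes <- vapply(1:6, function(s) {
    ch <- suppressWarnings(generate_cohort(cfg, seed = 100 + s))
    trend_test(ch$analysis, model_spec("fpg_mmol_l"))$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.004), 2 * mc_se + 1e-5)
})

test_that("the cohort matches its demographic margins", {
  ch <- small_cohort()
  p <- ch$participants
  expect_true(all(p$age >= 23 & p$age <= 69))
  expect_lt(abs(mean(p$female) - 0.529), 3 * sqrt(0.529 * 0.471 / nrow(p)) + 0.01)
  expect_true(all(table(ch$recalls$participant_id) > 0))
  n_days <- tapply(ch$recalls$day_index, ch$recalls$participant_id, max)
  expect_true(all(n_days %in% 1:3))
  expect_gt(mean(n_days == 3), 0.7)
})
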