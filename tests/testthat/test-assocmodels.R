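test_that("unadjusted LS means equal stratified geometric means exactly", {
  d <- toy_cohort()
  r <- fit_adjusted_means(d, model_spec("fpg_mmol_l", covariates = character(0)))
  oracle <- exp(tapply(log(d$fpg_mmol_l), d$tert_gi, mean))
  expect_lt(max(abs(r$means$mean - oracle)), 1e-8)
  expect_equal(r$means$n, as.integer(table(d$tert_gi)))
})

test_that("a constant outcome gives equal means and a null trend", {
  d <- toy_cohort()
  d$fpg_mmol_l <- 5.4
  r <- suppressWarnings(
    fit_adjusted_means(d, model_spec("fpg_mmol_l", covariates = character(0)))
  )
  expect_equal(r$means$mean, rep(5.4, 3))
  expect_gt(r$p_trend, 0.99)
})

test_that("back-transformed means are invariant to shifting covariates", {
  d <- toy_cohort()
  r1 <- fit_adjusted_means(d, model_spec("fpg_mmol_l", tier = 2))
  d2 <- d
  d2$age <- d2$age + 100
  d2$activity <- d2$activity + 55
  r2 <- fit_adjusted_means(d2, model_spec("fpg_mmol_l", tier = 2))
  expect_equal(r1$means$mean, r2$means$mean, tolerance = 1e-8)
  expect_equal(r1$p_trend, r2$p_trend, tolerance = 1e-8)
})

test_that("saturated logistic ORs equal the 2x2 cross-product ratio", {
  counts <- list(c(30, 70), c(40, 60), c(55, 45))  # cases, non-cases by tertile
  d <- dplyr::bind_rows(lapply(1:3, function(t) {
    tibble::tibble(
      tert_gi = t,
      z_gi = t - 2 + seq(0, 0.1, length.out = sum(counts[[t]])),
      prediabetes = rep(c(TRUE, FALSE), counts[[t]])
    )
  }))
  r <- fit_prediabetes_or(d, model_spec("prediabetes", log_transform = FALSE,
                                        covariates = character(0)))
  expect_equal(r$or$or[1], 1)
  expect_equal(r$or$or[2], (40 * 70) / (60 * 30), tolerance = 1e-6)
  expect_equal(r$or$or[3], (55 * 70) / (45 * 30), tolerance = 1e-6)
})

test_that("complete separation is refused rather than reported", {
  d <- toy_cohort()
  d$prediabetes <- d$tert_gi == 3
  expect_error(
    suppressWarnings(
      fit_prediabetes_or(d, model_spec("prediabetes", log_transform = FALSE,
                                       covariates = character(0)))
    ),
    "separation"
  )
})

test_that("rank-deficient designs are rejected with the offending term", {
  d <- toy_cohort()
  d$education <- d$smoking
  expect_error(fit_adjusted_means(d, model_spec("fpg_mmol_l", tier = 2)),
               "collinear.*education")
})

test_that("trend and interaction tests hold their nominal size under the null", {
  set.seed(10)
  n <- 200
  reps <- 500
  p_trend <- numeric(reps)
  p_int <- numeric(reps)
  base <- tibble::tibble(
    z_gi = rnorm(n), grs = rnorm(n, 0.8, 0.1)
  )
  base$tert_gi <- assign_tertiles(base$z_gi)
  for (i in seq_len(reps)) {
    d <- base
    d$fpg_mmol_l <- exp(rnorm(n, log(5.4), 0.1))
    spec <- model_spec("fpg_mmol_l", covariates = character(0))
    p_trend[i] <- trend_test(d, spec)$p_value
    p_int[i] <- interaction_scan(d, spec, modifier = "grs")$p_interaction
  }
  tol05 <- 3 * sqrt(0.05 * 0.95 / reps)
  tol10 <- 3 * sqrt(0.10 * 0.90 / reps)
  expect_lt(abs(mean(p_trend < 0.05) - 0.05), tol05)
  expect_lt(abs(mean(p_int < 0.10) - 0.10), tol10)
})

test_that("a constant interaction modifier is a loud error", {
  d <- toy_cohort()
  d$grs <- 0.8
  expect_error(
    interaction_scan(d, model_spec("fpg_mmol_l"), modifier = "grs"),
    "degenerate"
  )
  expect_error(
    interaction_scan(d, model_spec("fpg_mmol_l")),
    "no interaction modifier"
  )
})

test_that("cross-classification covers 9 cells with an OR-1 reference", {
  a <- small_cohort()$analysis
  cc <- cross_classify(a, "gi", "grs")
  expect_equal(nrow(cc$cells), 9)
  expect_equal(sum(cc$cells$n), nrow(a))
  ref <- cc$cells[cc$cells$exposure_tertile == 1 & cc$cells$modifier_tertile == 1, ]
  expect_equal(ref$or, 1)
  cc2 <- cross_classify(a, "gi", "fib", reference = c(1, 3))
  ref2 <- cc2$cells[cc2$cells$exposure_tertile == 1 & cc2$cells$modifier_tertile == 3, ]
  expect_equal(ref2$or, 1)
  ccm <- cross_classify(a, "gi", "grs", outcome = "fpg_mmol_l")
  expect_true(all(is.finite(ccm$cells$mean)))
})

test_that("an empty cross-classification cell is an error", {
  d <- toy_cohort()
  d$tert_grs <- ifelse(d$tert_gi == 1, 2, d$tert_grs)  # empties the (1,1) cell
  expect_error(cross_classify(d, "gi", "grs"), "empty cross-classification")
})

test_that("the energy partition model recovers known per-source effects", {
  set.seed(11)
  d <- toy_cohort(n = 800)
  comp <- tibble::tibble(
    rice = d$energy_kcal_d * pmin(pmax(0.4 + rnorm(800, 0, 0.03), 0.2), 0.55),
    noodles = d$energy_kcal_d * pmin(pmax(0.2 + rnorm(800, 0, 0.02), 0.05), 0.35)
  )
  remaining <- d$energy_kcal_d - comp$rice - comp$noodles
  stopifnot(all(remaining > 0))
  b <- c(rice = 4e-4, noodles = 1e-4, remaining = 2e-4)
  d$fpg_mmol_l <- exp(log(5) + b["rice"] * comp$rice +
                        b["noodles"] * comp$noodles +
                        b["remaining"] * remaining + rnorm(800, 0, 0.05))
  fit <- energy_partition_fit(d, comp, "fpg_mmol_l")
  est <- setNames(fit$coefficient, fit$component)
  for (nm in names(b)) {
    se <- fit$se[fit$component == nm]
    expect_lt(abs(est[[nm]] - b[[nm]]), 4 * se)
  }
  bad <- comp
  bad$rice <- d$energy_kcal_d + 1
  expect_error(energy_partition_fit(d, bad, "fpg_mmol_l"), "exceed total energy")
})

test_that("percent contrast matches printed arithmetic", {
  mk <- function(means) {
    structure(list(means = tibble::tibble(tertile = 1:3, mean = means)),
              class = "glycohort_modelresult")
  }
  expect_equal(percent_contrast(mk(c(5.19, 5.39, 5.67))), 9.2486, tolerance = 1e-4)
  expect_equal(round(percent_contrast(mk(c(5.19, 5.39, 5.67))), 2), 9.25)
  expect_equal(percent_contrast(mk(c(5.4, 5.4, 5.4))), 0)
  expect_equal(round(percent_contrast(mk(c(1.09, 1.2, 1.40))), 1), 28.4)
  expect_error(percent_contrast(mk(c(0, 1, 2))), "not positive")
})
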