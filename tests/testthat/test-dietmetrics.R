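catalog <- demo_food_catalog()

test_that("daily GL, GI and carbohydrate match hand arithmetic", {
  rec <- tibble::tibble(
    participant_id = "p1", day_index = 1,
    food_id = c("rice_sticky", "apple"), grams = c(100, 200)
  )
  out <- daily_gl_gi(rec, catalog)
  cho <- 28 + 2 * 13
  gl <- 28 * 0.83 + 26 * 0.28
  expect_equal(out$cho, cho)
  expect_equal(out$gl, gl)
  expect_equal(out$gi, 100 * gl / cho)
})

test_that("a carbohydrate-free day has GL 0 and undefined GI", {
  rec <- tibble::tibble(participant_id = "p1", day_index = 1,
                        food_id = "oil", grams = 30)
  out <- daily_gl_gi(rec, catalog)
  expect_equal(out$gl, 0)
  expect_true(is.na(out$gi))
})

test_that("unknown food ids in recalls are an error", {
  rec <- tibble::tibble(participant_id = "p1", day_index = 1,
                        food_id = "unobtainium", grams = 100)
  expect_error(daily_gl_gi(rec, catalog), "unobtainium")
})

test_that("participant summaries average days and use ratio-of-means GI", {
  rec <- tibble::tibble(
    participant_id = "p1", day_index = c(1, 2),
    food_id = c("rice_sticky", "rice_indica"), grams = c(100, 100)
  )
  s <- summarize_diet(rec, catalog)
  expect_equal(s$n_recalls, 2)
  expect_equal(s$cho_g_d, 28)
  gl <- c(28 * 0.83, 28 * 0.50)
  expect_equal(s$gl_g_d, mean(gl))
  expect_equal(s$gi, 100 * mean(gl) / 28)
  # single-recall participant passes through unchanged
  one <- summarize_participant(rec[1, ], catalog)
  expect_equal(one$n_recalls, 1)
  expect_equal(one$gi, 83)
  expect_error(summarize_participant(rec[0, ], catalog), "no recall days")
})

test_that("cereal fiber counts only cereal-flagged foods", {
  rec <- tibble::tibble(
    participant_id = "p1", day_index = 1,
    food_id = c("rice_sticky", "apple"), grams = c(100, 100)
  )
  s <- summarize_diet(rec, catalog)
  expect_equal(s$cereal_fiber_g_d, 1.2)      # apple fiber excluded
  expect_equal(s$fiber_g_d, 1.2 + 2.4)
  expect_identical(cereal_fiber(rec, catalog)$cereal_fiber_g_d, s$cereal_fiber_g_d)
  # property: cereal fiber never exceeds total fiber
  big <- small_cohort()
  s2 <- summarize_diet(big$recalls, catalog)
  expect_true(all(s2$cereal_fiber_g_d <= s2$fiber_g_d + 1e-12))
})

test_that("energy plausibility bounds are inclusive and sex-specific", {
  s <- tibble::tibble(
    participant_id = c("m_lo", "m_below", "m_hi", "m_above", "f_lo", "f_hi"),
    energy_kcal_d = c(800, 799.9, 4200, 4200.1, 500, 3500)
  )
  sex <- tibble::tibble(participant_id = s$participant_id,
                        female = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  out <- plausibility_filter(s, sex)
  expect_setequal(out$retained$participant_id, c("m_lo", "m_hi", "f_lo", "f_hi"))
  expect_equal(
    out$excluded$reason[out$excluded$participant_id == "m_below"],
    "energy below plausibility bound"
  )
  expect_equal(
    out$excluded$reason[out$excluded$participant_id == "m_above"],
    "energy above plausibility bound"
  )
  expect_error(plausibility_filter(s, sex[-1, ]), "unknown sex")
})

test_that("energy residuals are zero for perfectly linear intakes", {
  n <- 60
  set.seed(2)
  d <- tibble::tibble(
    participant_id = as.character(seq_len(n)),
    female = rep(c(0, 1), n / 2),
    energy_kcal_d = runif(n, 1000, 3000)
  )
  d$lin <- ifelse(d$female == 1, 5 + 0.01 * d$energy_kcal_d,
                  9 + 0.02 * d$energy_kcal_d)
  res <- energy_residuals(d, "lin")
  expect_lt(max(abs(res$residual)), 1e-8)
})

test_that("residuals are orthogonal to energy within sex and recover noise scale", {
  n <- 1000
  set.seed(3)
  d <- tibble::tibble(
    participant_id = as.character(seq_len(n)),
    female = rbinom(n, 1, 0.5),
    energy_kcal_d = runif(n, 1000, 3000)
  )
  d$x <- 10 + 0.02 * d$energy_kcal_d + rnorm(n, 0, 1.3)
  res <- energy_residuals(d, "x")
  r <- res$residual[match(d$participant_id, res$participant_id)]
  for (g in 0:1) {
    sel <- d$female == g
    expect_lt(abs(sum(r[sel] * d$energy_kcal_d[sel])), 1e-6)
    expect_lt(abs(mean(r[sel])), 1e-9)
  }
  expect_equal(sd(r), 1.3, tolerance = 0.1)
})

test_that("zero energy variance in a stratum degrades to centred values", {
  d <- tibble::tibble(
    participant_id = as.character(1:6),
    female = c(0, 0, 0, 1, 1, 1),
    energy_kcal_d = c(2000, 2000, 2000, 1500, 1600, 1700),
    x = c(1, 2, 3, 4, 5, 6)
  )
  expect_warning(res <- energy_residuals(d, "x"), "zero energy variance")
  expect_equal(res$residual[1:3], c(-1, 0, 1))
  expect_error(suppressWarnings(energy_residuals(d[1:4, ], "x")), "fewer than 3")
})

test_that("tertiles use pooled percentile cuts with ties to the lower group", {
  expect_identical(assign_tertiles(1:9), rep(1:3, each = 3))
  # values exactly at the lower cut stay in tertile 1
  x <- c(0, 0, 4, 4, 4, 4, 8, 8, 8)
  cuts <- quantile(x, c(1, 2) / 3, names = FALSE)
  expect_equal(cuts[1], 4)
  expect_identical(assign_tertiles(x)[3:6], rep(1L, 4))
  expect_warning(flat <- assign_tertiles(rep(2, 10)), "all values equal")
  expect_identical(flat, rep(1L, 10))
  expect_error(assign_tertiles(c(1, 2)), "at least 3")
  # near-balanced groups on continuous data
  set.seed(4)
  t <- assign_tertiles(rnorm(999))
  expect_lte(diff(range(table(t))), 2)
})

test_that("FFQ GI and GL match hand arithmetic", {
  one <- tibble::tibble(servings_per_day = 2, cho_per_serving = 25, gi = 70)
  out <- ffq_gi_gl(one)
  expect_equal(out$gl, 35)
  expect_equal(out$gi, 70)
  two <- tibble::tibble(servings_per_day = c(1, 1),
                        cho_per_serving = c(50, 25), gi = c(100, 40))
  out2 <- ffq_gi_gl(two)
  expect_equal(out2$gl, 60)
  expect_equal(out2$gi, 80)
  none <- tibble::tibble(servings_per_day = 1, cho_per_serving = 0, gi = 50)
  expect_error(ffq_gi_gl(none), "no carbohydrate")
})
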