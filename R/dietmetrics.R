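#' Diet scoring from repeated 24-hour recalls
#'
#' Recall records are long-format rows (`participant_id`, `day_index`,
#' `food_id`, `grams`). Each food's glycemic load contribution is its
#' carbohydrate mass times its GI over 100; the daily dietary GI is
#' 100 * GL / CHO. Participant-level intakes are unweighted means over the
#' available recall days (1-3), and the participant dietary GI is the ratio of
#' mean GL to mean CHO, mirroring the definition of the total dietary GI as
#' total GL divided by total carbohydrate.
#'
#' @name diet-scoring
NULL

resolve_food_nutrients <- function(db) {
  gi <- assign_gi_table(db)
  dplyr::left_join(db, gi[c("food_id", "gi", "tier")],
                   by = "food_id", suffix = c("_raw", "")) |>
    dplyr::select(dplyr::all_of(c(
      "food_id", "cho_per_100g", "fiber_per_100g", "protein_per_100g",
      "fat_per_100g", "kcal_per_100g", "is_cereal", "gi"
    )))
}

#' Glycemic load, dietary GI and carbohydrate for one recall day
#'
#' @param records Recall rows for a single participant-day.
#' @param db Food table; all `food_id`s must resolve to an assigned GI.
#' @return A list with `gl` (g), `gi` (dimensionless, `NA` when no
#'   carbohydrate was consumed) and `cho` (g).
#' @export
daily_gl_gi <- function(records, db) {
  nut <- resolve_food_nutrients(db)
  idx <- match(records$food_id, nut$food_id)
  if (anyNA(idx)) {
    abort(paste0("unresolved food_id in recalls: ",
                 paste(unique(records$food_id[is.na(idx)]), collapse = ", ")))
  }
  cho <- records$grams * nut$cho_per_100g[idx] / 100
  gl <- cho * nut$gi[idx] / 100
  total_cho <- sum(cho)
  list(
    gl = sum(gl),
    gi = if (total_cho > 0) 100 * sum(gl) / total_cho else NA_real_,
    cho = total_cho
  )
}

score_recall_days <- function(records, db) {
  nut <- resolve_food_nutrients(db)
  idx <- match(records$food_id, nut$food_id)
  if (anyNA(idx)) {
    abort(paste0("unresolved food_id in recalls: ",
                 paste(unique(records$food_id[is.na(idx)]), collapse = ", ")))
  }
  per_row <- tibble::tibble(
    participant_id = records$participant_id,
    day_index = records$day_index,
    cho = records$grams * nut$cho_per_100g[idx] / 100,
    fiber = records$grams * nut$fiber_per_100g[idx] / 100,
    protein = records$grams * nut$protein_per_100g[idx] / 100,
    fat = records$grams * nut$fat_per_100g[idx] / 100,
    kcal = records$grams * nut$kcal_per_100g[idx] / 100
  )
  per_row$gl <- per_row$cho * nut$gi[idx] / 100
  per_row$cereal_fiber <- ifelse(nut$is_cereal[idx], per_row$fiber, 0)
  dplyr::summarise(
    dplyr::group_by(per_row, .data$participant_id, .data$day_index),
    dplyr::across(dplyr::all_of(
      c("cho", "gl", "fiber", "cereal_fiber", "protein", "fat", "kcal")
    ), sum),
    .groups = "drop"
  )
}

#' Summarise one participant's recalls into daily-mean intakes
#'
#' @param records All recall rows of a single participant.
#' @param db Food table.
#' @return A one-row [summarize_diet()] tibble.
#' @export
summarize_participant <- function(records, db) {
  if (nrow(records) == 0) abort("no recall days for participant")
  summarize_diet(records, db)
}

#' Summarise recalls for all participants
#'
#' Produces one row per participant with `n_recalls`, mean daily energy,
#' carbohydrate, glycemic load, dietary GI, fiber, cereal fiber and percent
#' energy from protein, fat and carbohydrate.
#'
#' @param records Long recall table for any number of participants.
#' @param db Food table.
#' @return A tibble, one row per participant.
#' @export
summarize_diet <- function(records, db) {
  days <- score_recall_days(records, db)
  out <- dplyr::summarise(
    dplyr::group_by(days, .data$participant_id),
    n_recalls = dplyr::n_distinct(.data$day_index),
    energy_kcal_d = mean(.data$kcal),
    cho_g_d = mean(.data$cho),
    gl_g_d = mean(.data$gl),
    fiber_g_d = mean(.data$fiber),
    cereal_fiber_g_d = mean(.data$cereal_fiber),
    protein_g_d = mean(.data$protein),
    fat_g_d = mean(.data$fat),
    .groups = "drop"
  )
  out$gi <- ifelse(out$cho_g_d > 0, 100 * out$gl_g_d / out$cho_g_d, NA_real_)
  out$protein_pct_e <- 100 * 4 * out$protein_g_d / out$energy_kcal_d
  out$fat_pct_e <- 100 * 9 * out$fat_g_d / out$energy_kcal_d
  out$cho_pct_e <- 100 * 4 * out$cho_g_d / out$energy_kcal_d
  out
}

#' Mean daily cereal fiber intake
#'
#' Sum of the fiber contributed by foods flagged as cereals (rice, millet,
#' noodles, cereals, bread, cookies, crackers), averaged over recall days.
#'
#' @param records Long recall table.
#' @param db Food table with the `is_cereal` flag.
#' @return A tibble with `participant_id` and `cereal_fiber_g_d`.
#' @export
cereal_fiber <- function(records, db) {
  summarize_diet(records, db)[c("participant_id", "cereal_fiber_g_d")]
}

#' Energy plausibility filter
#'
#' Retains men reporting 800-4200 kcal/d and women reporting 500-3500 kcal/d
#' (bounds inclusive); everyone else is excluded with a logged reason.
#'
#' @param summaries Diet summaries with `participant_id` and `energy_kcal_d`.
#' @param sex Named or positionally aligned logical vector, `TRUE` for female;
#'   alternatively a data frame with `participant_id` and `female`.
#' @return A list with `retained` (tibble) and `excluded` (tibble with
#'   `reason`).
#' @export
plausibility_filter <- function(summaries, sex) {
  if (is.data.frame(sex)) {
    idx <- match(summaries$participant_id, sex$participant_id)
    female <- sex$female[idx]
  } else {
    female <- sex
  }
  if (anyNA(female)) {
    abort(paste0("unknown sex for participant(s): ",
                 paste(summaries$participant_id[is.na(female)], collapse = ", ")))
  }
  lo <- ifelse(female, 500, 800)
  hi <- ifelse(female, 3500, 4200)
  keep <- summaries$energy_kcal_d >= lo & summaries$energy_kcal_d <= hi
  excluded <- summaries[!keep, ]
  excluded$reason <- ifelse(
    excluded$energy_kcal_d < lo[!keep],
    "energy below plausibility bound", "energy above plausibility bound"
  )
  list(retained = summaries[keep, ], excluded = excluded)
}

residualize_on_energy <- function(value, energy, female) {
  res <- rep(NA_real_, length(value))
  for (grp in unique(female)) {
    sel <- which(female == grp)
    if (length(sel) < 3) {
      abort("fewer than 3 participants in a sex stratum")
    }
    if (stats::var(energy[sel]) == 0) {
      warn("zero energy variance in a sex stratum; residual = value - mean")
      res[sel] <- value[sel] - mean(value[sel])
    } else {
      fit <- lm(value[sel] ~ energy[sel])
      res[sel] <- stats::resid(fit)
    }
  }
  res
}

#' Sex-specific energy-adjusted residuals
#'
#' Each variable is regressed on total energy intake within sex strata
#' (ordinary least squares with intercept); the residual is the
#' energy-adjusted exposure. Residuals average to zero and are orthogonal to
#' energy within each stratum.
#'
#' @param data Data frame with the variables, an energy column and a `female`
#'   indicator.
#' @param vars Character vector of variable names to residualise.
#' @param energy Name of the energy column (kcal/d).
#' @param female Name of the female indicator column.
#' @return A long tibble with `participant_id`, `variable`, `residual` and
#'   pooled `tertile`.
#' @export
energy_residuals <- function(data, vars, energy = "energy_kcal_d",
                             female = "female") {
  dplyr::bind_rows(lapply(vars, function(v) {
    r <- residualize_on_energy(data[[v]], data[[energy]], data[[female]])
    tibble::tibble(
      participant_id = data$participant_id,
      variable = v,
      residual = r,
      tertile = assign_tertiles(r)
    )
  }))
}

#' Tertile assignment on the pooled distribution
#'
#' Cut points are the 33.33rd and 66.67th percentiles of the pooled values;
#' values exactly at a cut point fall into the lower tertile. With all values
#' equal, everything lands in tertile 1 with a warning.
#'
#' @param x Numeric vector, `n >= 3`.
#' @return Integer tertile labels 1-3.
#' @export
assign_tertiles <- function(x) {
  if (length(x) < 3) abort("tertiles need at least 3 values")
  cuts <- quantile(x, c(1, 2) / 3, na.rm = TRUE, names = FALSE)
  if (cuts[1] == cuts[2] && stats::var(x, na.rm = TRUE) == 0) {
    warn("all values equal; everything assigned to tertile 1")
    return(rep(1L, length(x)))
  }
  as.integer(1L + (x > cuts[1]) + (x > cuts[2]))
}

#' Dietary GI and GL from food-frequency questionnaire items
#'
#' GL is the sum over items of servings/day x carbohydrate per serving x
#' GI / 100; GI is 100 x GL over total daily carbohydrate.
#'
#' @param items Data frame with `servings_per_day`, `cho_per_serving`, `gi`.
#' @return A list with `gi` and `gl`.
#' @export
ffq_gi_gl <- function(items) {
  cho <- items$servings_per_day * items$cho_per_serving
  if (sum(cho) <= 0) abort("undefined GI: FFQ items contribute no carbohydrate")
  gl <- sum(cho * items$gi) / 100
  list(gi = 100 * gl / sum(cho), gl = gl)
}
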