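#' End-to-end analysis pipeline
#'
#' Orchestrates exclusions, diet scoring, energy-residualisation, tertiling,
#' biomarker derivation, descriptive tables, adjusted-mean and odds-ratio
#' models, interaction scans and cross-classification grids, and emits a
#' machine-readable manifest. Re-running with the same cohort and
#' configuration yields byte-identical report tables.
#'
#' @name pipeline
NULL

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("[stage ", stage, "] ", conditionMessage(e)))
  })
}

#' Variable declarations for the descriptive table
#'
#' The statistical test per descriptive variable is declared, not inferred
#' from a normality screen: `normal` uses one-way ANOVA, `nonnormal` the
#' Kruskal-Wallis test, `categorical` the chi-square test.
#'
#' @return Named character vector, variable -> declared type.
#' @export
descriptive_declarations <- function() {
  c(age = "normal", female = "categorical", smoking = "categorical",
    education = "categorical", urban = "categorical",
    activity = "nonnormal", bmi = "normal", bf_pct = "normal",
    energy_kcal_d = "normal", cho_g_d = "normal", gl_g_d = "normal",
    gi = "normal", cereal_fiber_g_d = "nonnormal", grs = "normal",
    fpg_mmol_l = "nonnormal", hba1c_pct = "nonnormal",
    insulin_uiu_ml = "nonnormal", homa_ir = "nonnormal",
    prediabetes = "categorical")
}

descriptive_table <- function(analysis, exposure, declarations) {
  tert <- factor(analysis[[paste0("tert_", exposure)]], levels = 1:3)
  rows <- lapply(names(declarations), function(v) {
    if (!v %in% names(analysis)) return(NULL)
    x <- analysis[[v]]
    type <- declarations[[v]]
    if (type == "categorical") {
      x <- as.numeric(x)
      p <- suppressWarnings(stats::chisq.test(table(x, tert))$p.value)
      stat <- tapply(x, tert, mean) * 100
      test <- "chi-square"
    } else if (type == "nonnormal") {
      p <- stats::kruskal.test(x, tert)$p.value
      stat <- tapply(x, tert, stats::median)
      test <- "kruskal-wallis"
    } else {
      p <- summary(stats::aov(x ~ tert))[[1]][["Pr(>F)"]][1]
      stat <- tapply(x, tert, mean)
      test <- "anova"
    }
    tibble::tibble(variable = v, type = type,
                   tertile_1 = stat[["1"]], tertile_2 = stat[["2"]],
                   tertile_3 = stat[["3"]],
                   test = test, p_value = p)
  })
  dplyr::bind_rows(rows)
}

apply_exclusions <- function(cohort, three_recall_only) {
  participants <- cohort$participants
  recalls <- cohort$recalls
  log <- tibble::tibble(stage = "input", excluded = 0L,
                        remaining = nrow(participants))
  note <- function(stage, keep_ids) {
    excluded <- log$remaining[nrow(log)] - length(keep_ids)
    log <<- dplyr::bind_rows(log, tibble::tibble(
      stage = stage, excluded = as.integer(excluded),
      remaining = length(keep_ids)
    ))
    keep_ids
  }
  ids <- participants$participant_id
  history_cols <- intersect(
    c("diabetes_history", "cvd_history", "cancer_history"),
    names(participants)
  )
  if (length(history_cols) > 0) {
    flagged <- rowSums(as.matrix(participants[history_cols])) > 0
    ids <- note("disease history", ids[!flagged[match(ids, participants$participant_id)]])
  }
  has_recalls <- ids %in% unique(recalls$participant_id)
  biom <- participants[match(ids, participants$participant_id), ]
  complete <- !is.na(biom$fpg_mmol_l) & !is.na(biom$hba1c_pct) &
    !is.na(biom$insulin_uiu_ml)
  ids <- note("missing recalls or biomarkers", ids[has_recalls & complete])
  summaries <- summarize_diet(
    recalls[recalls$participant_id %in% ids, ], cohort$config$catalog
  )
  pf <- plausibility_filter(
    summaries, participants[c("participant_id", "female")]
  )
  ids <- note("implausible energy intake", pf$retained$participant_id)
  if (three_recall_only) {
    full <- pf$retained$participant_id[pf$retained$n_recalls == 3]
    ids <- note("fewer than 3 recall days", full)
  }
  stopifnot(log$remaining[1] - sum(log$excluded) == log$remaining[nrow(log)])
  list(ids = ids, flow_log = log)
}

#' Run the full analysis pipeline on a cohort
#'
#' Applies the exclusion cascade (disease-history flags when present,
#' completeness, energy plausibility, optionally the three-recall
#' restriction), rebuilds the analysis table from raw parts, and produces the
#' four report tables: tertile descriptives, adjusted means for the
#' continuous glucose-homeostasis outcomes, pre-diabetes odds ratios (each by
#' GI and GL tertiles across the requested tiers, with trend and interaction
#' p-values), and the 3x3 cross-classification grids (exposure x genetic risk
#' score and exposure x cereal fiber), plus a run manifest.
#'
#' In `ffq_mode` the dietary exposures are recomputed from the cohort's
#' food-frequency items instead of the recalls (energy and the other
#' nutrients still come from the recalls), which attenuates diet-outcome
#' contrasts through the FFQ's extra measurement error.
#'
#' @param cohort A `glycohort_cohort` (or a list with the same elements).
#' @param tiers Adjustment tiers to run (subset of 1:4).
#' @param exposures Exposure stems, default GI and GL.
#' @param three_recall_only Restrict to participants with 3 recall days.
#' @param ffq_mode Score dietary GI/GL from FFQ items.
#' @return A `glycohort_report` list: `flow_log`, `descriptives`,
#'   `adjusted_means`, `odds_ratios`, `crossclass`, `interactions`,
#'   `analysis`, `manifest`.
#' @export
run_pipeline <- function(cohort, tiers = 1:3, exposures = c("gi", "gl"),
                         three_recall_only = FALSE, ffq_mode = FALSE) {
  stopifnot(length(tiers) >= 1, all(tiers %in% 1:4), length(exposures) >= 1)
  excl <- run_stage("exclusions", apply_exclusions(cohort, three_recall_only))
  ids <- excl$ids
  keep <- cohort$participants$participant_id %in% ids

  analysis <- run_stage("scoring", {
    summaries <- NULL
    if (ffq_mode) {
      if (is.null(cohort$ffq)) abort("ffq_mode requested but cohort has no FFQ items")
      summaries <- ffq_summaries(cohort$ffq, cohort$recalls, cohort$config)
    }
    build_analysis_table(
      cohort$participants[keep, ],
      cohort$recalls[cohort$recalls$participant_id %in% ids, ],
      cohort$config$catalog,
      cohort$genotypes[rownames(cohort$genotypes) %in% ids, , drop = FALSE],
      cohort$snp_info,
      summaries = summaries
    )
  })

  descriptives <- run_stage("descriptives", dplyr::bind_rows(lapply(
    exposures, function(e) {
      dplyr::mutate(
        descriptive_table(analysis, e, descriptive_declarations()),
        exposure = e, .before = 1
      )
    }
  )))

  outcomes <- c("fpg_mmol_l", "hba1c_pct", "insulin_uiu_ml",
                "homa_ir", "homa_beta_pct")
  adjusted_means <- run_stage("adjusted means", dplyr::bind_rows(lapply(
    exposures, function(e) dplyr::bind_rows(lapply(tiers, function(tr) {
      dplyr::bind_rows(lapply(outcomes, function(o) {
        res <- fit_adjusted_means(
          analysis, model_spec(o, exposure = e, tier = tr,
                               interaction_with = "grs")
        )
        dplyr::mutate(res$means, exposure = e, tier = tr, outcome = o,
                      p_trend = res$p_trend,
                      p_interaction_grs = res$p_interaction, .before = 1)
      }))
    }))
  )))

  odds_ratios <- run_stage("odds ratios", dplyr::bind_rows(lapply(
    exposures, function(e) dplyr::bind_rows(lapply(tiers, function(tr) {
      res <- fit_prediabetes_or(analysis, model_spec(
        "prediabetes", exposure = e, tier = tr, log_transform = FALSE
      ))
      dplyr::mutate(res$or, exposure = e, tier = tr, p_trend = res$p_trend,
                    .before = 1)
    }))
  )))

  interactions <- run_stage("interaction scans", dplyr::bind_rows(lapply(
    exposures, function(e) dplyr::bind_rows(lapply(
      c("grs", "cereal_fiber"), function(m) {
        rows <- lapply(c(outcomes, "prediabetes"), function(o) {
          sc <- interaction_scan(analysis, model_spec(
            o, exposure = e, tier = max(tiers),
            log_transform = !identical(o, "prediabetes")
          ), modifier = m)
          tibble::tibble(exposure = e, modifier = m, outcome = o,
                         coefficient = sc$coefficient,
                         p_interaction = sc$p_interaction,
                         threshold = sc$threshold)
        })
        dplyr::bind_rows(rows)
      }
    ))
  )))

  crossclass <- run_stage("cross-classification", dplyr::bind_rows(lapply(
    exposures, function(e) dplyr::bind_rows(lapply(
      c("grs", "fib"), function(m) {
        tryCatch({
          cc <- cross_classify(analysis, exposure = e, modifier = m,
                               outcome = "prediabetes", tier = max(tiers))
          dplyr::mutate(cc$cells, exposure = e, modifier = m, .before = 1)
        }, error = function(err) {
          warn(paste0("skipping degenerate cross-classification ", e, " x ",
                      m, ": ", conditionMessage(err)))
          NULL
        })
      }
    ))
  )))

  manifest <- tibble::tibble(
    key = c("seed", "config_hash", "n_input", "n_analyzed", "tiers",
            "exposures", "three_recall_only", "ffq_mode"),
    value = c(
      as.character(cohort$seed %||% NA),
      rlang::hash(cohort$config),
      as.character(nrow(cohort$participants)),
      as.character(nrow(analysis)),
      paste(tiers, collapse = ","),
      paste(exposures, collapse = ","),
      as.character(three_recall_only),
      as.character(ffq_mode)
    )
  )

  structure(list(
    flow_log = excl$flow_log,
    descriptives = descriptives,
    adjusted_means = adjusted_means,
    odds_ratios = odds_ratios,
    interactions = interactions,
    crossclass = crossclass,
    analysis = analysis,
    manifest = manifest
  ), class = "glycohort_report")
}

#' @export
print.glycohort_report <- function(x, ...) {
  cat("Pipeline report | analyzed n =", nrow(x$analysis), "\n")
  cat("Exclusion flow:\n")
  print(as.data.frame(x$flow_log), row.names = FALSE)
  cat("Tables: descriptives (", nrow(x$descriptives), " rows), adjusted_means (",
      nrow(x$adjusted_means), "), odds_ratios (", nrow(x$odds_ratios),
      "), interactions (", nrow(x$interactions), "), crossclass (",
      nrow(x$crossclass), ")\n", sep = "")
  invisible(x)
}

# Diet summaries with GI/GL replaced by FFQ-derived values.
ffq_summaries <- function(ffq, recalls, cfg) {
  base <- summarize_diet(recalls, cfg$catalog)
  nut <- resolve_food_nutrients(cfg$catalog)
  items <- dplyr::inner_join(ffq, nut, by = c(item_id = "food_id"))
  items$cho_per_serving <- cfg$serving_sizes[items$item_id] *
    items$cho_per_100g / 100
  per_person <- dplyr::summarise(
    dplyr::group_by(items, .data$participant_id),
    gl_g_d = sum(.data$servings_per_day * .data$cho_per_serving * .data$gi) / 100,
    cho_ffq = sum(.data$servings_per_day * .data$cho_per_serving),
    .groups = "drop"
  )
  per_person$gi <- ifelse(per_person$cho_ffq > 0,
                          100 * per_person$gl_g_d / per_person$cho_ffq,
                          NA_real_)
  idx <- match(base$participant_id, per_person$participant_id)
  base$gl_g_d <- per_person$gl_g_d[idx]
  base$gi <- per_person$gi[idx]
  base
}

#' Write a pipeline report as delimited text
#'
#' One tab-separated file per table plus the manifest, written
#' deterministically (fixed column order, full precision).
#'
#' @param report A `glycohort_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- c("flow_log", "descriptives", "adjusted_means", "odds_ratios",
              "interactions", "crossclass", "manifest")
  paths <- vapply(tables, function(t) {
    p <- file.path(dir, paste0(t, ".tsv"))
    readr::write_tsv(report[[t]], p)
    p
  }, character(1))
  invisible(paths)
}
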