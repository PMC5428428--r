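#' Food composition and glycemic index reference tables
#'
#' A food table is a tibble with one row per food and the columns
#' `food_id`, `name`, `cho_per_100g`, `fiber_per_100g`, `protein_per_100g`,
#' `fat_per_100g`, `is_cereal`, `gi`, `match_id` and `ingredients`.
#' `gi` is on the glucose = 100 scale and may be missing; `match_id` points at
#' a close-match food whose published GI is borrowed; `ingredients` encodes a
#' recipe as `"id:grams;id:grams"` (grams per 100 g of the recipe food).
#' Energy (`kcal_per_100g`) is derived as 4/4/9 kcal per gram of
#' carbohydrate/protein/fat.
#'
#' @name food-tables
NULL

FOOD_TABLE_COLUMNS <- c(
  "food_id", "name", "cho_per_100g", "fiber_per_100g", "protein_per_100g",
  "fat_per_100g", "is_cereal", "gi", "match_id", "ingredients"
)

# Recipe mass tolerance: ingredient grams may sum to up to 105 g per 100 g of
# recipe, absorbing water loss during cooking.
RECIPE_MASS_TOLERANCE <- 0.05

# Carbohydrate threshold below which a food is assigned GI 0 outright.
ZERO_RULE_CHO_CUTOFF <- 5

finalize_food_table <- function(tab) {
  tab$kcal_per_100g <- 4 * (tab$cho_per_100g + tab$protein_per_100g) +
    9 * tab$fat_per_100g
  check_food_table(tab)
  tab
}

check_food_table <- function(tab) {
  dup <- tab$food_id[duplicated(tab$food_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate food_id in food table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- which(!is.na(tab$fiber_per_100g) & tab$fiber_per_100g > 100)
  if (length(bad) > 0) {
    abort(paste0("fiber_per_100g above 100 g in rows: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(tab)
}

#' Read a food composition table from delimited text
#'
#' Accepts comma- or tab-delimited UTF-8 text with a header row matching the
#' documented schema (see [food-tables]). Rows with unparseable numeric fields
#' are rejected with their row numbers; duplicated `food_id`s raise an
#' integrity error.
#'
#' @param path Path to the delimited file.
#' @return A tibble of foods with a derived `kcal_per_100g` column.
#' @export
load_food_table <- function(path) {
  if (!file.exists(path)) abort(paste0("food table not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE
  )
  missing_cols <- setdiff(FOOD_TABLE_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("food table is missing mandatory columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  num_cols <- c("cho_per_100g", "fiber_per_100g", "protein_per_100g",
                "fat_per_100g", "gi")
  for (col in num_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(parsed))
    if (length(bad) > 0) {
      abort(paste0("unparseable numeric value in column '", col,
                   "', data row(s): ", paste(bad, collapse = ", ")))
    }
    raw[[col]] <- parsed
  }
  raw$is_cereal <- tolower(raw$is_cereal) %in% c("true", "t", "1", "yes")
  finalize_food_table(raw)
}

#' Write a food table to tab-delimited text
#'
#' @param tab A food table.
#' @param path Output path.
#' @export
write_food_table <- function(tab, path) {
  out <- tab[intersect(FOOD_TABLE_COLUMNS, names(tab))]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

parse_ingredients <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(NULL)
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  tibble::tibble(
    food_id = vapply(kv, `[[`, character(1), 1L),
    grams = as.numeric(vapply(kv, `[[`, character(1), 2L))
  )
}

#' Carbohydrate-weighted recipe GI
#'
#' The GI of a composite food is the carbohydrate-weighted mean of its
#' ingredients' GI values: sum(cho_i * gi_i) / sum(cho_i). The result always
#' lies between the smallest and largest ingredient GI.
#'
#' @param ingredients A data frame with columns `cho_grams` and `gi`.
#' @return A single GI value.
#' @export
recipe_gi <- function(ingredients) {
  cho <- ingredients$cho_grams
  gi <- ingredients$gi
  total <- sum(cho)
  if (!is.finite(total) || total <= 0) {
    abort("undefined GI: recipe contributes no carbohydrate")
  }
  sum(cho * gi) / total
}

#' Assign a glycemic index to one food
#'
#' Resolution follows a fixed tier order. A food with less than 5 g
#' carbohydrate per 100 g is assigned GI 0 (`zero_rule`) regardless of its
#' other fields. Otherwise a published value is used directly (`direct`), then
#' the published value of a declared close match (`close_match`), then the
#' carbohydrate-weighted mean over the recipe ingredients (`recipe`, resolved
#' iteratively to depth 5 with cycle detection). A carbohydrate-bearing food
#' that resolves through none of the tiers raises an error naming the food.
#'
#' @param food A single-row food table entry, or a `food_id` present in `table`.
#' @param table The food table used to resolve matches and ingredients.
#' @param .depth Internal recursion depth guard.
#' @param .seen Internal cycle-detection accumulator.
#' @return A one-row tibble with `food_id`, `gi`, `tier` and `source_note`.
#' @export
assign_gi <- function(food, table, .depth = 0L, .seen = character(0)) {
  if (is.character(food)) {
    idx <- match(food, table$food_id)
    if (is.na(idx)) abort(paste0("food not in table: ", food))
    food <- table[idx, ]
  }
  id <- food$food_id
  if (id %in% .seen) {
    abort(paste0("recipe cycle detected at food: ", id))
  }
  if (.depth > 5L) {
    abort(paste0("recipe nesting deeper than 5 at food: ", id))
  }
  result <- function(gi, tier, note) {
    tibble::tibble(food_id = id, gi = gi, tier = tier, source_note = note)
  }
  if (is.na(food$cho_per_100g)) {
    abort(paste0("cho_per_100g missing for food: ", id))
  }
  if (food$cho_per_100g < ZERO_RULE_CHO_CUTOFF) {
    return(result(0, "zero_rule",
                  sprintf("CHO %.1f g/100g below %g g cutoff",
                          food$cho_per_100g, ZERO_RULE_CHO_CUTOFF)))
  }
  if (!is.na(food$gi)) {
    return(result(food$gi, "direct", "published GI"))
  }
  if (!is.na(food$match_id) && nzchar(food$match_id)) {
    match <- assign_gi(food$match_id, table,
                       .depth = .depth + 1L, .seen = c(.seen, id))
    return(result(match$gi, "close_match",
                  paste0("GI of close match ", food$match_id)))
  }
  ing <- parse_ingredients(food$ingredients)
  if (!is.null(ing)) {
    if (sum(ing$grams) > 100 * (1 + RECIPE_MASS_TOLERANCE)) {
      abort(paste0("recipe ingredient mass exceeds tolerance for food: ", id))
    }
    resolved <- lapply(ing$food_id, assign_gi, table = table,
                       .depth = .depth + 1L, .seen = c(.seen, id))
    idx <- match(ing$food_id, table$food_id)
    if (anyNA(idx)) {
      abort(paste0("recipe ingredient not in table for food: ", id))
    }
    cho <- ing$grams * table$cho_per_100g[idx] / 100
    gi <- vapply(resolved, function(x) x$gi, numeric(1))
    return(result(recipe_gi(tibble::tibble(cho_grams = cho, gi = gi)),
                  "recipe", sprintf("%d-ingredient recipe", nrow(ing))))
  }
  abort(paste0("unresolved GI for carbohydrate-bearing food: ", id))
}

#' Assign GI values across a whole food table
#'
#' @param table A food table.
#' @return A tibble of GI assignments, one row per food.
#' @export
assign_gi_table <- function(table) {
  dplyr::bind_rows(lapply(seq_len(nrow(table)), function(i) {
    assign_gi(table[i, ], table)
  }))
}

#' Demonstration food catalog
#'
#' A small catalog of common South-Chinese staple foods with glucose-scale GI
#' values from published measurements: rice varieties spanning GI 42-83,
#' steamed bread (88), rice porridge (69), wheat noodles (46), mung-bean
#' noodles (39), black-rice porridge (42) and apple (28), plus low-carbohydrate
#' foods that fall under the zero rule, one close-match entry and one recipe
#' entry. Composition values (per 100 g edible portion, cooked where relevant)
#' are typical food-table magnitudes.
#'
#' @return A food table tibble.
#' @export
demo_food_catalog <- function() {
  tab <- tibble::tribble(
    ~food_id,        ~name,                       ~cho_per_100g, ~fiber_per_100g, ~protein_per_100g, ~fat_per_100g, ~is_cereal, ~gi, ~match_id, ~ingredients,
    "rice_sticky",   "sticky rice, cooked",             28.0, 1.2, 2.7, 0.3, TRUE,  83, NA, NA,
    "rice_jasmine",  "jasmine rice, cooked",            28.5, 1.1, 2.7, 0.3, TRUE,  78, NA, NA,
    "rice_longhi",   "high-GI long-grain rice, cooked", 28.0, 1.0, 2.6, 0.3, TRUE,  72, NA, NA,
    "steamed_bread", "steamed wheat bread",             48.0, 1.6, 8.0, 1.0, TRUE,  88, NA, NA,
    "rice_porridge", "rice porridge",                   12.0, 0.4, 1.1, 0.1, TRUE,  69, NA, NA,
    "rice_indica",   "indica rice, cooked",             28.0, 0.6, 2.6, 0.3, TRUE,  50, NA, NA,
    "rice_parboil",  "parboiled rice, cooked",          28.5, 0.7, 2.7, 0.3, TRUE,  64, NA, NA,
    "wheat_noodles", "wheat noodles, cooked",           25.0, 1.0, 4.5, 0.4, TRUE,  46, NA, NA,
    "mung_noodles",  "mung bean noodles, cooked",       22.0, 0.8, 0.2, 0.1, FALSE, 39, NA, NA,
    "black_porridge","black-rice porridge",             14.0, 0.6, 1.3, 0.2, TRUE,  42, NA, NA,
    "apple",         "apple, raw",                      13.0, 2.4, 0.3, 0.2, FALSE, 28, NA, NA,
    "rice_local",    "local high-GI rice, cooked",      28.5, 1.1, 2.7, 0.3, TRUE,  NA, "rice_jasmine", NA,
    "mixed_congee",  "rice and mung-bean congee",       16.0, 0.7, 1.4, 0.2, TRUE,  NA, NA, "rice_sticky:40;mung_noodles:35",
    "vegetables",    "leafy vegetables, cooked",         4.0, 1.8, 1.5, 0.2, FALSE, NA, NA, NA,
    "pork",          "pork, lean, cooked",               0.0, 0.0, 17.0, 28.0, FALSE, NA, NA, NA,
    "egg",           "hen egg, boiled",                  1.2, 0.0, 13.0, 10.0, FALSE, NA, NA, NA,
    "tofu",          "tofu, firm",                       2.0, 0.4, 8.0, 4.5, FALSE, NA, NA, NA,
    "oil",           "cooking oil",                      0.0, 0.0, 0.0, 100.0, FALSE, NA, NA, NA
  )
  finalize_food_table(tab)
}
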