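# FSA-NPS diet-quality scoring and the dietary derived variables:
# per-item nutrient-profiling scores, A-E quality classes, the
# energy-weighted diet index, per-meal quality profiles, excess fructose,
# the +/- 4 SD FODMAP outlier rule and the 800-4500 kcal plausibility filter.

#' Read an FSA-NPS point-attribution grid file
#'
#' The grid file has columns `component`, `role` (unfavorable/favorable),
#' `threshold`, `points`: a component's points are those of the highest
#' threshold its per-100 g value strictly exceeds (0 if none). Unfavorable
#' components (energy kJ, total sugars, saturated fat, sodium) award 0-10
#' points; favorable components (fibre, protein, fruit/veg %) award 0-5.
#'
#' @param path path to a grid csv; default: the packaged grids following the
#'   published point-attribution thresholds.
#' @return data.frame of class `fsanps_grids`.
#' @export
fsanps_read_grids <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("component", "role", "threshold", "points")
  if (!all(need %in% names(g)))
    stop("grid file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(g$role %in% c("unfavorable", "favorable")))
    stop("role must be unfavorable or favorable", call. = FALSE)
  for (comp in unique(g$component)) {
    gi <- g[g$component == comp, ]
    if (any(diff(gi$threshold) <= 0))
      stop("thresholds must be strictly increasing for ", comp, call. = FALSE)
    if (any(diff(gi$points) <= 0))
      stop("points must be increasing for ", comp, call. = FALSE)
    maxp <- if (gi$role[1] == "unfavorable") 10 else 5
    if (any(gi$points < 0 | gi$points > maxp))
      stop("points out of range for ", comp, call. = FALSE)
  }
  class(g) <- c("fsanps_grids", class(g))
  g
}

#' @rdname fsanps_read_grids
#' @export
fsanps_default_grids <- function() {
  path <- system.file("extdata", "fsanps_grids.csv", package = "dietmg")
  if (path == "") path <- file.path("inst", "extdata", "fsanps_grids.csv")
  fsanps_read_grids(path)
}

fsanps_points <- function(value, thresholds, points) {
  hit <- which(value > thresholds)
  if (length(hit) == 0) 0 else points[max(hit)]
}

#' FSA-NPS score of one food item
#'
#' Sum of unfavorable points (energy kJ, total sugars g, saturated fat g,
#' sodium mg; 0-10 each) minus favorable points (fibre g, protein g,
#' fruit/veg %; 0-5 each), all per 100 g. The theoretical range is -15
#' (most healthy) to +40 (least healthy).
#'
#' @param nutrients_per_100g named list/one-row data.frame with at least
#'   `energy_kj`, `sugar_g`, `satfat_g`, `sodium_mg`, `fiber_g`,
#'   `protein_g` (all >= 0).
#' @param fruit_veg_pct fruit/vegetable/legume/nut percentage (0-100); if
#'   `NULL`, taken from `nutrients_per_100g$fruitveg_pct`.
#' @param grids an `fsanps_grids` object.
#' @return integer score in \[-15, 40\].
#' @export
fsanps_item_score <- function(nutrients_per_100g, fruit_veg_pct = NULL,
                              grids = fsanps_default_grids()) {
  x <- as.list(nutrients_per_100g)
  if (is.null(fruit_veg_pct)) fruit_veg_pct <- x$fruitveg_pct
  x$fruitveg_pct <- fruit_veg_pct
  comps <- unique(grids$component)
  miss <- setdiff(comps, names(x))
  if (length(miss))
    stop("missing component(s): ", paste(miss, collapse = ", "), call. = FALSE)
  vals <- vapply(comps, function(cn) as.numeric(x[[cn]]), numeric(1))
  if (any(is.na(vals)) || any(vals < 0))
    stop("nutrient components must be nonnegative", call. = FALSE)
  score <- 0
  for (cn in comps) {
    gi <- grids[grids$component == cn, ]
    p <- fsanps_points(vals[[cn]], gi$threshold, gi$points)
    score <- score + if (gi$role[1] == "unfavorable") p else -p
  }
  as.integer(score)
}

#' FSA-NPS quality class (A-E)
#'
#' Items are classed A (high quality) to E (low quality): the first class
#' whose upper bound strictly exceeds the score, with bounds 1/2/5/9/40 for
#' drinks and 0/3/10/18/40 for all other foods. A score of exactly 40 is
#' class E.
#'
#' @param score integer FSA-NPS score in \[-15, 40\].
#' @param is_drink logical.
#' @return factor level in A-E.
#' @export
fsanps_class <- function(score, is_drink = FALSE) {
  stopifnot(length(score) == length(is_drink) || length(is_drink) == 1L)
  is_drink <- rep_len(is_drink, length(score))
  if (any(score < -15 | score > 40))
    stop("score out of the FSA-NPS range [-15, 40]", call. = FALSE)
  bounds_food <- c(0, 3, 10, 18, 40)
  bounds_drink <- c(1, 2, 5, 9, 40)
  cls <- vapply(seq_along(score), function(i) {
    b <- if (is_drink[i]) bounds_drink else bounds_food
    j <- which(score[i] < b)
    if (length(j) == 0) 5L else min(j)   # score == 40 -> E
  }, integer(1))
  factor(LETTERS[cls], levels = LETTERS[1:5])
}

#' Energy-weighted FSA-NPS diet index
#'
#' The diet index (DI) is the energy-weighted mean of the FSA-NPS scores of
#' all consumed portions: sum(energy_i * score_i) / sum(energy_i), where a
#' portion's energy is its per-100 g energy times grams/100. Higher DI means
#' poorer overall diet quality.
#'
#' @param diary data.frame with `item_id` and `grams`.
#' @param scores named numeric vector of per-item FSA-NPS scores.
#' @param energy_per_100g named numeric vector of per-item energy (per
#'   100 g; any fixed unit).
#' @return numeric scalar.
#' @export
fsanps_diet_index <- function(diary, scores, energy_per_100g) {
  miss <- setdiff(unique(diary$item_id), names(scores))
  if (length(miss))
    stop("no score for item(s): ", paste(miss, collapse = ", "), call. = FALSE)
  e <- energy_per_100g[diary$item_id] * diary$grams / 100
  s <- scores[diary$item_id]
  te <- sum(e)
  if (te <= 0) stop("total energy is zero", call. = FALSE)
  sum(e * s) / te
}

#' Per-meal food-quality profile
#'
#' Counts consumed items per FSA-NPS class within meals, yielding per-class
#' prevalence and a high/low quality ratio per subject. By default only main
#' meals (breakfast/lunch/dinner) enter; snacks are included with
#' `include_snacks = TRUE`. The ratio is (number of items in `high_classes`)
#' / (number in `low_classes`), A vs E by default.
#'
#' @param diary data.frame with `subject`, `is_main_meal`, `item_id`.
#' @param classes named factor/character of per-item classes (A-E).
#' @param include_snacks include non-main meals?
#' @param high_classes,low_classes class groupings for the ratio.
#' @return data.frame per subject: item counts per class, per-class
#'   prevalence, and `ratio_high_low` (Inf when no low-quality item).
#' @export
meal_quality_profile <- function(diary, classes, include_snacks = FALSE,
                                 high_classes = "A", low_classes = "E") {
  d <- if (include_snacks) diary else diary[diary$is_main_meal, , drop = FALSE]
  if (nrow(d) == 0) stop("no main meals in diary", call. = FALSE)
  miss <- setdiff(unique(d$item_id), names(classes))
  if (length(miss))
    stop("no class for item(s): ", paste(miss, collapse = ", "), call. = FALSE)
  cls <- factor(as.character(classes[d$item_id]), levels = LETTERS[1:5])
  tab <- table(d$subject, cls)
  out <- data.frame(subject = rownames(tab))
  for (k in LETTERS[1:5]) out[[paste0("n_", k)]] <- as.integer(tab[, k])
  tot <- rowSums(tab)
  for (k in LETTERS[1:5]) out[[paste0("prev_", k)]] <- as.numeric(tab[, k]) / tot
  hi <- rowSums(tab[, high_classes, drop = FALSE])
  lo <- rowSums(tab[, low_classes, drop = FALSE])
  out$ratio_high_low <- as.numeric(hi) / as.numeric(lo)
  rownames(out) <- NULL
  out
}

#' Excess fructose of a meal
#'
#' Glucose is total monosaccharides minus fructose; excess fructose is
#' fructose minus glucose, floored at zero (so a glucose-dominant meal has
#' excess fructose 0).
#'
#' @param fructose_g,monosacch_g per-meal totals (g); vectorised.
#' @return numeric vector of excess fructose (g).
#' @export
excess_fructose <- function(fructose_g, monosacch_g) {
  if (any(fructose_g < 0) || any(monosacch_g < 0))
    stop("negative input", call. = FALSE)
  if (any(fructose_g > monosacch_g))
    stop("fructose exceeds total monosaccharides", call. = FALSE)
  glucose <- monosacch_g - fructose_g
  pmax(fructose_g - glucose, 0)
}

#' Flag FODMAP intake outliers (mean +/- 4 SD rule)
#'
#' @param values per-subject intake values (n >= 3).
#' @return logical mask, TRUE = outlier. A zero-variance vector flags
#'   nothing.
#' @export
fodmap_outlier_mask <- function(values) {
  if (length(values) < 3) stop("need at least 3 values", call. = FALSE)
  m <- mean(values); s <- stats::sd(values)
  if (s == 0) return(rep(FALSE, length(values)))
  values < m - 4 * s | values > m + 4 * s
}

#' Exclude diaries with implausible mean daily energy
#'
#' Subjects whose 4-day mean daily energy intake is below 800 kcal or above
#' 4500 kcal are excluded (boundaries kept).
#'
#' @param diary diary table (`subject`, `day`, `item_id`, `grams`).
#' @param food_db food composition table with `energy_kcal` per 100 g.
#' @param lower,upper exclusion cutoffs in kcal/day.
#' @return list: `kept` (filtered diary) and `report` (subject, mean daily
#'   kcal, excluded flag, reason).
#' @export
filter_implausible_energy <- function(diary, food_db,
                                      lower = 800, upper = 4500) {
  kcal <- lookup_items(diary$item_id, food_db)$energy_kcal
  e <- diary$grams * kcal / 100
  per_day <- tapply(e, list(diary$subject, diary$day), sum, default = 0)
  mean_daily <- rowMeans(per_day, na.rm = TRUE)
  excl <- mean_daily < lower | mean_daily > upper
  report <- data.frame(subject = rownames(per_day),
                       mean_daily_kcal = as.numeric(mean_daily),
                       excluded = as.logical(excl),
                       reason = ifelse(mean_daily < lower, "below 800 kcal/day",
                                       ifelse(mean_daily > upper,
                                              "above 4500 kcal/day", "")))
  rownames(report) <- NULL
  kept <- diary[!diary$subject %in% report$subject[report$excluded], ,
                drop = FALSE]
  list(kept = kept, report = report)
}

lookup_items <- function(item_id, food_db) {
  i <- match(item_id, food_db$item_id)
  if (anyNA(i))
    stop("unknown item(s): ",
         paste(unique(item_id[is.na(i)]), collapse = ", "), call. = FALSE)
  food_db[i, , drop = FALSE]
}

#' Aggregate nutrient intake per meal, per day and as the 4-day mean
#'
#' All per-100 g nutrient columns of the food DB scale linearly with grams.
#'
#' @param diary diary table (`subject`, `day`, `meal`, `item_id`, `grams`).
#' @param food_db food composition table.
#' @param columns nutrient columns to aggregate; default: every numeric
#'   per-100 g column of `food_db`.
#' @return list of data.frames: `per_meal`, `per_day`, `mean_daily`.
#' @export
aggregate_intake <- function(diary, food_db, columns = NULL) {
  if (is.null(columns)) {
    num <- vapply(food_db, is.numeric, logical(1))
    columns <- setdiff(names(food_db)[num], "fruitveg_pct")
  }
  db <- lookup_items(diary$item_id, food_db)
  amounts <- as.matrix(db[, columns, drop = FALSE]) * diary$grams / 100
  key_meal <- interaction(diary$subject, diary$day, diary$meal, drop = TRUE)
  per_meal <- stats::aggregate(amounts,
                               by = list(subject = diary$subject, day = diary$day,
                                         meal = diary$meal), FUN = sum)
  per_day <- stats::aggregate(per_meal[, columns, drop = FALSE],
                              by = list(subject = per_meal$subject,
                                        day = per_meal$day), FUN = sum)
  mean_daily <- stats::aggregate(per_day[, columns, drop = FALSE],
                                 by = list(subject = per_day$subject), FUN = mean)
  list(per_meal = per_meal, per_day = per_day, mean_daily = mean_daily)
}
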