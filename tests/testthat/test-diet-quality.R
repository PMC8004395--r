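test_that("grid file validates and scores hit the theoretical extremes", {
  grids <- fsanps_default_grids()
  expect_s3_class(grids, "fsanps_grids")
  best <- list(energy_kj = 0, sugar_g = 0, satfat_g = 0, sodium_mg = 0,
               fiber_g = 100, protein_g = 100, fruitveg_pct = 100)
  worst <- list(energy_kj = 4000, sugar_g = 50, satfat_g = 20,
                sodium_mg = 1500, fiber_g = 0, protein_g = 0,
                fruitveg_pct = 0)
  expect_equal(fsanps_item_score(best, grids = grids), -15L)
  expect_equal(fsanps_item_score(worst, grids = grids), 40L)
  expect_error(fsanps_item_score(modifyList(best, list(sugar_g = -1)),
                                 grids = grids), "nonnegative")
  expect_error(fsanps_item_score(best[-1], grids = grids), "missing component")
})

test_that("a mid-grid case equals an independent threshold lookup", {
  # energy 1500 kJ -> 4, sugar 10 g -> 2, satfat 3.5 g -> 3, sodium 500 -> 5
  # fiber 2.5 -> 3, protein 7 -> 4, fruit/veg 70% -> 2 ; score = 14 - 9 = 5
  x <- list(energy_kj = 1500, sugar_g = 10, satfat_g = 3.5, sodium_mg = 500,
            fiber_g = 2.5, protein_g = 7, fruitveg_pct = 70)
  g <- fsanps_default_grids()
  lookup <- function(comp, v) {
    gi <- g[g$component == comp, ]
    hit <- gi$points[gi$threshold < v]
    if (length(hit)) max(hit) else 0
  }
  expected <- lookup("energy_kj", 1500) + lookup("sugar_g", 10) +
    lookup("satfat_g", 3.5) + lookup("sodium_mg", 500) -
    lookup("fiber_g", 2.5) - lookup("protein_g", 7) -
    lookup("fruitveg_pct", 70)
  expect_equal(expected, 5)
  expect_equal(fsanps_item_score(x, grids = g), 5L)
})

test_that("item scores stay within [-15, 40] over a randomized domain sweep", {
  g <- fsanps_default_grids()
  set.seed(99)
  for (i in 1:500) {
    x <- list(energy_kj = runif(1, 0, 4200), sugar_g = runif(1, 0, 60),
              satfat_g = runif(1, 0, 15), sodium_mg = runif(1, 0, 1200),
              fiber_g = runif(1, 0, 8), protein_g = runif(1, 0, 15),
              fruitveg_pct = runif(1, 0, 100))
    s <- fsanps_item_score(x, grids = g)
    expect_true(s >= -15 && s <= 40)
  }
})

test_that("class bounds follow the drink/food thresholds and are monotone", {
  expect_equal(as.character(fsanps_class(2L, is_drink = FALSE)), "B")
  expect_equal(as.character(fsanps_class(2L, is_drink = TRUE)), "C")
  expect_equal(as.character(fsanps_class(-15L, FALSE)), "A")
  expect_equal(as.character(fsanps_class(-15L, TRUE)), "A")
  expect_equal(as.character(fsanps_class(40L, FALSE)), "E")
  expect_error(fsanps_class(41L), "range")
  for (drink in c(TRUE, FALSE)) {
    cls <- as.integer(fsanps_class(-15:40, drink))
    expect_true(all(diff(cls) >= 0))
  }
})

test_that("diet index is the energy-weighted mean and split-invariant", {
  sc <- c(i1 = 4, i2 = 8, one = 3)
  en <- c(i1 = 300, i2 = 100, one = 200)
  expect_equal(fsanps_diet_index(diary_of("one", 100), sc, en), 3)
  two <- diary_of(c("i1", "i2"), c(100, 300))  # equal portion energy
  expect_equal(fsanps_diet_index(two, sc, en), 6)
  # energy-weight 3:1 with scores 4 and 8 -> 5
  d31 <- diary_of(c("i1", "i2"), c(100, 100))
  expect_equal(fsanps_diet_index(d31, sc, en), 5)
  split <- diary_of(c("i1", "i1", "i2"), c(50, 50, 100))
  expect_equal(fsanps_diet_index(split, sc, en),
               fsanps_diet_index(d31, sc, en))
  expect_error(fsanps_diet_index(diary_of("i1", 10), sc, c(i1 = 0)), "zero")
  expect_error(fsanps_diet_index(diary_of("zz", 10), sc, en), "zz")
})

test_that("meal quality profile counts classes and honours the snack flag", {
  cls <- setNames(factor(c("A", "A", "A", "A", "A", "E"),
                         levels = LETTERS[1:5]),
                  paste0("i", 1:6))
  main <- diary_of(paste0("i", 1:6), rep(100, 6))
  prof <- meal_quality_profile(main, cls)
  expect_equal(prof$n_A, 5L)
  expect_equal(prof$ratio_high_low, 5)
  allA <- diary_of(paste0("i", 1:5), rep(100, 5))
  profA <- meal_quality_profile(allA, cls)
  expect_equal(profA$prev_E, 0)
  expect_equal(profA$ratio_high_low, Inf)
  # snacks (all E) only enter with include_snacks = TRUE
  snack <- diary_of("i6", 50, meal = "snack1", is_main = FALSE)
  d <- rbind(allA, snack)
  expect_equal(meal_quality_profile(d, cls)$n_E, 0L)
  expect_equal(meal_quality_profile(d, cls, include_snacks = TRUE)$n_E, 1L)
  expect_error(meal_quality_profile(snack, cls), "no main meals")
})

test_that("excess fructose follows the glucose-dominance rule", {
  expect_equal(excess_fructose(3, 8), 0)   # glucose 5 > fructose
  expect_equal(excess_fructose(5, 8), 2)
  expect_equal(excess_fructose(4, 8), 0)   # fructose == glucose
  expect_equal(excess_fructose(c(3, 5), c(8, 8)), c(0, 2))
  expect_error(excess_fructose(9, 8), "exceeds")
  expect_error(excess_fructose(-1, 8), "negative")
})

test_that("the 4-SD outlier mask flags exactly the extreme values", {
  expect_false(any(fodmap_outlier_mask(rep(2, 10))))
  v <- c(rep(0, 20), 100)
  expect_equal(which(fodmap_outlier_mask(v)), 21L)
  sym <- c(rep(0, 50), -40, 40)
  m <- fodmap_outlier_mask(sym)
  expect_true(m[51] && m[52])
  expect_error(fodmap_outlier_mask(c(1, 2)), "at least 3")
})

test_that("energy plausibility filter uses the 800/4500 kcal cutoffs on 4-day means", {
  db <- data.frame(item_id = "x", level2 = "others", level3 = "sweets",
                   level4 = "candy", protein_g = 0, fat_g = 0, carb_g = 25,
                   fiber_g = 0, energy_kcal = 100, is_drink = FALSE)
  mk <- function(subject, grams) data.frame(subject = subject, day = rep(1:4, each = 1),
                                            meal = "lunch", is_main_meal = TRUE,
                                            item_id = "x", grams = grams)
  diary <- rbind(mk("low", 700), mk("edge", 800), mk("high", 5000),
                 mk("ok", 2000))
  out <- filter_implausible_energy(diary, db)
  rep <- out$report
  expect_true(rep$excluded[rep$subject == "low"])
  expect_false(rep$excluded[rep$subject == "edge"])   # rule is strictly below
  expect_true(rep$excluded[rep$subject == "high"])
  expect_false(rep$excluded[rep$subject == "ok"])
  expect_setequal(unique(out$kept$subject), c("edge", "ok"))
})

test_that("intake aggregation scales linearly and sums meals into days", {
  db <- data.frame(item_id = c("p", "q"), level2 = "others",
                   level3 = "composite", level4 = "mixed_dishes",
                   protein_g = c(10, 2), fat_g = c(1, 5), carb_g = c(0, 20),
                   fiber_g = 0, energy_kcal = c(49, 143), is_drink = FALSE)
  diary <- data.frame(subject = "s", day = c(1, 1, 1, 2),
                      meal = c("lunch", "lunch", "dinner", "lunch"),
                      is_main_meal = TRUE,
                      item_id = c("p", "q", "p", "q"),
                      grams = c(200, 100, 50, 100))
  agg <- aggregate_intake(diary, db)
  lunch1 <- agg$per_meal[agg$per_meal$day == 1 & agg$per_meal$meal == "lunch", ]
  expect_equal(lunch1$protein_g, 200 * 10 / 100 + 100 * 2 / 100)
  day1 <- agg$per_day[agg$per_day$day == 1, ]
  meals1 <- agg$per_meal[agg$per_meal$day == 1, ]
  expect_equal(day1$protein_g, sum(meals1$protein_g))
  expect_equal(agg$mean_daily$protein_g,
               mean(agg$per_day$protein_g))
  expect_error(aggregate_intake(diary_of("nope", 10), db), "nope")
})

test_that("worst-quality-quartile subjects eat more low-quality food in main meals", {
  db <- gen_food_db(120, 8, seed = 17)
  dd <- gen_diaries(db, 40, gradient_sd = 0.5, quality_sd = 1.5, seed = 17)
  grids <- fsanps_default_grids()
  scores <- setNames(vapply(seq_len(nrow(db)), function(i)
    fsanps_item_score(db[i, ], db$fruitveg_pct[i], grids), numeric(1)),
    db$item_id)
  classes <- setNames(fsanps_class(as.integer(scores), db$is_drink), db$item_id)
  prof <- meal_quality_profile(dd$diary, classes,
                               high_classes = c("A", "B"),
                               low_classes = c("D", "E"))
  lat <- dd$truth$subject_latents
  q <- lat$quality_score[match(prof$subject, lat$subject)]
  worst <- q >= quantile(q, 0.75); best <- q <= quantile(q, 0.25)
  low_prev <- prof$prev_D + prof$prev_E
  expect_gt(mean(low_prev[worst]), mean(low_prev[best]))
})
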