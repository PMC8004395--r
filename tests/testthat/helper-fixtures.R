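# Shared fixtures, built in code at test time.

# A minimal hand-made food DB whose tree topology is fully controlled:
# three items, two sharing a level-4 category with identical nutrients
# (so a k=1 DMM keeps them in one level-5 node), one in a different
# level-2 branch.
tiny_food_db <- function() {
  data.frame(
    item_id = c("a", "b", "c"),
    level2 = c("plant-based", "plant-based", "animal-based"),
    level3 = c("fruits", "fruits", "meat"),
    level4 = c("fresh_fruit", "fresh_fruit", "red_meat"),
    protein_g = c(1, 1, 20), fat_g = c(0.5, 0.5, 10),
    carb_g = c(12, 12, 0), fiber_g = c(2, 2, 0),
    sugar_g = c(10, 10, 0), satfat_g = c(0.1, 0.1, 4),
    sodium_mg = c(5, 5, 60), fruitveg_pct = c(100, 100, 0),
    fructose_g = c(4, 4, 0), monosacch_g = c(8, 8, 0),
    energy_kcal = c(60, 60, 170), energy_kj = c(251, 251, 711),
    is_drink = FALSE)
}

tiny_tree <- function() build_food_tree(tiny_food_db(), dmm_k_range = 1L, seed = 1L)

# Independent unweighted-UniFrac oracle: enumerate each profile's branch
# set from the item table by set operations (no matrix algebra).
unifrac_oracle <- function(items_present_p, items_present_q, tree) {
  it <- tree$items
  branch_set <- function(ids) {
    rows <- it[it$item_id %in% ids, ]
    unique(c(rows$node2, rows$node3, rows$node4, rows$node5, rows$item_id))
  }
  bp <- branch_set(items_present_p); bq <- branch_set(items_present_q)
  length(setdiff(union(bp, bq), intersect(bp, bq))) / length(union(bp, bq))
}

# One-subject diary from an item -> grams mapping.
diary_of <- function(items, grams, subject = "s1", meal = "lunch",
                     day = 1L, is_main = TRUE) {
  data.frame(subject = subject, day = day, meal = meal,
             is_main_meal = is_main, item_id = items, grams = grams)
}

# Exhaustive triangle-inequality violation count over all triples.
count_triangle_violations <- function(D, tol = 1e-9) {
  n <- nrow(D); bad <- 0L
  for (k in seq_len(n))
    bad <- bad + sum(D > outer(D[, k], D[k, ], `+`) + tol) / 2
  bad
}

well_separated_alpha <- function(J = 6, K = 3, high = 50, low = 5) {
  al <- matrix(low, K, J)
  for (k in seq_len(K)) al[k, k] <- high
  al
}
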