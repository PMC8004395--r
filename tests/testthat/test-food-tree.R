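test_that("tree structure: one leaf per item, >= 1 leaf per level-5 node", {
  db <- gen_food_db(80, 8, seed = 11)
  tree <- build_food_tree(db, seed = 1)
  expect_equal(nrow(tree$items), nrow(db))
  expect_setequal(tree$items$item_id, db$item_id)
  expect_true(all(table(tree$items$node5) >= 1))
  expect_gte(tree$n_level5, length(unique(db$level4)))
  # items with missing level-2 mapping are named in the error
  db2 <- db; db2$level2[3] <- NA
  expect_error(build_food_tree(db2, seed = 1), db$item_id[3])
})

test_that("a category with separated nutrient clusters is split into level-5 nodes", {
  # one level-4 category, three clearly distinct composition clusters
  n <- 18
  db <- data.frame(item_id = sprintf("it%02d", 1:n),
                   level2 = "animal-based", level3 = "dairy",
                   level4 = "cheese",
                   protein_g = 0, fat_g = 0, carb_g = 0, fiber_g = 0,
                   sugar_g = 0, satfat_g = 0, sodium_mg = 100,
                   fruitveg_pct = 0, fructose_g = 0, monosacch_g = 0,
                   energy_kcal = 100, energy_kj = 418, is_drink = FALSE)
  grp <- rep(1:3, each = 6)
  db$protein_g <- c(20, 30, 2)[grp] + rep(c(-0.5, 0.5), 9)
  db$fat_g <- c(35, 4, 1)[grp] + rep(c(-0.3, 0.3), 9)
  db$carb_g <- c(1, 2, 30)[grp] + rep(c(-0.2, 0.2), 9)
  db$fiber_g <- 0.1
  tree <- build_food_tree(db, dmm_k_range = 1:4, seed = 2)
  expect_equal(tree$n_level5, 3L)
  split_sizes <- table(tree$items$level5)
  expect_true(all(split_sizes == 6))
  # one-item category: exactly one level-5 child
  db1 <- db[1, ]; db1$level4 <- "whey"; db1$item_id <- "solo"
  tree1 <- build_food_tree(rbind(db, db1), dmm_k_range = 1:4, seed = 2)
  expect_equal(sum(grepl("whey", tree1$items$level5)), 1L)
})

test_that("unweighted UniFrac matches hand computation and the set oracle", {
  tree <- tiny_tree()
  p <- diet_profile(diary_of("a", 100), tree)
  q <- diet_profile(diary_of(c("a", "b"), c(50, 50), subject = "s2"), tree)
  r <- diet_profile(diary_of("c", 80, subject = "s3"), tree)
  # a and b share all four internal nodes; the unique branch is b's leaf
  expect_equal(unweighted_unifrac(p, q, tree), 1 / 6)
  expect_equal(unweighted_unifrac(p, q, tree), unifrac_oracle("a", c("a", "b"), tree))
  expect_equal(unweighted_unifrac(p, p, tree), 0)
  expect_equal(unweighted_unifrac(p, r, tree), 1)  # disjoint below root
  expect_equal(unweighted_unifrac(q, r, tree), unifrac_oracle(c("a", "b"), "c", tree))
  empty <- p; empty$presence[] <- FALSE
  expect_error(unweighted_unifrac(empty, empty, tree), "empty")
})

test_that("UniFrac agrees with the set oracle on random synthetic profiles", {
  db <- gen_food_db(60, 8, seed = 12)
  tree <- build_food_tree(db, seed = 3)
  set.seed(42)
  for (i in 1:10) {
    ids_p <- sample(db$item_id, sample(3:20, 1))
    ids_q <- sample(db$item_id, sample(3:20, 1))
    p <- structure(list(subject = "p",
                        presence = setNames(db$item_id %in% ids_p, db$item_id)),
                   class = "diet_profile")
    q <- structure(list(subject = "q",
                        presence = setNames(db$item_id %in% ids_q, db$item_id)),
                   class = "diet_profile")
    expect_equal(unweighted_unifrac(p, q, tree),
                 unifrac_oracle(ids_p, ids_q, tree))
  }
})

test_that("UniFrac agrees with picante on the exported tree", {
  db <- gen_food_db(40, 6, seed = 13)
  tree <- build_food_tree(db, seed = 4)
  dd <- gen_diaries(db, 6, seed = 13)
  D <- unifrac_matrix(dd$diary, tree)
  # dichotomise the multifurcating tree with zero-length edges: these carry
  # no branch length, so the unweighted metric is unchanged
  phy <- ape::multi2di(as_phylo_food_tree(tree), random = FALSE)
  subjects <- rownames(D)
  otu <- t(vapply(subjects, function(s) {
    as.numeric(db$item_id %in% dd$diary$item_id[dd$diary$subject == s])
  }, numeric(nrow(db))))
  colnames(otu) <- db$item_id
  D2 <- as.matrix(picante::unifrac(otu, phy))
  expect_equal(unname(D), unname(D2[subjects, subjects]), tolerance = 1e-10)
})

test_that("unifrac_matrix is a proper distance matrix and respects ordering", {
  db <- gen_food_db(50, 8, seed = 14)
  dd <- gen_diaries(db, 10, seed = 14)
  tree <- build_food_tree(db, seed = 5)
  D <- unifrac_matrix(dd$diary, tree)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(count_triangle_violations(D), 0)
  # permuting the subject order permutes the matrix
  subj <- rownames(D)
  D2 <- unifrac_matrix(dd$diary, tree, subjects = rev(subj))
  expect_equal(D2, D[rev(subj), rev(subj)])
  # a duplicated diary gives off-diagonal zero
  dup <- dd$diary[dd$diary$subject == subj[1], ]
  dup$subject <- "clone"
  D3 <- unifrac_matrix(rbind(dd$diary, dup), tree)
  expect_equal(D3[subj[1], "clone"], 0)
  expect_error(unifrac_matrix(dd$diary, tree, subjects = c("s", "s")),
               "duplicate")
})

test_that("meat/plant log2 ratio matches arithmetic and recovers the latent", {
  tree <- tiny_tree()
  expect_equal(meat_plant_log2ratio(diary_of("c", 100), tree, 1),
               log2(101 / 1))
  both <- diary_of(c("a", "c"), c(100, 100))
  expect_equal(meat_plant_log2ratio(both, tree, 1), 0)
  expect_error(meat_plant_log2ratio(diary_of("a", 10)[0, ], tree), "empty")
  db <- gen_food_db(100, 8, seed = 15)
  dd <- gen_diaries(db, 30, seed = 15)
  big <- build_food_tree(db, seed = 6)
  ratio <- vapply(unique(dd$diary$subject), function(s)
    meat_plant_log2ratio(dd$diary, big, subject = s), numeric(1))
  rho <- cor(ratio, dd$truth$subject_latents$meat_plant_score,
             method = "spearman")
  expect_gt(rho, 0.8)
})

test_that("newick export parses and preserves the leaf set", {
  tree <- build_food_tree(gen_food_db(30, 6, seed = 16), seed = 7)
  phy <- as_phylo_food_tree(tree)
  expect_s3_class(phy, "phylo")
  expect_setequal(phy$tip.label, tree$items$item_id)
  expect_true(all(phy$edge.length == tree$branch_length))
})
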