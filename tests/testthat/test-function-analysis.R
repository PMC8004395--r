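test_that("family aggregation renormalises per sample and recovers planted profiles", {
  counts <- matrix(c(6, 2, 2, 0,
                     3, 1, 4, 0), 4, 2,
                   dimnames = list(c("g1", "g2", "g3", "gx"), c("s1", "s2")))
  ann <- data.frame(gene = c("g1", "g2", "g3"),
                    family = c("F1", "F1", "F2"), universe = "cazy")
  tab <- aggregate_families(counts, ann, "cazy")
  expect_equal(rowSums(tab), c(s1 = 1, s2 = 1))
  expect_equal(tab["s1", "F1"], 0.8)
  expect_equal(tab["s2", "F2"], 0.5)
  one <- aggregate_families(counts, ann[ann$family == "F1", ])
  expect_true(all(one[, "F1"] == 1))
  expect_error(aggregate_families(counts, data.frame(gene = "zz", family = "F")),
               "no gene")
  ft <- gen_function_tables(n_samples = 60, seed = 31)
  agg <- aggregate_families(ft$gene_counts, ft$gene_map, "cazy")
  rho <- cor(as.numeric(agg), as.numeric(ft$cazy[, colnames(agg)]),
             method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("CAZotype partitioning recovers planted mixtures and is seed-stable", {
  al <- well_separated_alpha(J = 8, K = 3, high = 30)
  sim <- simulate_dmm(90, al, rep(1 / 3, 3), size = 2000, seed = 32)
  rel <- sim$counts / rowSums(sim$counts)
  rownames(rel) <- paste0("s", 1:90)
  cz <- cazotype_partition(rel, 1:4, seed = 2)
  expect_equal(cz$K, 3L)
  expect_gte(mclust::adjustedRandIndex(cz$labels, sim$labels), 0.9)
  cz2 <- cazotype_partition(rel, 1:4, seed = 2)
  expect_identical(cz$labels, cz2$labels)
  single <- simulate_dmm(60, rbind(rep(10, 8)), 1, size = 2000, seed = 33)
  rel1 <- single$counts / rowSums(single$counts)
  expect_equal(cazotype_partition(rel1, 1:3, seed = 3)$K, 1L)
})

test_that("partition association reproduces the hand chi-squared", {
  a <- rep(c("x", "y"), each = 10)
  b <- rep(c("p", "q"), each = 10)
  res <- cazotype_enterotype_assoc(a, b)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)
  expect_lt(res$p, 1e-4)
  expect_error(cazotype_enterotype_assoc(a, rep("p", 20)), "levels")
  expect_warning(cazotype_enterotype_assoc(c("x", "y", "x"), c("p", "q", "q")),
                 "expected cell")
})

test_that("the correlation network keeps exactly the strong cross pairs", {
  set.seed(34)
  n <- 60
  cazy <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("GH", 1:4)))
  hydro <- matrix(rnorm(n * 3), n, 3,
                  dimnames = list(NULL, c("FeFe_A3", "FeFe_B", "NiFe_1")))
  hydro[, "FeFe_A3"] <- cazy[, "GH1"]        # rho = 1 planted copy
  net <- correlation_network(cazy, hydro, threshold = 0.4)
  hit <- net$edges[net$edges$family_a == "GH1" & net$edges$family_b == "FeFe_A3", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$rho, 1)
  expect_equal(hit$sign, "+")
  # symmetric under swapping the input tables
  net2 <- correlation_network(hydro, cazy, threshold = 0.4)
  expect_setequal(paste(net$edges$family_a, net$edges$family_b),
                  paste(net2$edges$family_b, net2$edges$family_a))
  # constant columns are skipped with a warning
  cazy2 <- cbind(cazy, GHconst = 1)
  expect_warning(correlation_network(cazy2, hydro, 0.4), "constant")
  expect_error(correlation_network(cazy[1:5, ], hydro[1:5, ]), ">= 10")
  # independent tables rarely produce any edge
  edges <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    a <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("a", 1:5)))
    b <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("b", 1:5)))
    edges <- edges + (nrow(correlation_network(a, b, 0.4)$edges) > 0)
  }
  expect_lte(edges, 1)
})

test_that("LDA ranks a strongly shifted feature first with the right sign", {
  set.seed(35)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  lab <- rep(c("control", "severe"), each = n / 2)
  X[lab == "severe", 3] <- X[lab == "severe", 3] + 3
  sc <- lda_scores(X, lab, positive_class = "severe")
  expect_equal(sc$feature[1], "f3")
  expect_equal(sc$enriched_in[1], "severe")
  expect_gt(sc$score[1], 0)
  # null: no feature dominates strongly
  sc0 <- lda_scores(matrix(rnorm(n * 6), n, 6,
                           dimnames = list(NULL, paste0("f", 1:6))), lab)
  expect_lt(max(abs(sc0$score)), max(abs(sc$score)))
  # sign structure is invariant to feature rescaling
  X2 <- X; X2[, 3] <- X2[, 3] * 100; X2[, 1] <- X2[, 1] / 50
  sc2 <- lda_scores(X2, lab, positive_class = "severe")
  expect_equal(sc2$feature[1], "f3")
  expect_equal(sign(sc2$score[match(sc$feature, sc2$feature)]),
               sign(sc$score))
  lab8 <- rep(c("control", "severe"), 4)
  expect_error(lda_scores(X[1:8, ], lab8), ">= 5")
})

test_that("the packaged substrate map loads with the four broad categories", {
  m <- read_substrate_map()
  expect_true(all(m %in% c("animal carbohydrates", "plant cell wall",
                           "peptidoglycan", "other")))
  expect_gt(sum(m == "animal carbohydrates"), 5)
  expect_false(anyDuplicated(names(m)) > 0)
})
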