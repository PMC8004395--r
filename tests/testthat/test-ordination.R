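test_that("sqrt-JSD matches closed forms and is a metric", {
  a <- rbind(s1 = c(1, 2, 1), s2 = c(1, 2, 1))
  expect_equal(jsd_distance(a)["s1", "s2"], 0)
  disj <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(jsd_distance(disj, 1e-12)["x", "y"], sqrt(log(2)),
               tolerance = 1e-6)
  expect_error(jsd_distance(rbind(ok = c(1, 1), bad = c(0, 0))), "bad")
  set.seed(7)
  comp <- matrix(rgamma(30 * 8, 1), 30, 8,
                 dimnames = list(paste0("s", 1:30), NULL))
  D <- jsd_distance(comp)
  expect_true(isSymmetric(D))
  expect_equal(count_triangle_violations(D), 0)
})

test_that("PCoA recovers Euclidean configurations and orders axes", {
  line <- cbind(seq(0, 10, length.out = 12))
  D <- as.matrix(dist(line)); dimnames(D) <- list(1:12, 1:12)
  p <- pcoa(D)
  expect_equal(p$var_fraction[1], 1, tolerance = 1e-10)
  set.seed(8)
  pts <- matrix(rnorm(60), 30, 2)
  D2 <- as.matrix(dist(pts)); dimnames(D2) <- list(1:30, 1:30)
  p2 <- pcoa(D2)
  expect_true(all(diff(p2$eigenvalues) <= 1e-9))
  # Procrustes: recovered configuration matches up to rotation/translation
  pr <- vegan::procrustes(pts, p2$coords[, 1:2])
  expect_lt(sqrt(sum(pr$residuals^2)), 1e-8)
  expect_error(pcoa(D2[1:2, 1:2]), ">= 3")
})

test_that("out-of-sample PCoA projection is exact for training points", {
  set.seed(9)
  pts <- matrix(rnorm(50), 25, 2)
  D <- as.matrix(dist(pts)); dimnames(D) <- list(1:25, 1:25)
  p <- pcoa(D)
  proj <- pcoa_project(p, D[c(4, 9, 17), ])
  expect_equal(unname(proj), unname(p$coords[c(4, 9, 17), ]),
               tolerance = 1e-9)
  # a genuinely new point lands where its Euclidean position says: the
  # PCoA coordinates of Euclidean data are an affine image of the
  # original configuration, so the training-fitted affine map must send
  # the projected point back to its true position
  new <- matrix(c(0.3, -0.2), 1)
  dn <- sqrt(colSums((t(pts) - as.numeric(new))^2))
  pn <- pcoa_project(p, matrix(dn, 1))
  ax <- p$coords[, 1:2]
  map <- lm(pts ~ ax)
  recov <- cbind(1, pn[, 1:2, drop = FALSE]) %*% coef(map)
  expect_equal(as.numeric(recov), as.numeric(new), tolerance = 1e-6)
})

test_that("PERMANOVA yields R2 = 1 and minimal p on the degenerate construction", {
  n <- 12
  D <- matrix(1, n, n); D[1:6, 1:6] <- 0; D[7:12, 7:12] <- 0; diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:n), paste0("s", 1:n))
  res <- permanova(D, factor(rep(1:2, each = 6)), n_perm = 199, seed = 2)
  expect_gt(res$R2, 0.99)
  expect_equal(res$p, 1 / 200)
  expect_error(permanova(D, rep(1, n), 99), "constant")
  # duplicating the whole dataset leaves R2 unchanged
  D2 <- rbind(cbind(D, D), cbind(D, D))
  dimnames(D2) <- list(paste0("t", 1:(2 * n)), paste0("t", 1:(2 * n)))
  diag(D2) <- 0
  res2 <- permanova(D2, factor(rep(rep(1:2, each = 6), 2)), n_perm = 49,
                    seed = 2)
  expect_equal(res2$R2, res$R2, tolerance = 1e-10)
})

test_that("the PERMANOVA scan finds diet-coupled subspecies beating their parent", {
  db <- gen_food_db(100, 8, seed = 23)
  dd <- gen_diaries(db, 60, seed = 23)
  tree <- build_food_tree(db, seed = 8)
  D <- unifrac_matrix(dd$diary, tree)
  gm <- gen_msp_metagenome(60, 3, list(c(25, 25), c(25, 25), integer(0)),
                           seed = 23, truth = dd$truth, coupling = 0.8)
  ab <- msp_core_abundance(gm$counts, gm$catalog)
  calls <- call_subspecies(gm$counts, gm$catalog, n_boot = 10, seed = 9)
  sub <- subspecies_abundance(calls, ab)
  common <- rownames(D)
  det <- t(vapply(rownames(ab), function(m)
    as.numeric(common %in% calls[[m]]$detected), numeric(length(common))))
  node_ab <- rbind(ab[, common] * det, sub[, common])
  parent <- c(setNames(rep(NA_character_, nrow(ab)), rownames(ab)),
              setNames(sub("\\|.*$", "", rownames(sub)), rownames(sub)))
  scan <- permanova_scan(D, t(node_ab), parent, n_perm = 19, seed = 3)
  tab <- scan$table
  # the diet-coupled MSP has diet-neutral abundance but diet-driven
  # subspecies: at least one child node out-resolves its parent
  cm <- gm$truth$diet_coupled_msp
  kids <- tab$R2[tab$parent %in% cm]
  expect_gt(max(kids), tab$R2[tab$node == cm])
  expect_gt(max(kids), 0.02)
  expect_true(cm %in% unlist(scan$retained_lineages) ||
                any(grepl(cm, scan$retained_nodes)))
})

test_that("co-inertia RV hits its analytic anchors and rotation invariance", {
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3)
  expect_equal(coinertia(X, X, 3)$rv, 1, tolerance = 1e-12)
  Y <- matrix(rnorm(300), 100, 3)
  expect_lt(coinertia(X, Y, 3)$rv, 0.2)
  # orthogonal rotation of a block leaves RV unchanged
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  expect_equal(coinertia(X, Y %*% Q, 3)$rv, coinertia(X, Y, 3)$rv,
               tolerance = 1e-12)
  expect_error(coinertia(X[1:2, ], Y[1:2, ]), ">= 3")
  ci <- coinertia(X, X + matrix(rnorm(300, sd = 0.3), 100), 3)
  expect_true(all(diff(ci$singular_values) <= 1e-12))
  expect_equal(crossprod(ci$x_loadings), diag(3), tolerance = 1e-12)
})

test_that("single-block projection reproduces training scores exactly", {
  set.seed(12)
  X <- matrix(rnorm(200), 50, 4)
  Y <- X[, c(2, 1, 3, 4)] + matrix(rnorm(200, sd = 0.4), 50)
  ci <- coinertia(X, Y, 3)
  expect_equal(project_single_block(ci, X, "diet"), ci$x_scores)
  expect_equal(project_single_block(ci, Y, "microbiome"), ci$y_scores)
  expect_equal(as.numeric(project_single_block(ci, matrix(ci$x_center, 1), "x")),
               rep(0, 3))
  expect_error(project_single_block(ci, X[, 1:2], "x"), "axis-count")
})

test_that("pc regression is exact on noise-free responses and honours k limits", {
  set.seed(13)
  coords <- matrix(rnorm(200), 40, 5)
  y <- 2 * coords[, 1] - 1
  reg <- pc_regression(coords, y, k = 3)
  pred <- predict(reg, coords, y)
  expect_equal(pred$r, 1, tolerance = 1e-12)
  expect_equal(pred$predicted, y, tolerance = 1e-9)
  expect_error(pc_regression(coords, y, k = 6), "exceeds")
  expect_error(pc_regression(coords[1:4, ], y[1:4], k = 4), "<")
  # permuted response: held-out prediction shows no signal
  nonsig <- 0
  for (i in 1:100) {
    yp <- sample(y)
    regp <- pc_regression(coords[1:20, ], yp[1:20], k = 3)
    r <- predict(regp, coords[21:40, ], yp[21:40])
    nonsig <- nonsig + (r$p > 0.05)
  }
  expect_gte(nonsig, 90)
})

test_that("axis correlations report rho/p/q with NA for constants and BH matching p.adjust", {
  set.seed(14)
  ax <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("A1", "A2")))
  f <- data.frame(same = ax[, 1], const = 1, indep = rnorm(100))
  res <- axis_feature_correlations(f, ax)
  expect_equal(res$rho[res$feature == "same" & res$axis == "A1"], 1)
  expect_true(all(is.na(res$rho[res$feature == "const"])))
  expect_lt(abs(res$rho[res$feature == "indep" & res$axis == "A2"]), 0.3)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.8), "BH"),
               c(0.04, 0.04, 0.8 / 15, 0.8))
})
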