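# Ordination and two-table coupling: sqrt-JSD compositional distances,
# principal coordinate analysis with out-of-sample projection, PERMANOVA
# (vegan's adonis2 behind the module surface) including the per-taxon-node
# scan, co-inertia analysis with the RV coefficient, projection of
# single-block individuals, and principal component regression of clinical
# read-outs on co-inertia axes.

#' Square-root Jensen-Shannon divergence distance matrix
#'
#' Abundances are made positive with a pseudocount, normalised to
#' probabilities per sample, and d = sqrt(JSD) (natural logarithm) is
#' computed for every pair. sqrt(JSD) is a metric; two samples with
#' disjoint one-hot compositions approach sqrt(log 2).
#'
#' @param abundance samples x features nonnegative matrix.
#' @param pseudocount value replacing zeros before normalisation.
#' @return symmetric `DistanceMatrix`.
#' @export
jsd_distance <- function(abundance, pseudocount = 1e-9) {
  x <- as.matrix(abundance)
  if (any(rowSums(x) == 0)) {
    bad <- which(rowSums(x) == 0)
    lab <- if (!is.null(rownames(x))) rownames(x)[bad] else bad
    stop("all-zero sample(s): ", paste(lab, collapse = ", "), call. = FALSE)
  }
  x[x == 0] <- pseudocount
  p <- x / rowSums(x)
  n <- nrow(p)
  plogp <- rowSums(p * log(p))
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) {
    pm <- (p[rep(i, n - i), , drop = FALSE] + p[(i + 1L):n, , drop = FALSE]) / 2
    hm <- -rowSums(pm * log(pm))
    jsd <- hm + (plogp[i] + plogp[(i + 1L):n]) / 2
    d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- sqrt(pmax(jsd, 0))
  }
  check_dist_matrix(d, "sqrt-JSD matrix")
}

#' Principal coordinate analysis (classical MDS)
#'
#' Eigendecomposition of the double-centred Gram matrix of squared
#' distances. Variance fractions are computed over positive eigenvalues
#' only; axes are ordered by decreasing eigenvalue.
#'
#' @param dist a `DistanceMatrix` (n >= 3).
#' @param k number of axes to keep (default: all positive-eigenvalue axes).
#' @return object of class `pcoa_result`: `coords` (samples x axes),
#'   `eigenvalues` (positive), `var_fraction`, and the ingredients needed
#'   to project new samples (`dist_sq_rowmeans`, `dist_sq_mean`,
#'   `vectors`, `training_dist`).
#' @export
pcoa <- function(dist, k = NULL) {
  check_dist_matrix(dist)
  n <- nrow(dist)
  if (n < 3) stop("need >= 3 samples", call. = FALSE)
  d2 <- dist^2
  G <- -0.5 * (d2 - outer(rowMeans(d2), rep(1, n)) -
                 outer(rep(1, n), colMeans(d2)) + mean(d2))
  e <- eigen(G, symmetric = TRUE)
  pos <- which(e$values > 1e-9 * max(abs(e$values)))
  if (is.null(k)) k <- length(pos) else k <- min(k, length(pos))
  idx <- pos[seq_len(k)]
  coords <- e$vectors[, idx, drop = FALSE] %*% diag(sqrt(e$values[idx]), k)
  rownames(coords) <- rownames(dist)
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coords = coords,
                 eigenvalues = e$values[idx],
                 var_fraction = e$values[idx] / sum(e$values[pos]),
                 vectors = e$vectors[, idx, drop = FALSE],
                 dist_sq_rowmeans = rowMeans(d2),
                 dist_sq_mean = mean(d2),
                 n_train = n),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("PCoA:", x$n_train, "samples,", ncol(x$coords), "axes; first axes explain",
      paste(sprintf("%.1f%%", 100 * utils::head(x$var_fraction, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Project new samples onto a fitted PCoA (Gower's formula)
#'
#' Given each new sample's distances to every training sample, the new
#' coordinates are obtained by double-centring those squared distances
#' against the training Gram terms. Projecting a training sample through
#' its own training distances reproduces its coordinates.
#'
#' @param object a `pcoa_result`.
#' @param newdist new-samples x training-samples distance matrix.
#' @return new-samples x axes coordinate matrix.
#' @export
pcoa_project <- function(object, newdist) {
  newdist <- rbind(newdist)
  if (ncol(newdist) != object$n_train)
    stop("newdist must have one column per training sample", call. = FALSE)
  d2 <- newdist^2
  g <- -0.5 * (sweep(d2, 2L, object$dist_sq_rowmeans) -
                 rowMeans(d2) + object$dist_sq_mean)
  coords <- g %*% object$vectors %*% diag(1 / sqrt(object$eigenvalues),
                                          length(object$eigenvalues))
  colnames(coords) <- colnames(object$coords)
  rownames(coords) <- rownames(newdist)
  coords
}

#' PERMANOVA of a distance matrix on a covariate
#'
#' Permutational multivariate analysis of variance (pseudo-F from the
#' among/within partition of the squared distances), delegated to
#' `vegan::adonis2`. The permutation p-value is
#' (1 + #\{perm F >= observed F\}) / (1 + n_perm).
#'
#' @param dist a `DistanceMatrix`.
#' @param covariate grouping factor or numeric covariate (length n).
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutations.
#' @return list with `R2`, `F`, `p`.
#' @export
permanova <- function(dist, covariate, n_perm = 999L, seed = 1L) {
  check_dist_matrix(dist)
  if (length(unique(covariate)) < 2)
    stop("constant covariate", call. = FALSE)
  if (length(covariate) != nrow(dist))
    stop("covariate length must match the distance matrix", call. = FALSE)
  df <- data.frame(x = covariate)
  fit <- with_seed(seed,
                   vegan::adonis2(stats::as.dist(dist) ~ x, data = df,
                                  permutations = n_perm))
  list(R2 = fit$R2[1], F = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' PERMANOVA scan over a taxonomic node table
#'
#' For every node of a taxonomic tree (phylum down to subspecies), runs a
#' continuous-covariate PERMANOVA of the diet distance matrix on the node's
#' abundance and records the effect size R2. Lineages (root-to-leaf paths)
#' with at least one node exceeding `r2_threshold` are retained; no
#' significance filter is applied.
#'
#' @param dist diet `DistanceMatrix` (samples must match the abundance rows).
#' @param node_abundance samples x nodes abundance matrix.
#' @param node_parent named character vector: parent node id per node (NA
#'   for roots).
#' @param r2_threshold lineage retention threshold on R2 (default 0.02).
#' @param n_perm permutations for the per-node p-value (R2 itself is
#'   permutation-free).
#' @param seed integer seed.
#' @return list: `table` (node, parent, R2, p), `retained_lineages`
#'   (leaf-to-root paths with any node above threshold), `retained_nodes`.
#' @export
permanova_scan <- function(dist, node_abundance, node_parent,
                           r2_threshold = 0.02, n_perm = 99L, seed = 1L) {
  nodes <- colnames(node_abundance)
  res <- data.frame(node = nodes,
                    parent = unname(node_parent[nodes]),
                    R2 = NA_real_, p = NA_real_)
  for (i in seq_along(nodes)) {
    a <- node_abundance[, i]
    if (stats::sd(a) == 0) next
    fit <- permanova(dist, a, n_perm = n_perm, seed = child_seed(seed, i))
    res$R2[i] <- fit$R2
    res$p[i] <- fit$p
  }
  children <- split(res$node, res$parent)
  leaves <- setdiff(res$node, res$parent)
  lineage_of <- function(leaf) {
    path <- leaf
    while (!is.na(node_parent[path[1]]) &&
           node_parent[path[1]] %in% res$node)
      path <- c(node_parent[path[1]], path)
    path
  }
  lineages <- lapply(leaves, lineage_of)
  names(lineages) <- leaves
  keep <- vapply(lineages, function(p)
    any(res$R2[match(p, res$node)] > r2_threshold, na.rm = TRUE), logical(1))
  list(table = res,
       retained_lineages = lineages[keep],
       retained_nodes = unique(unlist(lineages[keep])))
}

#' Co-inertia analysis of two coordinate blocks
#'
#' Singular value decomposition of the uniform-weight cross-covariance of
#' the two centred coordinate sets (e.g. PCoA coordinates of the diet and
#' microbiome blocks over common subjects). The RV coefficient
#' trace(XtY YtX) / sqrt(trace((XtX)^2) trace((YtY)^2)) summarises the
#' global coupling in \[0, 1\].
#'
#' @param X,Y matched coordinate matrices (common subjects in rows, >= 3).
#' @param n_axes number of co-inertia axes retained (default 7).
#' @return object of class `coinertia_model`: `rv`, `singular_values`,
#'   `x_loadings`, `y_loadings` (orthonormal per block), `x_scores`,
#'   `y_scores`, `cov_fraction`, and the block centres.
#' @export
coinertia <- function(X, Y, n_axes = 7L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have matched rows", call. = FALSE)
  if (nrow(X) < 3) stop("need >= 3 common rows", call. = FALSE)
  n <- nrow(X)
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx); Yc <- sweep(Y, 2L, cy)
  C <- crossprod(Xc, Yc) / n
  sv <- svd(C)
  n_axes <- min(n_axes, length(sv$d))
  Sx <- crossprod(Xc) / n; Sy <- crossprod(Yc) / n
  rv <- sum(diag(C %*% t(C))) / sqrt(sum(Sx * Sx) * sum(Sy * Sy))
  x_scores <- Xc %*% sv$u[, seq_len(n_axes), drop = FALSE]
  y_scores <- Yc %*% sv$v[, seq_len(n_axes), drop = FALSE]
  colnames(x_scores) <- colnames(y_scores) <- paste0("A", seq_len(n_axes))
  structure(list(rv = rv,
                 singular_values = sv$d,
                 cov_fraction = sv$d^2 / sum(sv$d^2),
                 x_loadings = sv$u[, seq_len(n_axes), drop = FALSE],
                 y_loadings = sv$v[, seq_len(n_axes), drop = FALSE],
                 x_center = cx, y_center = cy,
                 x_scores = x_scores, y_scores = y_scores,
                 n_axes = n_axes),
            class = "coinertia_model")
}

#' @export
print.coinertia_model <- function(x, ...) {
  cat("co-inertia model: RV =", round(x$rv, 3), ";", x$n_axes,
      "axes accounting for",
      sprintf("%.0f%%", 100 * sum(x$cov_fraction[seq_len(x$n_axes)])),
      "of covariation\n")
  invisible(x)
}

#' Project individuals with a single data block onto co-inertia axes
#'
#' Individuals having only diet (or only microbiome) data are placed in the
#' common co-inertia space by centring their PCoA coordinates with the
#' training centres and applying that block's loadings. Training
#' individuals projected through their own block land exactly on their
#' training scores.
#'
#' @param model a `coinertia_model`.
#' @param pcoa_coords coordinates on the same PCoA axes used in training
#'   (new individuals: use [pcoa_project()] first).
#' @param block `"x"`/`"diet"` or `"y"`/`"microbiome"` (which loadings).
#' @return matrix of co-inertia coordinates.
#' @export
project_single_block <- function(model, pcoa_coords,
                                 block = c("x", "y", "diet", "microbiome")) {
  block <- match.arg(block)
  xside <- block %in% c("x", "diet")
  L <- if (xside) model$x_loadings else model$y_loadings
  ctr <- if (xside) model$x_center else model$y_center
  pcoa_coords <- rbind(pcoa_coords)
  if (ncol(pcoa_coords) != nrow(L))
    stop("axis-count mismatch: expected ", nrow(L), " PCoA axes", call. = FALSE)
  out <- sweep(pcoa_coords, 2L, ctr) %*% L
  colnames(out) <- paste0("A", seq_len(ncol(out)))
  out
}

#' Principal component regression on co-inertia axes
#'
#' Ordinary least squares of a numeric response (e.g. H2/CH4 ratio,
#' severity coded 1-4, meat/plant ratio) on the first k co-inertia
#' coordinates.
#'
#' @param coords training coordinates (rows = individuals).
#' @param y numeric response.
#' @param k number of leading axes used (default 5; must be < n).
#' @return object of class `pc_regression` with coefficients, fitted
#'   values and training Pearson r/p.
#' @export
pc_regression <- function(coords, y, k = 5L) {
  coords <- as.matrix(coords)
  if (k > ncol(coords)) stop("k exceeds available axes", call. = FALSE)
  if (k >= nrow(coords)) stop("k must be < number of training rows", call. = FALSE)
  X <- coords[, seq_len(k), drop = FALSE]
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  ct <- stats::cor.test(stats::fitted(fit), y)
  structure(list(fit = fit, k = k,
                 coefficients = stats::coef(fit),
                 train_r = unname(ct$estimate), train_p = ct$p.value),
            class = "pc_regression")
}

#' @rdname pc_regression
#' @param object a `pc_regression`.
#' @param newcoords test coordinates on the same axes.
#' @param newy optional observed test response; adds test Pearson r/p.
#' @param ... unused.
#' @export
predict.pc_regression <- function(object, newcoords, newy = NULL, ...) {
  newcoords <- rbind(as.matrix(newcoords))
  X <- newcoords[, seq_len(object$k), drop = FALSE]
  colnames(X) <- names(object$coefficients)[-1]
  yhat <- as.numeric(cbind(1, X) %*% object$coefficients)
  if (is.null(newy)) return(yhat)
  ct <- stats::cor.test(yhat, newy)
  list(predicted = yhat, r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman correlations of features with ordination axes
#'
#' Used to project food levels, clinical variables or taxa onto PCoA or
#' co-inertia axes. Constant features yield NA. p-values can be
#' Benjamini-Hochberg adjusted across the whole feature x axis table.
#'
#' @param features data.frame/matrix of features (rows matched to axes).
#' @param axes matrix of axis coordinates.
#' @param adjust apply BH adjustment (adds column `q`).
#' @return data.frame: feature, axis, rho, p (and q).
#' @export
axis_feature_correlations <- function(features, axes, adjust = TRUE) {
  features <- as.data.frame(features)
  axes <- as.matrix(axes)
  if (nrow(features) != nrow(axes))
    stop("features and axes must have matched rows", call. = FALSE)
  if (is.null(colnames(axes)))
    colnames(axes) <- paste0("axis", seq_len(ncol(axes)))
  grid <- expand.grid(feature = names(features), axis = colnames(axes),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    f <- features[[grid$feature[i]]]
    a <- axes[, grid$axis[i]]
    if (!is.numeric(f) || stats::sd(f, na.rm = TRUE) == 0 || all(is.na(f)))
      return(c(NA_real_, NA_real_))
    ct <- suppressWarnings(stats::cor.test(f, a, method = "spearman"))
    c(unname(ct$estimate), ct$p.value)
  })
  grid$rho <- vapply(res, `[`, numeric(1), 1L)
  grid$p <- vapply(res, `[`, numeric(1), 2L)
  if (adjust) grid$q <- stats::p.adjust(grid$p, method = "BH")
  grid
}
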