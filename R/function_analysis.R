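# Functional profiling: aggregation of gene abundances to CAZy families and
# hydrogenase metal-site groups, DMM CAZotype partitioning, the CAZy -
# hydrogenase Spearman correlation network, two-class linear discriminant
# scores for severe-vs-control, and the CAZotype x enterotype association.

#' Read a CAZy substrate-category map
#'
#' Maps CAZy families to broad glycan substrate categories (animal
#' carbohydrates, plant cell wall, peptidoglycan, other), as used to colour
#' the correlation network. A curated default ships with the package and is
#' meant to be edited/extended for a given catalog; synthetic runs use the
#' generator's own map instead.
#'
#' @param path csv with columns `family`, `category`; default: the packaged
#'   map.
#' @return named character vector: category per family.
#' @export
read_substrate_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cazy_substrate_categories.csv",
                        package = "dietmg")
    if (path == "")
      path <- file.path("inst", "extdata", "cazy_substrate_categories.csv")
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("family", "category") %in% names(m)))
    stop("substrate map needs columns family, category", call. = FALSE)
  stats::setNames(m$category, m$family)
}

#' Aggregate gene counts to functional families
#'
#' Sums counts per family within one annotation universe (e.g. CAZy
#' families, or hydrogenase groups) and renormalises per sample so rows sum
#' to 1. Unannotated genes are excluded.
#'
#' @param gene_counts genes x samples matrix.
#' @param annotation data.frame with columns `gene` and `family` (rows of
#'   other universes may be filtered by `universe`/`universe_col`).
#' @param universe optional value selecting rows of `annotation` by
#'   `universe_col`.
#' @param universe_col column of `annotation` holding the universe label.
#' @return samples x families relative-abundance matrix.
#' @export
aggregate_families <- function(gene_counts, annotation, universe = NULL,
                               universe_col = "universe") {
  ann <- as.data.frame(annotation)
  if (!is.null(universe) && universe_col %in% names(ann))
    ann <- ann[ann[[universe_col]] == universe, , drop = FALSE]
  ann <- ann[ann$gene %in% rownames(gene_counts), , drop = FALSE]
  if (nrow(ann) == 0) stop("annotation covers no gene in the matrix", call. = FALSE)
  fams <- sort(unique(ann$family))
  agg <- t(vapply(fams, function(f) {
    colSums(gene_counts[ann$gene[ann$family == f], , drop = FALSE])
  }, numeric(ncol(gene_counts))))
  tot <- colSums(agg)
  if (any(tot == 0)) {
    bad <- colnames(gene_counts)[tot == 0]
    stop("sample(s) with zero annotated counts: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  t(sweep(agg, 2L, tot, `/`))
}

#' CAZotype partitioning of samples (DMM on CAZy profiles)
#'
#' Converts CAZy relative abundances to pseudo-counts (x `scale`, rounded)
#' and reuses [fit_dmm()] with Laplace model selection; the selected
#' components are the CAZotypes.
#'
#' @param cazy samples x families relative-abundance matrix.
#' @param k_range candidate numbers of CAZotypes.
#' @param seed integer seed.
#' @param scale pseudo-count scale (default 1e4).
#' @return list: `labels` (named integer CAZotype per sample), `K`, `fit`
#'   (the underlying `dmm_fit`).
#' @export
cazotype_partition <- function(cazy, k_range = 1:5, seed = 1L, scale = 1e4) {
  counts <- round(as.matrix(cazy) * scale)
  fit <- fit_dmm(counts, k_range = k_range, seed = seed)
  list(labels = stats::setNames(fit$assignments, rownames(cazy)),
       K = fit$K, fit = fit)
}

#' Association between two sample partitions (Pearson chi-squared)
#'
#' E.g. CAZotypes x enterotypes. Uncorrected chi-squared on the
#' contingency table; warns when any expected cell is below 1.
#'
#' @param labels_a,labels_b matched label vectors (>= 2 levels each).
#' @return list with `statistic`, `df`, `p` and the contingency `table`.
#' @export
cazotype_enterotype_assoc <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must be matched", call. = FALSE)
  if (length(unique(labels_a)) < 2 || length(unique(labels_b)) < 2)
    stop("each partition needs >= 2 levels", call. = FALSE)
  tab <- table(labels_a, labels_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1))
    warning("expected cell count below 1; chi-squared may be unreliable")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab)
}

#' CAZy - hydrogenase Spearman correlation network
#'
#' All cross-table (optionally also within-table) Spearman correlations;
#' pairs with |rho| above the threshold become edges, keeping the sign.
#' Constant columns are skipped with a warning.
#'
#' @param cazy,hydro samples x families relative-abundance matrices with
#'   matched rows (>= 10 samples).
#' @param threshold absolute-rho edge threshold (default 0.4).
#' @param within include within-table edges too (default FALSE:
#'   CAZy-hydrogenase pairs only).
#' @return object of class `correlation_network`: data.frame of edges
#'   (`family_a`, `family_b`, `rho`, `sign`) plus the `threshold`.
#' @export
correlation_network <- function(cazy, hydro, threshold = 0.4,
                                within = FALSE) {
  if (nrow(cazy) != nrow(hydro))
    stop("tables must have matched samples", call. = FALSE)
  if (nrow(cazy) < 10) stop("need >= 10 samples", call. = FALSE)
  drop_const <- function(m, nm) {
    cst <- apply(m, 2L, stats::sd) == 0
    if (any(cst))
      warning("constant ", nm, " column(s) skipped: ",
              paste(colnames(m)[cst], collapse = ", "))
    m[, !cst, drop = FALSE]
  }
  cazy <- drop_const(cazy, "cazy"); hydro <- drop_const(hydro, "hydrogenase")
  rho <- suppressWarnings(stats::cor(cazy, hydro, method = "spearman"))
  idx <- which(abs(rho) > threshold, arr.ind = TRUE)
  edges <- data.frame(family_a = rownames(rho)[idx[, 1]],
                      family_b = colnames(rho)[idx[, 2]],
                      rho = rho[idx])
  if (within) {
    for (tab in list(cazy, hydro)) {
      r <- suppressWarnings(stats::cor(tab, method = "spearman"))
      r[lower.tri(r, diag = TRUE)] <- 0
      id2 <- which(abs(r) > threshold, arr.ind = TRUE)
      edges <- rbind(edges, data.frame(family_a = rownames(r)[id2[, 1]],
                                       family_b = colnames(r)[id2[, 2]],
                                       rho = r[id2]))
    }
  }
  edges$sign <- ifelse(edges$rho > 0, "+", "-")
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold = threshold),
            class = "correlation_network")
}

#' @export
print.correlation_network <- function(x, ...) {
  cat("correlation network:", nrow(x$edges), "edges at |rho| >",
      x$threshold, "\n")
  invisible(x)
}

#' Export a correlation network as an edge list file
#'
#' @param network a `correlation_network`.
#' @param path output file (tab-separated edge list).
#' @return invisibly, the path.
#' @export
write_network <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-feature linear discriminant scores (severe vs control)
#'
#' Two-class Fisher discriminant on standardised features: the discriminant
#' direction w solves (Sw + ridge I) w = m1 - m0 over the pooled
#' within-class scatter. Each feature's score is its |loading|, signed
#' towards the class in which the feature's mean is higher, and features
#' are ranked by score magnitude. A singular within-class scatter is
#' ridge-regularised with a warning. A log10-style display magnitude is
#' reported alongside the raw loadings.
#'
#' @param features samples x features numeric matrix/data.frame.
#' @param labels two-class factor/character (e.g. "severe"/"control"), each
#'   class with >= 5 samples.
#' @param positive_class class towards which positive signs point (default:
#'   the second sorted level).
#' @param ridge regularisation added when the scatter is singular.
#' @return data.frame sorted by decreasing score magnitude: feature,
#'   loading (raw discriminant coefficient), enriched_in, score,
#'   log10_magnitude.
#' @export
lda_scores <- function(features, labels, positive_class = NULL,
                       ridge = 1e-3) {
  X <- as.matrix(features)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must have exactly 2 classes", call. = FALSE)
  if (min(table(labels)) < 5)
    stop("each class needs >= 5 samples", call. = FALSE)
  if (is.null(positive_class)) positive_class <- lev[2]
  s <- apply(X, 2L, stats::sd)
  s[s == 0] <- 1
  Z <- scale(X, scale = s)
  g1 <- labels == positive_class
  m1 <- colMeans(Z[g1, , drop = FALSE]); m0 <- colMeans(Z[!g1, , drop = FALSE])
  Sw <- (crossprod(scale(Z[g1, , drop = FALSE], scale = FALSE)) +
           crossprod(scale(Z[!g1, , drop = FALSE], scale = FALSE))) /
    (nrow(Z) - 2)
  w <- tryCatch(solve(Sw, m1 - m0), error = function(e) {
    warning("singular within-class scatter; ridge-regularised")
    solve(Sw + diag(ridge, ncol(Sw)), m1 - m0)
  })
  enriched <- ifelse(m1 >= m0, positive_class, setdiff(lev, positive_class))
  score <- abs(w) * sign(m1 - m0)
  out <- data.frame(feature = colnames(X),
                    loading = w,
                    enriched_in = enriched,
                    score = score,
                    log10_magnitude = log10(1 + abs(score)))
  out <- out[order(-abs(out$score)), ]
  rownames(out) <- NULL
  out
}
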