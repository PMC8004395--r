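# MSP (metagenomic species pangenome) subspecies delineation: detection by
# median core coverage, accessory presence calls inside the core-coverage
# quantile band, Jaccard distances between samples, and bootstrapped
# partitioning around medoids with silhouette-selected k.

#' Per-sample MSP abundance from median core-gene coverage
#'
#' @param gene_counts genes x samples numeric matrix (coverage or counts).
#' @param catalog named list, one entry per MSP, each with character vectors
#'   `core` and `accessory` of gene ids.
#' @return MSP x sample abundance matrix (median core value per sample).
#'   MSPs with no core gene in the matrix are dropped with a warning.
#' @export
msp_core_abundance <- function(gene_counts, catalog) {
  keep <- vapply(catalog, function(m) any(m$core %in% rownames(gene_counts)),
                 logical(1))
  if (!all(keep)) {
    warning("MSP(s) with no core genes in the matrix omitted: ",
            paste(names(catalog)[!keep], collapse = ", "))
    catalog <- catalog[keep]
  }
  if (length(catalog) == 0) stop("no usable MSP in catalog", call. = FALSE)
  out <- t(vapply(catalog, function(m) {
    apply(gene_counts[intersect(m$core, rownames(gene_counts)), , drop = FALSE],
          2L, stats::median)
  }, numeric(ncol(gene_counts))))
  rownames(out) <- names(catalog)
  out
}

#' MSP detection rule
#'
#' An MSP is detected in a sample when the median coverage of its core
#' genes is strictly greater than 2.
#'
#' @param core_coverages numeric vector of core-gene coverages for one
#'   sample and MSP (>= 1 gene).
#' @param threshold detection threshold on the median (default 2).
#' @return logical scalar.
#' @export
detect_msp <- function(core_coverages, threshold = 2) {
  if (length(core_coverages) < 1) stop("no core genes", call. = FALSE)
  stats::median(core_coverages) > threshold
}

#' Accessory-gene presence calls from the core-coverage quantile band
#'
#' For one sample and MSP, the 2.5% and 97.5% quantiles of the core-gene
#' coverages define a band: accessory coverage inside the band is called
#' present (1), below it absent (0). Coverage above the band indicates a
#' multi-copy or conserved gene; by default it is still coded present
#' (the gene is evidently there), `above = "absent"` codes it 0 instead.
#' The calls are returned with a `multicopy` attribute flagging above-band
#' genes.
#'
#' @param accessory_coverages named numeric vector for one sample.
#' @param core_coverages core-gene coverages of the same sample/MSP.
#' @param q band quantiles (default c(0.025, 0.975)).
#' @param above handling of above-band coverage: "present" or "absent".
#' @return integer 0/1 vector with attribute `multicopy`.
#' @export
accessory_presence <- function(accessory_coverages, core_coverages,
                               q = c(0.025, 0.975),
                               above = c("present", "absent")) {
  above <- match.arg(above)
  band <- stats::quantile(core_coverages, q, names = FALSE)
  if (band[1] >= band[2]) {
    warning("degenerate core-coverage band; falling back to > 0 presence")
    call <- as.integer(accessory_coverages > 0)
    attr(call, "multicopy") <- rep(FALSE, length(call))
    return(call)
  }
  multi <- accessory_coverages > band[2]
  call <- as.integer(accessory_coverages >= band[1] & !multi)
  if (above == "present") call[multi] <- 1L
  attr(call, "multicopy") <- multi
  names(call) <- names(accessory_coverages)
  call
}

#' Accessory presence/absence matrix for one MSP
#'
#' Applies [detect_msp()] and [accessory_presence()] across samples: only
#' detected samples appear in the result.
#'
#' @param gene_counts genes x samples matrix.
#' @param msp one catalog entry (list with `core`, `accessory`).
#' @inheritParams accessory_presence
#' @param detection_threshold median core coverage above which the MSP is
#'   detected.
#' @return samples x accessory-genes binary matrix (possibly 0 rows), with
#'   attribute `band` (per-sample quantile bands).
#' @export
accessory_binary_matrix <- function(gene_counts, msp,
                                    q = c(0.025, 0.975),
                                    above = c("present", "absent"),
                                    detection_threshold = 2) {
  above <- match.arg(above)
  core <- gene_counts[intersect(msp$core, rownames(gene_counts)), , drop = FALSE]
  acc <- gene_counts[intersect(msp$accessory, rownames(gene_counts)), , drop = FALSE]
  det <- apply(core, 2L, detect_msp, threshold = detection_threshold)
  samples <- colnames(gene_counts)[det]
  out <- matrix(0L, length(samples), nrow(acc),
                dimnames = list(samples, rownames(acc)))
  bands <- matrix(NA_real_, length(samples), 2L,
                  dimnames = list(samples, c("q_low", "q_high")))
  for (i in seq_along(samples)) {
    s <- samples[i]
    call <- suppressWarnings(
      accessory_presence(acc[, s], core[, s], q = q, above = above))
    out[i, ] <- call
    bands[i, ] <- stats::quantile(core[, s], q, names = FALSE)
  }
  attr(out, "band") <- bands
  out
}

#' Jaccard distance between samples of a binary matrix
#'
#' d(A, B) = 1 - |A intersect B| / |A union B| over the presence sets of
#' two rows. A pair of all-absent rows is 0 with a warning.
#'
#' @param binary samples x genes 0/1 matrix (>= 2 rows).
#' @return symmetric `DistanceMatrix`.
#' @export
jaccard_distance <- function(binary) {
  if (nrow(binary) < 2) stop("need >= 2 samples", call. = FALSE)
  b <- (binary > 0) * 1
  inter <- b %*% t(b)
  tot <- rowSums(b)
  uni <- outer(tot, tot, `+`) - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("sample pair(s) with empty union; distance set to 0")
    d[uni == 0] <- 0
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(binary), rownames(binary))
  check_dist_matrix(d, "Jaccard matrix")
}

#' Partition samples into MSP subspecies (bootstrapped PAM)
#'
#' Partitioning around medoids is fitted on the full distance matrix for
#' k = 2..k_max; the k with the best mean silhouette width is selected,
#' unless that silhouette falls below `silhouette_floor`, in which case the
#' MSP is left unsplit (k = 1). Cluster stability is the mean Jaccard
#' agreement between each original cluster and its best-matching cluster
#' across `n_boot` refits on random subsets (fraction `subset_frac`, drawn
#' without replacement); clusters below `stability_threshold` are flagged.
#'
#' @param dist a `DistanceMatrix` (samples x samples).
#' @param k_max largest number of clusters tried (>= 2, < n samples).
#' @param n_boot bootstrap refits for stability (default 100).
#' @param subset_frac subset fraction per refit (default 2/3).
#' @param seed integer seed (bootstrap subsampling).
#' @param silhouette_floor below this best mean silhouette no split is made.
#' @param stability_threshold clusters below it are flagged unstable.
#' @return object of class `subspecies_partition`: `labels` (named, 1..k),
#'   `k`, `silhouette` (mean width per candidate k), `stability` (per
#'   cluster), `unstable` (logical per cluster).
#' @export
partition_subspecies <- function(dist, k_max = 6L, n_boot = 100L,
                                 subset_frac = 2 / 3, seed = 1L,
                                 silhouette_floor = 0.25,
                                 stability_threshold = 0.6) {
  check_dist_matrix(dist)
  n <- nrow(dist)
  if (k_max < 2) stop("k_max must be >= 2", call. = FALSE)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  k_max <- min(k_max, n - 1L)
  d <- stats::as.dist(dist)
  ks <- 2:k_max
  sil <- vapply(ks, function(k) {
    fit <- cluster::pam(d, k, diss = TRUE)
    fit$silinfo$avg.width
  }, numeric(1))
  names(sil) <- ks
  best <- ks[which.max(sil)]
  if (max(sil) < silhouette_floor) {
    labels <- stats::setNames(rep(1L, n), rownames(dist))
    return(structure(list(labels = labels, k = 1L, silhouette = sil,
                          stability = stats::setNames(1, "1"),
                          unstable = stats::setNames(FALSE, "1")),
                     class = "subspecies_partition"))
  }
  fit <- cluster::pam(d, best, diss = TRUE)
  labels <- stats::setNames(as.integer(fit$clustering), rownames(dist))

  m <- max(2L, floor(subset_frac * n))
  agree <- matrix(NA_real_, n_boot, best)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sort(sample.int(n, m))
      if (length(unique(labels[idx])) < 2) next
      sub <- tryCatch(
        cluster::pam(stats::as.dist(dist[idx, idx]), best, diss = TRUE),
        error = function(e) NULL)
      if (is.null(sub)) next
      for (cl in seq_len(best)) {
        orig <- which(labels[idx] == cl)
        if (length(orig) == 0) next
        jac <- vapply(seq_len(best), function(c2) {
          new <- which(sub$clustering == c2)
          length(intersect(orig, new)) / length(union(orig, new))
        }, numeric(1))
        agree[b, cl] <- max(jac)
      }
    }
  })
  stability <- colMeans(agree, na.rm = TRUE)
  names(stability) <- seq_len(best)
  structure(list(labels = labels, k = best, silhouette = sil,
                 stability = stability,
                 unstable = stability < stability_threshold),
            class = "subspecies_partition")
}

#' @export
print.subspecies_partition <- function(x, ...) {
  cat("subspecies partition: k =", x$k, "\n")
  cat("  mean silhouette by k:",
      paste(sprintf("k=%s %.3f", names(x$silhouette), x$silhouette),
            collapse = "; "), "\n")
  if (x$k > 1)
    cat("  cluster stability:", paste(round(x$stability, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Call subspecies for every MSP of a catalog
#'
#' Runs the full per-MSP chain (detection, accessory presence, Jaccard,
#' bootstrapped PAM). MSPs with fewer than `min_detected` detected samples
#' or no accessory genes are left unsplit.
#'
#' @inheritParams accessory_binary_matrix
#' @param catalog named list of MSP entries.
#' @param k_max,n_boot,subset_frac,seed,silhouette_floor passed to
#'   [partition_subspecies()].
#' @param min_detected minimum detected samples to attempt splitting.
#' @return named list per MSP: `partition` (or NULL), `detected` sample ids,
#'   `binary` matrix.
#' @export
call_subspecies <- function(gene_counts, catalog, k_max = 6L, n_boot = 100L,
                            subset_frac = 2 / 3, seed = 1L,
                            silhouette_floor = 0.25, min_detected = 10L,
                            q = c(0.025, 0.975), above = "present",
                            detection_threshold = 2) {
  out <- vector("list", length(catalog))
  names(out) <- names(catalog)
  for (m in names(catalog)) {
    bin <- accessory_binary_matrix(gene_counts, catalog[[m]], q = q,
                                   above = above,
                                   detection_threshold = detection_threshold)
    part <- NULL
    if (nrow(bin) >= min_detected && ncol(bin) > 0 &&
        nrow(bin) >= 4 && any(colSums(bin) > 0)) {
      d <- suppressWarnings(jaccard_distance(bin))
      part <- partition_subspecies(d, k_max = min(k_max, nrow(bin) - 1L),
                                   n_boot = n_boot, subset_frac = subset_frac,
                                   seed = child_seed(seed, match(m, names(catalog))),
                                   silhouette_floor = silhouette_floor)
    }
    out[[m]] <- list(partition = part, detected = rownames(bin), binary = bin)
  }
  out
}

#' Subspecies-level abundance table
#'
#' Attributes each sample's MSP abundance wholly to its assigned
#' subspecies; undetected samples get 0 everywhere; MSPs without a split
#' are carried as a single unassigned unit. Column sums over one MSP's
#' subspecies reproduce the MSP abundance for detected samples.
#'
#' @param calls result of [call_subspecies()].
#' @param core_abundance MSP x sample matrix from [msp_core_abundance()].
#' @return subspecies x sample matrix with rownames `msp|ssN` or
#'   `msp|unassigned`.
#' @export
subspecies_abundance <- function(calls, core_abundance) {
  samples <- colnames(core_abundance)
  rows <- list()
  for (m in names(calls)) {
    ab <- core_abundance[m, ]
    det <- calls[[m]]$detected
    part <- calls[[m]]$partition
    if (is.null(part) || part$k == 1L) {
      v <- ifelse(samples %in% det, ab, 0)
      rows[[paste0(m, "|unassigned")]] <- v
    } else {
      for (cl in seq_len(part$k)) {
        in_cl <- names(part$labels)[part$labels == cl]
        rows[[paste0(m, "|ss", cl)]] <-
          ifelse(samples %in% in_cl, ab, 0)
      }
    }
  }
  out <- do.call(rbind, rows)
  colnames(out) <- samples
  out
}

#' Gene richness of a sample
#'
#' @param gene_counts genes x samples matrix (counts >= 0).
#' @param sample sample id or index.
#' @return integer: number of genes with count > 0.
#' @export
gene_richness <- function(gene_counts, sample) {
  sum(gene_counts[, sample] > 0)
}
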