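#' Dirichlet multinomial mixture (DMM) fitting with Laplace model selection
#'
#' Fits a mixture of Dirichlet-multinomial components to a nonnegative
#' integer count table by expectation-maximisation, for each number of
#' components in `k_range`, and selects the number of components that
#' minimises a Laplace approximation to the negative log model evidence.
#' This is the community-typing model used both to split food categories
#' into nutrient subcategories of the food tree and to partition samples
#' into CAZotypes from CAZy family profiles.
#'
#' The M-step updates each component's Dirichlet parameters by a
#' responsibility-weighted fixed-point iteration; the E-step uses the exact
#' Dirichlet-multinomial marginal likelihood. After EM converges the
#' posterior mode is polished by BFGS under a weak Gamma(0.1, 0.1) prior on
#' each Dirichlet parameter (the conventional regularisation for this model
#' family) and a N(0, 2) prior on the softmax weight coordinates. The
#' Laplace score is
#' \deqn{-\log L(\hat\theta) - \log \pi(\hat\theta) - \tfrac{d}{2}\log(2\pi)
#'       + \tfrac12 \log\lvert H \rvert}
#' where \eqn{d} is the number of free parameters, \eqn{\theta} collects the
#' log Dirichlet parameters and the softmax-transformed mixture weights, and
#' \eqn{H} is the observed information of the log posterior at the mode
#' (finite differences of the analytic score function). Lower is better;
#' redundant components pay both their prior mass and their curvature.
#'
#' @param counts matrix of nonnegative integers, rows = observations,
#'   columns = features (nutrients, CAZy families, ...). Every row must have
#'   a positive total.
#' @param k_range integer vector of component numbers to fit. Values larger
#'   than `nrow(counts)` are skipped with a warning.
#' @param seed integer seed controlling initialisation.
#' @param n_init number of EM restarts per K; the best likelihood wins.
#' @param max_iter,tol EM stopping rule (absolute log-likelihood change).
#' @return an object of class `dmm_fit`: list with `K` (selected number of
#'   components), `alpha` (K x J Dirichlet parameters), `weights`,
#'   `assignments` (max-posterior component per row, ties broken towards the
#'   lowest index), `posterior`, `laplace` (named per-K score vector),
#'   `loglik`, and `fits` (per-K summaries).
#' @examples
#' x <- simulate_dmm(60, alpha = rbind(c(20, 2, 2), c(2, 20, 2)),
#'                   weights = c(0.5, 0.5), size = 100, seed = 1)
#' fit <- fit_dmm(x$counts, k_range = 1:3, seed = 1)
#' fit$K
#' @export
fit_dmm <- function(counts, k_range, seed = 1L, n_init = 2L,
                    max_iter = 150L, tol = 1e-4) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers", call. = FALSE)
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    bad <- which(rs == 0)
    lab <- if (!is.null(rownames(counts))) rownames(counts)[bad] else bad
    stop("all-zero row(s) in count table: ", paste(lab, collapse = ", "),
         call. = FALSE)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) stop("k_range must be nonempty", call. = FALSE)
  if (any(k_range < 1)) stop("k_range must be >= 1", call. = FALSE)
  n <- nrow(counts)
  if (any(k_range > n)) {
    warning("skipping K > number of rows (", n, "): ",
            paste(k_range[k_range > n], collapse = ", "))
    k_range <- k_range[k_range <= n]
    if (length(k_range) == 0) stop("no feasible K left in k_range", call. = FALSE)
  }

  fits <- vector("list", length(k_range))
  names(fits) <- as.character(k_range)
  for (i in seq_along(k_range)) {
    K <- k_range[i]
    best <- NULL
    for (init in seq_len(max(1L, if (K == 1L) 1L else n_init))) {
      f <- with_seed(child_seed(seed, K * 101L + init),
                     dmm_em(counts, K, max_iter = max_iter, tol = tol))
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    best <- dmm_map_polish(counts, best)
    best$laplace <- dmm_laplace(counts, best$alpha, best$weights)
    fits[[i]] <- best
  }
  lap <- vapply(fits, `[[`, numeric(1), "laplace")
  sel <- fits[[which.min(lap)]]
  structure(list(
    K = nrow(sel$alpha),
    alpha = sel$alpha,
    weights = sel$weights,
    assignments = sel$assignments,
    posterior = sel$posterior,
    loglik = sel$loglik,
    laplace = lap,
    fits = lapply(fits, function(f)
      f[c("loglik", "laplace", "weights")]),
    k_range = k_range
  ), class = "dmm_fit")
}

#' @export
print.dmm_fit <- function(x, ...) {
  cat("Dirichlet multinomial mixture fit\n")
  cat("  selected K:", x$K, "over candidates", paste(x$k_range, collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  Laplace scores:", paste(sprintf("K=%s %.1f", names(x$laplace), x$laplace),
                                 collapse = "; "), "\n")
  invisible(x)
}

# Dirichlet-multinomial log density of every row under every component,
# including the multinomial normalising constant (shared across components).
dmm_loglik_matrix <- function(counts, alpha) {
  n <- nrow(counts); K <- nrow(alpha); S <- rowSums(counts)
  const <- lgamma(S + 1) - rowSums(lgamma(counts + 1))
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    a <- alpha[k, ]; A <- sum(a)
    ll[, k] <- const + lgamma(A) - lgamma(A + S) +
      rowSums(lgamma(sweep(counts, 2L, a, `+`))) - sum(lgamma(a))
  }
  ll
}

# One EM run at fixed K. Initialisation: k-means on row proportions.
dmm_em <- function(counts, K, max_iter, tol) {
  n <- nrow(counts); J <- ncol(counts)
  prop <- counts / rowSums(counts)
  if (K == 1L) {
    z <- matrix(1, n, 1L)
  } else {
    km <- tryCatch(
      stats::kmeans(prop + matrix(stats::rnorm(n * J, sd = 1e-4), n, J),
                    centers = K, nstart = 3L, iter.max = 50L),
      error = function(e) NULL)
    cl <- if (is.null(km)) sample(rep_len(seq_len(K), n)) else km$cluster
    z <- matrix(1e-6, n, K)
    z[cbind(seq_len(n), cl)] <- 1
    z <- z / rowSums(z)
  }
  alpha <- matrix(0, K, J)
  for (k in seq_len(K)) {
    m <- colSums(z[, k] * prop) / sum(z[, k])
    alpha[k, ] <- pmax(m, 1e-4) * 10
  }
  weights <- colSums(z) / n
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    alpha <- dmm_mstep_alpha(counts, z, alpha)
    weights <- pmax(colSums(z) / n, 1e-12)
    weights <- weights / sum(weights)
    ll_ik <- dmm_loglik_matrix(counts, alpha)
    logw <- sweep(ll_ik, 2L, log(weights), `+`)
    ll <- sum(logsumexp_rows(logw))
    z <- softmax_rows(logw)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  post <- z
  assign <- apply(post, 1L, which.max)   # which.max: lowest index on ties
  list(alpha = alpha, weights = weights, loglik = ll,
       posterior = post, assignments = as.integer(assign))
}

# Responsibility-weighted fixed-point update of the Dirichlet parameters.
dmm_mstep_alpha <- function(counts, z, alpha, inner = 3L) {
  S <- rowSums(counts); K <- nrow(alpha)
  for (it in seq_len(inner)) {
    for (k in seq_len(K)) {
      a <- alpha[k, ]; A <- sum(a); w <- z[, k]
      num <- colSums(w * (digamma(sweep(counts, 2L, a, `+`)) -
                            rep(digamma(a), each = nrow(counts))))
      den <- sum(w * (digamma(S + A) - digamma(A)))
      if (den <= 0) next
      alpha[k, ] <- pmax(a * num / den, 1e-8)
    }
  }
  alpha
}

# Observed-data log-likelihood and its analytic gradient in the
# unconstrained parametrisation theta = (log alpha by row, eta_{1..K-1})
# with weights = softmax(c(eta, 0)).
dmm_unpack <- function(theta, K, J) {
  alpha <- matrix(exp(theta[seq_len(K * J)]), K, J, byrow = TRUE)
  if (K > 1L) {
    eta <- c(theta[K * J + seq_len(K - 1L)], 0)
    w <- exp(eta - max(eta)); w <- w / sum(w)
  } else w <- 1
  list(alpha = alpha, weights = w)
}

dmm_grad <- function(theta, counts, K, J) {
  p <- dmm_unpack(theta, K, J)
  alpha <- p$alpha; weights <- p$weights
  S <- rowSums(counts); n <- nrow(counts)
  ll_ik <- dmm_loglik_matrix(counts, alpha)
  logw <- sweep(ll_ik, 2L, log(weights), `+`)
  z <- softmax_rows(logw)
  g_alpha <- matrix(0, K, J)
  for (k in seq_len(K)) {
    a <- alpha[k, ]; A <- sum(a)
    d_a <- digamma(sweep(counts, 2L, a, `+`)) -
      rep(digamma(a), each = n) +
      (digamma(A) - digamma(A + S))      # recycled down columns
    g_alpha[k, ] <- colSums(z[, k] * d_a) * a   # chain rule to log alpha
  }
  g <- as.numeric(t(g_alpha))
  if (K > 1L) g <- c(g, colSums(z)[seq_len(K - 1L)] - n * weights[seq_len(K - 1L)])
  g
}

# Prior hyperparameters: Gamma(eta, nu) on each Dirichlet parameter
# (log density in lambda = log alpha coordinates, Jacobian included) and
# N(0, sd_eta) on each free softmax weight coordinate.
.dmm_eta <- 0.1
.dmm_nu <- 0.1
.dmm_sd_eta <- 2

dmm_log_prior <- function(theta, K, J) {
  lam <- theta[seq_len(K * J)]
  lp <- sum(.dmm_eta * log(.dmm_nu) - lgamma(.dmm_eta) +
              .dmm_eta * lam - .dmm_nu * exp(lam))
  if (K > 1L) {
    eta <- theta[K * J + seq_len(K - 1L)]
    lp <- lp + sum(stats::dnorm(eta, 0, .dmm_sd_eta, log = TRUE))
  }
  lp
}

dmm_prior_grad <- function(theta, K, J) {
  lam <- theta[seq_len(K * J)]
  g <- .dmm_eta - .dmm_nu * exp(lam)
  if (K > 1L) {
    eta <- theta[K * J + seq_len(K - 1L)]
    g <- c(g, -eta / .dmm_sd_eta^2)
  }
  g
}

dmm_pack <- function(alpha, weights) {
  K <- nrow(alpha)
  c(as.numeric(t(log(alpha))), if (K > 1L) log(weights[-K] / weights[K]))
}

# Polish the EM solution to the posterior mode of the penalized
# observed-data likelihood (BFGS with analytic gradient).
dmm_map_polish <- function(counts, fit, maxit = 100L) {
  K <- nrow(fit$alpha); J <- ncol(fit$alpha)
  theta0 <- dmm_pack(fit$alpha, fit$weights)
  obj <- function(th) {
    p <- dmm_unpack(th, K, J)
    ll <- sum(logsumexp_rows(sweep(dmm_loglik_matrix(counts, p$alpha),
                                   2L, log(p$weights), `+`)))
    -(ll + dmm_log_prior(th, K, J))
  }
  grad <- function(th) -(dmm_grad(th, counts, K, J) + dmm_prior_grad(th, K, J))
  opt <- stats::optim(theta0, obj, grad, method = "BFGS",
                      control = list(maxit = maxit))
  p <- dmm_unpack(opt$par, K, J)
  ll_ik <- dmm_loglik_matrix(counts, p$alpha)
  logw <- sweep(ll_ik, 2L, log(p$weights), `+`)
  post <- softmax_rows(logw)
  list(alpha = p$alpha, weights = p$weights,
       loglik = sum(logsumexp_rows(logw)),
       posterior = post,
       assignments = as.integer(apply(post, 1L, which.max)))
}

# Laplace approximation to the negative log evidence at the posterior mode.
dmm_laplace <- function(counts, alpha, weights, h = 1e-4) {
  K <- nrow(alpha); J <- ncol(alpha)
  theta <- dmm_pack(alpha, weights)
  d <- length(theta)
  pen_grad <- function(th) dmm_grad(th, counts, K, J) + dmm_prior_grad(th, K, J)
  H <- matrix(0, d, d)
  for (j in seq_len(d)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- -(pen_grad(tp) - pen_grad(tm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-8)
  ll_ik <- dmm_loglik_matrix(counts, alpha)
  ll <- sum(logsumexp_rows(sweep(ll_ik, 2L, log(weights), `+`)))
  -ll - dmm_log_prior(theta, K, J) - d / 2 * log(2 * pi) + 0.5 * sum(log(ev))
}

#' Simulate counts from a Dirichlet multinomial mixture
#'
#' Independent oracle companion of [fit_dmm()]: draws component labels from
#' `weights`, a composition from the component's Dirichlet, then multinomial
#' counts of the given size.
#'
#' @param n number of observations.
#' @param alpha K x J matrix of Dirichlet parameters.
#' @param weights mixture weights (length K, summing to 1).
#' @param size total count per observation (scalar or length-n vector).
#' @param seed integer seed.
#' @return list with `counts` (n x J) and `labels` (true components).
#' @export
simulate_dmm <- function(n, alpha, weights, size, seed = 1L) {
  alpha <- as.matrix(alpha)
  K <- nrow(alpha); J <- ncol(alpha)
  stopifnot(length(weights) == K, abs(sum(weights) - 1) < 1e-8)
  size <- rep_len(size, n)
  with_seed(seed, {
    labels <- sample.int(K, n, replace = TRUE, prob = weights)
    counts <- matrix(0L, n, J)
    for (i in seq_len(n)) {
      g <- stats::rgamma(J, shape = alpha[labels[i], ], rate = 1)
      p <- g / sum(g)
      counts[i, ] <- stats::rmultinom(1L, size[i], p)[, 1L]
    }
    list(counts = counts, labels = labels)
  })
}
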