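# One-dimensional Gaussian mixture decomposition by EM with BIC model
# selection, used to separate compensated from uncompensated expression
# ratio populations.

#' One-dimensional Gaussian mixture fit with BIC model choice
#'
#' Fits k-component univariate Gaussian mixtures by expectation-
#' maximization (convergence when the log-likelihood changes by less than
#' `tol`, at most `max_iter` iterations, variance floor `var_floor`), takes
#' the best of `n_init` random initializations per k, and chooses k by
#' minimal BIC = `-2 logL + (3k - 1) log n`.
#'
#' @param values Numeric vector (n >= 8 finite values).
#' @param k_set Candidate component counts (default 1:2).
#' @param n_init Random initializations per k (default 10).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations (default 500).
#' @param var_floor Lower bound on component variances (default 1e-6).
#' @return List with `k` (chosen), `weights`, `means`, `variances`,
#'   `loglik`, `bic` (named by k), `degenerate` (TRUE when the data are
#'   all equal; k is forced to 1 with a zero-variance flag), and
#'   `loglik_trace` of the winning fit.
#' @export
gmm_bic <- function(values, k_set = c(1L, 2L), n_init = 10L, tol = 1e-8,
                    max_iter = 500L, var_floor = 1e-6) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8L) stop("need at least 8 finite values")
  if (stats::sd(x) == 0) {
    return(list(k = 1L, weights = 1, means = mean(x), variances = 0,
                loglik = Inf, bic = stats::setNames(-Inf, "1"),
                degenerate = TRUE, loglik_trace = numeric(0)))
  }
  fits <- list()
  bics <- stats::setNames(rep(NA_real_, length(k_set)), k_set)
  for (k in k_set) {
    best <- NULL
    for (init in seq_len(n_init)) {
      fit <- em_1d(x, k, tol, max_iter, var_floor)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    fits[[as.character(k)]] <- best
    bics[as.character(k)] <- -2 * best$loglik + (3 * k - 1) * log(n)
  }
  kbest <- k_set[which.min(bics)]
  win <- fits[[as.character(kbest)]]
  list(k = kbest, weights = win$weights, means = win$means,
       variances = win$variances, loglik = win$loglik, bic = bics,
       degenerate = FALSE, loglik_trace = win$trace)
}

#' @noRd
em_1d <- function(x, k, tol, max_iter, var_floor) {
  n <- length(x)
  # random initialization: means from sampled points, common variance
  mu <- sample(x, k)
  v <- rep(stats::var(x), k)
  w <- rep(1 / k, k)
  ll_old <- -Inf
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sqrt(v[j])),
                   numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_ <- rowSums(dens)
    rowsum_[rowsum_ == 0] <- .Machine$double.xmin
    ll <- sum(log(rowsum_))
    trace <- c(trace, ll)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    r <- dens / rowsum_
    nk <- colSums(r)
    nk[nk == 0] <- .Machine$double.eps
    w <- nk / n
    mu <- colSums(r * x) / nk
    v <- pmax(colSums(r * (x - rep(mu, each = n))^2) / nk, var_floor)
  }
  ord <- order(mu)
  list(weights = w[ord], means = mu[ord], variances = v[ord],
       loglik = ll, trace = trace)
}
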