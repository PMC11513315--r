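#' Fit a univariate Gaussian mixture by expectation-maximization
#'
#' Standard EM for a K-component univariate Gaussian mixture, the intensity
#' model used to separate CSF, choroid plexus and ventricular wall inside
#' the lateral-ventricle mask. Initialization splits the sorted sample into
#' K contiguous equal-size chunks (`init = "quantile"`, default) or uses
#' k-means (`init = "kmeans"`, seeded). A variance floor of
#' `1e-6 * var(x)` is applied at every M-step; iteration stops when the
#' relative log-likelihood change drops below `tol` or after `max_iter`
#' iterations. Components are returned sorted by ascending mean.
#'
#' @param x Numeric sample (finite values, length >= 10 * K).
#' @param K Number of components (>= 1).
#' @param init `"quantile"` or `"kmeans"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param seed Optional seed; only consumed by the k-means initializer.
#' @return An object of class `gmm`: list with `K`, `weights`, `means`,
#'   `variances`, `loglik_trace` (per-iteration, non-decreasing),
#'   `converged`, `iterations`. For `K = 1` the closed form is returned:
#'   weight 1, the sample mean and the biased (divide-by-n) sample variance.
#' @export
fit_gmm_em <- function(x, K = 3L, init = c("quantile", "kmeans"),
                       tol = 1e-6, max_iter = 500L, seed = NULL) {
  init <- match.arg(init)
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("non-finite intensities in sample")
  n <- length(x)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (n < 10L * K) stop(sprintf("need >= %d observations for K = %d",
                                10L * K, K))
  if (length(unique(x)) < K)
    stop("K exceeds the number of distinct intensity values")

  if (K == 1L) {
    mu <- mean(x); v <- mean((x - mu)^2)
    return(structure(list(K = 1L, weights = 1, means = mu, variances = v,
                          loglik_trace = sum(stats::dnorm(x, mu, sqrt(v),
                                                          log = TRUE)),
                          converged = TRUE, iterations = 0L),
                     class = "gmm"))
  }

  var_floor <- 1e-6 * stats::var(x)
  if (var_floor == 0) var_floor <- 1e-12

  if (init == "quantile") {
    xs <- sort(x)
    chunk <- split(xs, cut(seq_len(n), K, labels = FALSE))
    mu <- vapply(chunk, mean, 0)
    v <- pmax(vapply(chunk, function(c) mean((c - mean(c))^2), 0), var_floor)
    w <- vapply(chunk, length, 0L) / n
  } else {
    if (!is.null(seed)) set.seed(seed)
    km <- stats::kmeans(x, centers = K, nstart = 5L)
    mu <- as.numeric(km$centers)
    v <- pmax(vapply(seq_len(K), function(k) {
      xi <- x[km$cluster == k]
      if (length(xi) > 1) mean((xi - mean(xi))^2) else var_floor
    }, 0), var_floor)
    w <- km$size / n
  }

  log_sum_exp_rows <- function(m) {
    mx <- do.call(pmax, as.data.frame(m))
    mx + log(rowSums(exp(m - mx)))
  }

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    logd <- vapply(seq_len(K), function(k)
      stats::dnorm(x, mu[k], sqrt(v[k]), log = TRUE) + log(w[k]),
      numeric(n))
    lse <- log_sum_exp_rows(logd)
    ll <- sum(lse)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) / (abs(ll) + .Machine$double.eps) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    resp <- exp(logd - lse)            # n x K responsibilities
    nk <- colSums(resp)
    nk[nk < .Machine$double.xmin] <- .Machine$double.xmin
    w <- nk / n
    mu <- colSums(resp * x) / nk
    v <- pmax(colSums(resp * (outer(x, mu, `-`)^2)) / nk, var_floor)
  }

  o <- order(mu)
  structure(list(K = K, weights = unname(w[o]), means = unname(mu[o]),
                 variances = unname(v[o]), loglik_trace = trace,
                 converged = converged, iterations = it),
            class = "gmm")
}

#' @export
print.gmm <- function(x, ...) {
  cat(sprintf("<gmm> K = %d, %s after %d iterations\n", x$K,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(data.frame(weight = round(x$weights, 4),
                   mean = signif(x$means, 6),
                   sd = signif(sqrt(x$variances), 6)))
  invisible(x)
}

#' Posterior component responsibilities under a fitted mixture
#' @param model A `gmm` object.
#' @param x Numeric values.
#' @return Matrix `length(x)` x `K` of posterior probabilities.
#' @export
gmm_posterior <- function(model, x) {
  logd <- vapply(seq_len(model$K), function(k)
    stats::dnorm(x, model$means[k], sqrt(model$variances[k]), log = TRUE) +
      log(model$weights[k]), numeric(length(x)))
  logd <- matrix(logd, nrow = length(x))
  mx <- apply(logd, 1, max)
  p <- exp(logd - mx)
  p / rowSums(p)
}

#' Maximum-a-posteriori component labels under a fitted mixture
#' @inheritParams gmm_posterior
#' @return Integer labels in `1..K` (components sorted by ascending mean).
#' @export
gmm_map <- function(model, x) {
  max.col(gmm_posterior(model, x), ties.method = "first")
}
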