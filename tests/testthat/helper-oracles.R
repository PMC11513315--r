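# Independent brute-force / quadrature oracles used to cross-check the
# statistical operations, and small shared fixtures.

# Welch statistic and Welch-Satterthwaite df straight from the formulas.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = oracle_t_p(t, df))
}

# Two-sided p by numerical integration of the t density (not pt()).
oracle_t_p <- function(t, df) {
  2 * stats::integrate(function(u) stats::dt(u, df), abs(t), Inf,
                       rel.tol = 1e-12)$value
}

# Pearson chi-square statistic from the textbook formula.
oracle_chisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  p <- stats::integrate(function(u) stats::dchisq(u, df), stat, Inf,
                        rel.tol = 1e-12)$value
  list(stat = stat, df = df, p = p)
}

# Pearson r from raw sums; p through the t transform + integration.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = oracle_t_p(t, n - 2))
}

# Dense grid search over (mean1, mean2, shared variance, weight) for a
# 2-component mixture log-likelihood; a lower bound the EM fit must beat.
oracle_gmm2_grid <- function(x, mean_grid, var_grid, w_grid) {
  best <- -Inf
  n <- length(x)
  for (v in var_grid) {
    D <- vapply(mean_grid, function(m) stats::dnorm(x, m, sqrt(v)),
                numeric(n))
    for (w in w_grid) {
      A <- w * D; B <- (1 - w) * D
      for (i in seq_along(mean_grid)) {
        lls <- colSums(log(A[, i] + B))
        m <- max(lls)
        if (m > best) best <- m
      }
    }
  }
  best
}

# Small, fast phantom used across segmentation tests.
small_phantom_spec <- function(seed = 1L, sds = c(3, 3, 3),
                               cp_fraction = 0.25, bias_amplitude = 0) {
  phantom_spec(cp_fraction = cp_fraction, bias_amplitude = bias_amplitude,
               class_params = list(csf = c(mean = 30, sd = sds[1]),
                                   cp = c(mean = 55, sd = sds[2]),
                                   wall = c(mean = 80, sd = sds[3])),
               seed = seed)
}

# Diagonal tensor volume helper: one constant diagonal everywhere.
uniform_tensor_volume <- function(shape, dxx, dyy, dzz, spacing = c(1, 1, 1)) {
  comp <- array(0, dim = c(shape, 6))
  comp[, , , 1] <- dxx; comp[, , , 4] <- dyy; comp[, , , 6] <- dzz
  tensor_volume(comp, spacing)
}

# Deterministic ESRD-like subtest score matrix with a given number of
# impaired subjects (two affected domains each) out of n.
scores_with_impaired <- function(n, n_impaired) {
  subtests <- cerad_subtests()
  m <- matrix(0, nrow = n, ncol = length(subtests),
              dimnames = list(NULL, subtests))
  if (n_impaired > 0) {
    m[seq_len(n_impaired), "verbal_fluency"] <- -2.0   # frontal/executive
    m[seq_len(n_impaired), "word_list_recall"] <- -1.6 # verbal memory
  }
  m
}
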