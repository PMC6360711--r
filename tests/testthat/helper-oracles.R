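# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (numerical integration, grid search) and never call
# the code paths they check.

# E[X_gm | X_gm + X_wm = y] and E[X_gm^2 | ...] for two independent
# Gaussians, by numerical integration on a fine grid over x_gm.
oracle_conditional_moments <- function(y, dm_gm, dm_wm, s_gm, s_wm,
                                       p_gm, p_wm, n_grid = 40001L) {
  mu_g <- p_gm * dm_gm
  mu_w <- p_wm * dm_wm
  sd_g <- sqrt(p_gm * s_gm)
  sd_w <- sqrt(p_wm * s_wm)
  # conditional density of x_gm given the sum is Gaussian-shaped; cover
  # both component supports generously
  lo <- min(mu_g, y - mu_w) - 10 * max(sd_g, sd_w)
  hi <- max(mu_g, y - mu_w) + 10 * max(sd_g, sd_w)
  xg <- seq(lo, hi, length.out = n_grid)
  wgt <- stats::dnorm(xg, mu_g, sd_g) * stats::dnorm(y - xg, mu_w, sd_w)
  wgt <- wgt / sum(wgt)
  m1 <- sum(xg * wgt)
  m2 <- sum(xg^2 * wgt)
  list(x_gm = m1, x_wm = y - m1, x2_gm = m2,
       x2_wm = y^2 - 2 * y * m1 + m2)
}

# The conditional expectation Q of the complete-data log likelihood for
# one tissue, as a function of candidate (dm, s), given E-step moments.
oracle_q_tissue <- function(dm, s, x1, x2, p) {
  -0.5 * sum(log(2 * pi * p * s) +
               (x2 - 2 * p * dm * x1 + (p * dm)^2) / (p * s))
}

# Maximize Q over (dm, s) for one tissue by iteratively refined grid
# search down to a 1e-3 grid spacing.
oracle_q_argmax <- function(x1, x2, p, dm_range, s_range) {
  best <- c(mean(dm_range), mean(s_range))
  width <- c(diff(dm_range), diff(s_range))
  lo <- c(dm_range[1], s_range[1])
  repeat {
    dm_grid <- seq(best[1] - width[1] / 2, best[1] + width[1] / 2,
                   length.out = 41)
    s_grid <- seq(max(best[2] - width[2] / 2, 1e-6),
                  best[2] + width[2] / 2, length.out = 41)
    qv <- outer(dm_grid, s_grid,
                Vectorize(function(d, s) oracle_q_tissue(d, s, x1, x2, p)))
    ix <- which(qv == max(qv), arr.ind = TRUE)[1, ]
    best <- c(dm_grid[ix[1]], s_grid[ix[2]])
    width <- width / 10
    if (all(width < 1e-3)) break
  }
  best
}

# per-voxel observed-data log likelihood, direct dnorm sum
oracle_loglik <- function(y, params, p_gm, p_wm) {
  mu <- p_gm * params$dm_gm + p_wm * params$dm_wm
  v <- p_gm * params$s_gm + p_wm * params$s_wm
  sum(stats::dnorm(y, mu, sqrt(v), log = TRUE))
}

# small shared phantom, built once per test run
phantom_cache <- new.env(parent = emptyenv())
small_phantom <- function() {
  if (is.null(phantom_cache$fr)) {
    phantom_cache$fr <- synth_fractions(c(32L, 36L, 32L), seed = 2)
    phantom_cache$truth <- build_truth_sim1(phantom_cache$fr)
  }
  list(fr = phantom_cache$fr, truth = phantom_cache$truth)
}
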