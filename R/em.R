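#' Per-voxel sufficient statistics of a measurement vector
#'
#' Sample mean and population variance (divisor T) of the T difference
#' measurements at one voxel. These are the only functions of the data the
#' mixed-voxel Gaussian model can identify: at an EM fixed point the
#' tissue-weighted parameter sums reproduce exactly these two numbers.
#'
#' @param y Numeric vector of at least 2 finite measurements.
#' @return List with elements `mean` and `variance`.
#' @export
voxel_sufficient_stats <- function(y) {
  if (length(y) < 2L) stop("need at least 2 measurements", call. = FALSE)
  if (!all(is.finite(y))) stop("measurements must be finite", call. = FALSE)
  m <- mean(y)
  list(mean = m, variance = mean((y - m)^2))
}

#' E-step: conditional moments of the latent tissue components
#'
#' Given current parameters, computes for every measurement the conditional
#' expectation of the GM and WM latent components and of their squares,
#' under the constraint that the components sum to the observation. The
#' observation's innovation against the model mean is split between tissues
#' in proportion to their variance contributions, and both tissues share a
#' single conditional variance.
#'
#' @param y Numeric vector of measurements (length T >= 1).
#' @param params A [voxel_params()] with current parameter values.
#' @param p_gm,p_wm Tissue proportions of the voxel, both > 0.
#' @return List of numeric length-T vectors `x_gm`, `x_wm`, `x2_gm`,
#'   `x2_wm` (first and second conditional moments).
#' @export
e_step <- function(y, params, p_gm, p_wm) {
  v_gm <- p_gm * params$s_gm
  v_wm <- p_wm * params$s_wm
  v_tot <- v_gm + v_wm
  if (!is.finite(v_tot) || v_tot <= 0) {
    stop("degenerate model: total component variance is not positive",
         call. = FALSE)
  }
  mu <- p_gm * params$dm_gm + p_wm * params$dm_wm
  innov <- y - mu
  x_gm <- p_gm * params$dm_gm + (v_gm / v_tot) * innov
  x_wm <- p_wm * params$dm_wm + (v_wm / v_tot) * innov
  cond_var <- v_gm * v_wm / v_tot
  list(x_gm = x_gm, x_wm = x_wm,
       x2_gm = x_gm^2 + cond_var,
       x2_wm = x_wm^2 + cond_var)
}

#' M-step: parameter update from conditional moments
#'
#' Updates the four voxel parameters from the E-step moments. The mean
#' updates divide the summed latent components by `T * p`. The variance
#' update references a mean iterate inside its quadratic form:
#' `"as_printed"` uses the previous iterate, `"joint_update"` the freshly
#' updated one (the exact maximizer of the conditional expectation, which
#' guarantees monotone ascent of the observed-data likelihood). Both
#' coincide at a fixed point.
#'
#' @param moments E-step output (list with `x_gm`, `x_wm`, `x2_gm`,
#'   `x2_wm`).
#' @param params_prev A [voxel_params()]: the previous iterate.
#' @param p_gm,p_wm Tissue proportions, both > 0.
#' @param variant `"as_printed"` or `"joint_update"`.
#' @param variance_floor Lower clamp for the updated variances.
#' @return A [voxel_params()] with the next iterate.
#' @export
m_step <- function(moments, params_prev, p_gm, p_wm,
                   variant = c("as_printed", "joint_update"),
                   variance_floor = 1e-8) {
  variant <- match.arg(variant)
  if (p_gm <= 0 || p_wm <= 0) {
    stop("m_step requires both tissue proportions > 0; ",
         "route pure voxels to fit_pure_voxel", call. = FALSE)
  }
  tt <- length(moments$x_gm)
  dm_gm_new <- sum(moments$x_gm) / (tt * p_gm)
  dm_wm_new <- sum(moments$x_wm) / (tt * p_wm)
  ref_gm <- if (variant == "as_printed") params_prev$dm_gm else dm_gm_new
  ref_wm <- if (variant == "as_printed") params_prev$dm_wm else dm_wm_new
  s_gm_new <- sum(moments$x2_gm - 2 * moments$x_gm * p_gm * ref_gm +
                    (p_gm * ref_gm)^2) / (tt * p_gm)
  s_wm_new <- sum(moments$x2_wm - 2 * moments$x_wm * p_wm * ref_wm +
                    (p_wm * ref_wm)^2) / (tt * p_wm)
  voxel_params(dm_gm_new, dm_wm_new,
               max(s_gm_new, variance_floor),
               max(s_wm_new, variance_floor))
}

#' Fit the mixed-voxel model at one voxel by EM
#'
#' Alternates [e_step()] and [m_step()] from the supplied initialization
#' until the configured stopping rule fires. Under `fixed_iterations`
#' exactly `max_iter` iterations are run; under `param_change` iteration
#' stops as soon as the largest absolute change across the four parameters
#' drops below `tol` (capped at `max_iter`).
#'
#' @param y Numeric vector of T >= 2 finite measurements.
#' @param p_gm,p_wm Tissue proportions, both > 0 (mixed voxel).
#' @param init A [voxel_params()] initialization with nonnegative variances.
#' @param config An [em_config()].
#' @return List with `params` (a [voxel_params()]), `n_iter`, `converged`
#'   (logical: parameter change below `tol` at the last transition).
#' @export
fit_voxel <- function(y, p_gm, p_wm, init, config = em_config()) {
  if (length(y) < 2L || !all(is.finite(y))) {
    stop("y must hold at least 2 finite measurements", call. = FALSE)
  }
  if (p_gm <= 0 && p_wm <= 0) stop("voxel outside mask", call. = FALSE)
  if (p_gm <= 0 || p_wm <= 0) {
    stop("fit_voxel needs a mixed voxel; use fit_pure_voxel", call. = FALSE)
  }
  cur <- voxel_params(init$dm_gm, init$dm_wm,
                      max(init$s_gm, config$variance_floor),
                      max(init$s_wm, config$variance_floor))
  delta <- Inf
  n <- 0L
  while (n < config$max_iter) {
    mom <- e_step(y, cur, p_gm, p_wm)
    nxt <- m_step(mom, cur, p_gm, p_wm, variant = config$m_step_variant,
                  variance_floor = config$variance_floor)
    delta <- max(abs(nxt$dm_gm - cur$dm_gm), abs(nxt$dm_wm - cur$dm_wm),
                 abs(nxt$s_gm - cur$s_gm), abs(nxt$s_wm - cur$s_wm))
    cur <- nxt
    n <- n + 1L
    if (config$stop_rule == "param_change" && delta < config$tol) break
  }
  list(params = cur, n_iter = n, converged = delta < config$tol)
}

#' Closed-form fit for a voxel containing a single tissue
#'
#' When one tissue's proportion is (effectively) zero, the mixture model
#' degenerates and the EM updates divide by zero. The single-tissue maximum
#' likelihood is available in closed form: `dm = mean(y) / p`,
#' `s = popvar(y) / p`. The absent tissue's parameters are returned as 0
#' and the variance floor, flagged via the `absent` attribute.
#'
#' @param y Numeric vector of T >= 2 finite measurements.
#' @param p_tissue Proportion of the present tissue, > 0.
#' @param tissue `"gm"` or `"wm"`: which tissue is present.
#' @param variance_floor Lower clamp for the fitted variance.
#' @return A [voxel_params()] with attribute `absent` naming the missing
#'   tissue.
#' @export
fit_pure_voxel <- function(y, p_tissue, tissue = c("gm", "wm"),
                           variance_floor = 1e-8) {
  tissue <- match.arg(tissue)
  if (p_tissue <= 0) stop("voxel outside mask", call. = FALSE)
  st <- voxel_sufficient_stats(y)
  dm <- st$mean / p_tissue
  s <- max(st$variance / p_tissue, variance_floor)
  out <- if (tissue == "gm") {
    voxel_params(dm, 0, s, variance_floor)
  } else {
    voxel_params(0, dm, variance_floor, s)
  }
  attr(out, "absent") <- if (tissue == "gm") "wm" else "gm"
  out
}

#' Observed-data Gaussian log-likelihood per voxel
#'
#' Evaluates, for every in-mask voxel, the log-likelihood of its T
#' measurements under the fitted model: each measurement is Gaussian with
#' mean `p_gm*dm_gm + p_wm*dm_wm` and variance `p_gm*s_gm + p_wm*s_wm`
#' (absent-tissue terms contribute zero). Used to verify EM ascent; the
#' estimator itself never needs it.
#'
#' @param series A [difference_series()].
#' @param fractions A [tissue_fraction_volume()].
#' @param maps A `param_maps` object defined on the mask.
#' @return 3D array of per-voxel log-likelihood, `NA` off the mask.
#' @export
compute_gaussian_loglik <- function(series, fractions, maps) {
  check_same_grid(series, fractions)
  idx <- which(fractions$mask)
  tt <- series$n_measurements
  ymat <- matrix(series$data, ncol = tt)[idx, , drop = FALSE]
  ybar <- rowMeans(ymat)
  yvar <- rowMeans(ymat^2) - ybar^2
  pg <- fractions$p_gm[idx]
  pw <- fractions$p_wm[idx]
  dg <- ifelse(is.na(maps$dm_gm[idx]), 0, maps$dm_gm[idx])
  dw <- ifelse(is.na(maps$dm_wm[idx]), 0, maps$dm_wm[idx])
  sg <- ifelse(is.na(maps$s_gm[idx]), 0, maps$s_gm[idx])
  sw <- ifelse(is.na(maps$s_wm[idx]), 0, maps$s_wm[idx])
  mu <- pg * dg + pw * dw
  v <- pg * sg + pw * sw
  if (any(v <= 0)) stop("degenerate model: nonpositive voxel variance",
                        call. = FALSE)
  ll <- -tt / 2 * log(2 * pi * v) - tt * (yvar + (ybar - mu)^2) / (2 * v)
  out <- array(NA_real_, dim = fractions$grid_shape)
  out[idx] <- ll
  out
}
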