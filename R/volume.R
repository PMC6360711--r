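#' Apply the probability mask to a tissue fraction volume
#'
#' Voxels where a tissue's probability falls below `threshold` have that
#' tissue treated as absent (proportion set to 0) for estimation; voxels
#' where both fall below leave the mask entirely. This reproduces the
#' standard preprocessing step of removing voxels with probabilities lower
#' than 0.1 before PV correction.
#'
#' @param fractions A [tissue_fraction_volume()].
#' @param threshold Probability threshold in `[0, 1)`; default 0.1.
#' @return A masked [tissue_fraction_volume()].
#' @export
apply_probability_mask <- function(fractions, threshold = 0.1) {
  stopifnot(inherits(fractions, "tissue_fraction_volume"))
  if (threshold < 0 || threshold >= 1) {
    stop("threshold must be in [0, 1)", call. = FALSE)
  }
  p_gm <- fractions$p_gm
  p_wm <- fractions$p_wm
  p_gm[p_gm < threshold] <- 0
  p_wm[p_wm < threshold] <- 0
  mask <- if (threshold > 0) {
    (p_gm >= threshold) | (p_wm >= threshold)
  } else {
    (p_gm + p_wm) > 0
  }
  tissue_fraction_volume(p_gm, p_wm,
                         voxel_size_mm = fractions$voxel_size_mm,
                         mask = mask)
}

# internal: per-voxel sufficient statistics over the mask, as vectors
mask_suff_stats <- function(series, fractions, idx) {
  tt <- series$n_measurements
  ymat <- matrix(series$data, ncol = tt)[idx, , drop = FALSE]
  if (!all(is.finite(ymat))) {
    stop("non-finite measurements inside the mask", call. = FALSE)
  }
  ybar <- rowMeans(ymat)
  list(ybar = ybar, yvar = rowMeans(ymat^2) - ybar^2, tt = tt)
}

#' Fit the mixed-voxel model over a whole volume
#'
#' Applies the EM estimator voxel by voxel: mixed voxels (both proportions
#' above `pure_tissue_threshold`) run the EM of [fit_voxel()]; voxels with
#' one tissue absent use the closed form of [fit_pure_voxel()]. Voxels are
#' independent, so the result does not depend on traversal order. The
#' implementation iterates all mixed voxels simultaneously on their
#' sufficient statistics, which is algebraically identical to the per-voxel
#' E/M recursion (every E-step moment is linear or quadratic in the
#' measurements, so the updates only ever touch the per-voxel mean and
#' population variance).
#'
#' @param series A [difference_series()].
#' @param fractions A masked [tissue_fraction_volume()].
#' @param init_maps A `param_maps` object holding the initialization
#'   (see [init_from_uncorrected()] and [init_from_lr()]).
#' @param config An [em_config()].
#' @return A `param_maps` object with fields `dm_gm`, `dm_wm`, `s_gm`,
#'   `s_wm`, `n_iter`, `converged`, defined on the mask (`NA` elsewhere and
#'   for absent tissues).
#' @export
fit_volume <- function(series, fractions, init_maps, config = em_config()) {
  check_same_grid(series, fractions)
  out <- new_param_maps(fractions$grid_shape)
  idx <- which(fractions$mask)
  if (length(idx) == 0L) return(out)
  ss <- mask_suff_stats(series, fractions, idx)
  pg <- fractions$p_gm[idx]
  pw <- fractions$p_wm[idx]
  thr <- config$pure_tissue_threshold
  floor_s <- config$variance_floor

  mixed <- pg > thr & pw > thr
  gm_only <- !mixed & pg > 0
  wm_only <- !mixed & pw > 0 & !gm_only

  # single-tissue closed forms
  if (any(gm_only)) {
    out$dm_gm[idx[gm_only]] <- ss$ybar[gm_only] / pg[gm_only]
    out$s_gm[idx[gm_only]] <- pmax(ss$yvar[gm_only] / pg[gm_only], floor_s)
    out$n_iter[idx[gm_only]] <- 0L
    out$converged[idx[gm_only]] <- TRUE
  }
  if (any(wm_only)) {
    out$dm_wm[idx[wm_only]] <- ss$ybar[wm_only] / pw[wm_only]
    out$s_wm[idx[wm_only]] <- pmax(ss$yvar[wm_only] / pw[wm_only], floor_s)
    out$n_iter[idx[wm_only]] <- 0L
    out$converged[idx[wm_only]] <- TRUE
  }
  if (!any(mixed)) return(out)

  mi <- idx[mixed]
  pgm <- pg[mixed]; pwm <- pw[mixed]
  ybar <- ss$ybar[mixed]; yvar <- ss$yvar[mixed]
  dg <- init_maps$dm_gm[mi]; dw <- init_maps$dm_wm[mi]
  sg <- pmax(init_maps$s_gm[mi], floor_s)
  sw <- pmax(init_maps$s_wm[mi], floor_s)
  if (anyNA(dg) || anyNA(dw) || anyNA(sg) || anyNA(sw)) {
    stop("init_maps must be defined on all mixed in-mask voxels",
         call. = FALSE)
  }
  as_printed <- config$m_step_variant == "as_printed"
  n_iter <- integer(length(mi))
  converged <- logical(length(mi))
  active <- seq_along(mi)

  for (n in seq_len(config$max_iter)) {
    a <- active
    v_gm <- pgm[a] * sg[a]
    v_wm <- pwm[a] * sw[a]
    v_tot <- v_gm + v_wm
    w <- v_gm / v_tot
    w2 <- v_wm / v_tot
    cond_var <- v_gm * v_wm / v_tot
    innov <- ybar[a] - (pgm[a] * dg[a] + pwm[a] * dw[a])
    xbar_g <- pgm[a] * dg[a] + w * innov
    xbar_w <- pwm[a] * dw[a] + w2 * innov
    dg_new <- xbar_g / pgm[a]
    dw_new <- xbar_w / pwm[a]
    ref_g <- if (as_printed) dg[a] else dg_new
    ref_w <- if (as_printed) dw[a] else dw_new
    # mean over t of (x2 - 2 x p ref + (p ref)^2), via
    # mean(x^2) = xbar^2 + w^2 * popvar(y)
    num_g <- xbar_g^2 + w^2 * yvar[a] + cond_var -
      2 * xbar_g * pgm[a] * ref_g + (pgm[a] * ref_g)^2
    num_w <- xbar_w^2 + w2^2 * yvar[a] + cond_var -
      2 * xbar_w * pwm[a] * ref_w + (pwm[a] * ref_w)^2
    sg_new <- pmax(num_g / pgm[a], floor_s)
    sw_new <- pmax(num_w / pwm[a], floor_s)
    delta <- pmax(abs(dg_new - dg[a]),
                  pmax(abs(dw_new - dw[a]),
                       pmax(abs(sg_new - sg[a]), abs(sw_new - sw[a]))))
    dg[a] <- dg_new; dw[a] <- dw_new; sg[a] <- sg_new; sw[a] <- sw_new
    n_iter[a] <- n
    if (config$stop_rule == "param_change") {
      done <- delta < config$tol
      converged[a[done]] <- TRUE
      active <- a[!done]
      if (length(active) == 0L) break
    } else {
      converged[a] <- delta < config$tol
    }
  }

  out$dm_gm[mi] <- dg; out$dm_wm[mi] <- dw
  out$s_gm[mi] <- sg; out$s_wm[mi] <- sw
  out$n_iter[mi] <- n_iter
  out$converged[mi] <- converged
  out
}

#' Initialize EM parameters from the uncorrected averaged image
#'
#' Computes the time-averaged difference image and initializes the GM / WM
#' magnetizations with the mean of that image over near-pure GM / WM
#' regions (probability at or above the purity cuts). The variance
#' parameters are initialized from the spatial variance of the same regions
#' divided by the region's mean tissue proportion, keeping the per-unit-
#' tissue variance dimensionally consistent with the model. All four values
#' are broadcast as spatially constant maps.
#'
#' @param series A [difference_series()].
#' @param fractions A masked [tissue_fraction_volume()].
#' @param gm_pure_cut,wm_pure_cut Purity cuts defining the "GM region" and
#'   "WM region"; default 0.9.
#' @return A `param_maps` object with constant `dm_*`, `s_*` on the mask.
#' @export
init_from_uncorrected <- function(series, fractions,
                                  gm_pure_cut = 0.9, wm_pure_cut = 0.9) {
  check_same_grid(series, fractions)
  avg <- rowMeans(matrix(series$data, ncol = series$n_measurements))
  dim(avg) <- fractions$grid_shape
  region_stats <- function(p, cut, label) {
    sel <- fractions$mask & p >= cut
    if (!any(sel)) {
      stop("no voxels with ", label, " probability >= ", cut,
           "; cannot initialize", call. = FALSE)
    }
    vals <- avg[sel]
    m <- mean(vals)
    v <- mean((vals - m)^2)
    list(dm = m, s = v / mean(p[sel]))
  }
  g <- region_stats(fractions$p_gm, gm_pure_cut, "GM")
  w <- region_stats(fractions$p_wm, wm_pure_cut, "WM")
  out <- new_param_maps(fractions$grid_shape)
  msk <- fractions$mask
  out$dm_gm[msk] <- g$dm; out$dm_wm[msk] <- w$dm
  out$s_gm[msk] <- g$s; out$s_wm[msk] <- w$s
  out
}

#' Convert fitted magnetizations to CBF maps
#'
#' Applies the calibration relation `cbf = p * F * dm / M0` per tissue.
#' `cbf_total` is the sum of the GM and WM contributions; `cbf_gm_pure`
#' is the per-unit-GM value `F_GM * dm_gm / M0` used by the ROI analyses.
#' Under the phantom convention (`F = 1`, `M0 = 1`) CBF equals the
#' difference magnetization numerically.
#'
#' @param maps A `param_maps` object.
#' @param fractions A masked [tissue_fraction_volume()].
#' @param calib A [calibration_constants()].
#' @return An object of class `cbf_maps` with fields `cbf_gm`, `cbf_wm`,
#'   `cbf_total`, `cbf_gm_pure` (3D arrays, `NA` off the mask).
#' @export
quantify_cbf <- function(maps, fractions, calib = calibration_constants()) {
  msk <- fractions$mask
  m0 <- calib$m0
  if (is.array(m0)) {
    if (!identical(dim(m0), fractions$grid_shape)) {
      stop("m0 grid shape mismatch", call. = FALSE)
    }
    if (any(m0[msk] <= 0)) stop("m0 must be positive on the mask", call. = FALSE)
  } else if (m0 <= 0) {
    stop("m0 must be positive", call. = FALSE)
  }
  gm_pure <- calib$f_gm * maps$dm_gm / m0
  wm_pure <- calib$f_wm * maps$dm_wm / m0
  cbf_gm <- fractions$p_gm * gm_pure
  cbf_wm <- fractions$p_wm * wm_pure
  # absent tissue contributes zero flow (its proportion is zero)
  cbf_gm[msk & is.na(cbf_gm)] <- 0
  cbf_wm[msk & is.na(cbf_wm)] <- 0
  cbf_gm[!msk] <- NA_real_
  cbf_wm[!msk] <- NA_real_
  total <- cbf_gm + cbf_wm
  gm_pure[!msk] <- NA_real_
  structure(
    list(cbf_gm = cbf_gm, cbf_wm = cbf_wm, cbf_total = total,
         cbf_gm_pure = gm_pure, grid_shape = fractions$grid_shape),
    class = "cbf_maps")
}
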