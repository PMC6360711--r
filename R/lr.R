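# Kernel-wise linear-regression PV correction (Asllani-style comparator).
# The model has no intercept: within a kernel the difference signal is
# p_gm * dm_gm + p_wm * dm_wm with locally constant dm's.

# moving sum along rows of a matrix, window i-h .. i+h truncated at edges
moving_sum_rows <- function(m, h) {
  n <- nrow(m)
  if (h == 0L || n == 1L) return(m)
  k <- ncol(m)
  csf <- matrix(cumsum(m), n, k)
  if (k > 1L) csf <- csf - rep(c(0, csf[n, -k]), each = n)
  hi <- pmin(seq_len(n) + h, n)
  lo <- seq_len(n) - h - 1L
  out <- csf[hi, , drop = FALSE]
  pos <- lo >= 1L
  if (any(pos)) {
    out[pos, ] <- out[pos, , drop = FALSE] - csf[lo[pos], , drop = FALSE]
  }
  out
}

# in-plane (x, y) box sum of a 3D array, window truncated at volume edges
box_sum_xy <- function(a, hx, hy) {
  d <- dim(a)
  m <- moving_sum_rows(matrix(a, d[1], d[2] * d[3]), hx)
  a1 <- array(m, d)
  ap <- aperm(a1, c(2L, 1L, 3L))
  m2 <- moving_sum_rows(matrix(ap, d[2], d[1] * d[3]), hy)
  aperm(array(m2, c(d[2], d[1], d[3])), c(2L, 1L, 3L))
}

# shared rank logic for the 2x2 normal equations; vectors in, vectors out
solve_normal_eq <- function(sgg, sgw, sww, sgy, swy, policy) {
  det <- sgg * sww - sgw^2
  scale <- sgg * sww
  full <- scale > 0 & det > 1e-10 * scale
  dg <- dw <- rep(NA_real_, length(sgg))
  if (any(full)) {
    dg[full] <- (sww[full] * sgy[full] - sgw[full] * swy[full]) / det[full]
    dw[full] <- (sgg[full] * swy[full] - sgw[full] * sgy[full]) / det[full]
  }
  def <- !full
  if (any(def)) {
    if (policy == "single_tissue_fallback") {
      gm_dom <- def & sgg >= sww & sgg > 0
      wm_dom <- def & !gm_dom & sww > 0
      dg[gm_dom] <- sgy[gm_dom] / sgg[gm_dom]
      dw[wm_dom] <- swy[wm_dom] / sww[wm_dom]
    } else {
      # minimum-norm solution of the rank-1 system: gram = s1 * v v'
      s1 <- sgg + sww
      ok <- def & s1 > 0
      if (any(ok)) {
        v1 <- ifelse(sgg[ok] >= sww[ok], sgg[ok], sgw[ok])
        v2 <- ifelse(sgg[ok] >= sww[ok], sgw[ok], sww[ok])
        nv <- sqrt(v1^2 + v2^2)
        v1 <- v1 / nv; v2 <- v2 / nv
        proj <- (v1 * sgy[ok] + v2 * swy[ok]) / s1[ok]
        dg[ok] <- v1 * proj
        dw[ok] <- v2 * proj
      }
    }
  }
  list(dm_gm = dg, dm_wm = dw)
}

#' Least-squares tissue separation within one kernel
#'
#' Solves `values ~ p_gm * dm_gm + p_wm * dm_wm` (no intercept) over the
#' in-mask voxels of one regression kernel. Rank-deficient designs (e.g. a
#' kernel containing a single pure tissue) are resolved per the configured
#' policy; too few voxels yield a missing result.
#'
#' @param values Numeric vector of in-kernel difference intensities.
#' @param p_gm,p_wm Tissue proportions of the same voxels.
#' @param config An [lr_config()].
#' @return List with `dm_gm` and `dm_wm` (either may be `NA`).
#' @export
lr_fit_kernel <- function(values, p_gm, p_wm, config = lr_config()) {
  if (length(values) != length(p_gm) || length(values) != length(p_wm)) {
    stop("values, p_gm, p_wm must have equal length", call. = FALSE)
  }
  if (length(values) < config$min_valid_voxels) {
    return(list(dm_gm = NA_real_, dm_wm = NA_real_))
  }
  res <- solve_normal_eq(sum(p_gm^2), sum(p_gm * p_wm), sum(p_wm^2),
                         sum(p_gm * values), sum(p_wm * values),
                         config$rank_deficiency_policy)
  list(dm_gm = res$dm_gm, dm_wm = res$dm_wm)
}

#' LR PV correction of a single 3D difference image
#'
#' Slides an in-plane regression kernel over every in-mask voxel and fits
#' the two tissue magnetizations locally. Kernels are truncated at volume
#' boundaries and only in-mask voxels enter each regression, so the result
#' at a voxel depends exclusively on its kernel's in-mask neighbourhood.
#'
#' @param image 3D difference image (a.u.). Off-mask values are ignored.
#' @param fractions A masked [tissue_fraction_volume()].
#' @param config An [lr_config()].
#' @return A `param_maps` object with the `dm_gm`, `dm_wm` fields filled
#'   (variances stay `NA`; this method does not estimate them).
#' @export
lr_correct_volume <- function(image, fractions, config = lr_config()) {
  if (!identical(dim(image), fractions$grid_shape)) {
    stop("image and fractions have different grid shapes", call. = FALSE)
  }
  msk <- fractions$mask
  mnum <- msk * 1
  pg <- fractions$p_gm * mnum
  pw <- fractions$p_wm * mnum
  y0 <- image
  y0[!msk] <- 0
  y0[is.na(y0)] <- 0
  hx <- (config$kernel_x - 1L) %/% 2L
  hy <- (config$kernel_y - 1L) %/% 2L
  sgg <- box_sum_xy(pg * pg, hx, hy)
  sgw <- box_sum_xy(pg * pw, hx, hy)
  sww <- box_sum_xy(pw * pw, hx, hy)
  sgy <- box_sum_xy(pg * y0, hx, hy)
  swy <- box_sum_xy(pw * y0, hx, hy)
  cnt <- box_sum_xy(mnum, hx, hy)
  idx <- which(msk)
  res <- solve_normal_eq(sgg[idx], sgw[idx], sww[idx], sgy[idx], swy[idx],
                         config$rank_deficiency_policy)
  short <- cnt[idx] < config$min_valid_voxels
  res$dm_gm[short] <- NA_real_
  res$dm_wm[short] <- NA_real_
  out <- new_param_maps(fractions$grid_shape)
  out$dm_gm[idx] <- res$dm_gm
  out$dm_wm[idx] <- res$dm_wm
  out
}

#' Initialize EM parameters from per-measurement LR corrections
#'
#' Runs [lr_correct_volume()] on each of the T difference volumes
#' separately. Per voxel and tissue, the initialization takes the mean of
#' the T LR estimates as `dm` and their population variance divided by the
#' tissue proportion as `s` (keeping the per-unit-tissue variance scale of
#' the model). Voxels with fewer than 2 valid per-measurement estimates
#' for a needed tissue fall back to the global
#' [init_from_uncorrected()] values.
#'
#' @param series A [difference_series()] with T >= 2.
#' @param fractions A masked [tissue_fraction_volume()].
#' @param config An [lr_config()].
#' @return A `param_maps` object with `dm_*` and `s_*` set on the mask.
#' @export
init_from_lr <- function(series, fractions, config = lr_config()) {
  check_same_grid(series, fractions)
  shp <- fractions$grid_shape
  zero <- array(0, shp)
  n_g <- zero; s1_g <- zero; s2_g <- zero
  n_w <- zero; s1_w <- zero; s2_w <- zero
  for (t in seq_len(series$n_measurements)) {
    est <- lr_correct_volume(series$data[, , , t], fractions, config)
    ok_g <- !is.na(est$dm_gm)
    n_g[ok_g] <- n_g[ok_g] + 1
    s1_g[ok_g] <- s1_g[ok_g] + est$dm_gm[ok_g]
    s2_g[ok_g] <- s2_g[ok_g] + est$dm_gm[ok_g]^2
    ok_w <- !is.na(est$dm_wm)
    n_w[ok_w] <- n_w[ok_w] + 1
    s1_w[ok_w] <- s1_w[ok_w] + est$dm_wm[ok_w]
    s2_w[ok_w] <- s2_w[ok_w] + est$dm_wm[ok_w]^2
  }
  fb <- init_from_uncorrected(series, fractions)
  out <- new_param_maps(shp)
  msk <- fractions$mask
  fill_tissue <- function(n, s1, s2, p, dm_fb, s_fb) {
    ok <- msk & n >= 2 & p > 0
    dm <- array(NA_real_, shp)
    s <- array(NA_real_, shp)
    dm[ok] <- s1[ok] / n[ok]
    s[ok] <- pmax(s2[ok] / n[ok] - dm[ok]^2, 0) / p[ok]
    fbv <- msk & !ok & p > 0
    dm[fbv] <- dm_fb[fbv]
    s[fbv] <- s_fb[fbv]
    list(dm = dm, s = s, n = n)
  }
  g <- fill_tissue(n_g, s1_g, s2_g, fractions$p_gm, fb$dm_gm, fb$s_gm)
  w <- fill_tissue(n_w, s1_w, s2_w, fractions$p_wm, fb$dm_wm, fb$s_wm)
  out$dm_gm <- g$dm; out$s_gm <- g$s
  out$dm_wm <- w$dm; out$s_wm <- w$s
  attr(out, "n_valid_gm") <- n_g
  attr(out, "n_valid_wm") <- n_w
  out
}
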