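#' Tissue fraction volume
#'
#' Bundles co-registered gray-matter (GM) and white-matter (WM) probability
#' volumes with the analyzable-voxel mask. Probabilities come from structural
#' image segmentation and give, per voxel, the proportion of each tissue
#' contributing to the perfusion signal.
#'
#' @param p_gm,p_wm 3D arrays of tissue proportions in `[0, 1]`.
#' @param voxel_size_mm Numeric length-3 voxel size in millimetres.
#' @param mask Optional 3D logical array of analyzable voxels. Defaults to
#'   `p_gm + p_wm > 0`.
#' @return An object of class `tissue_fraction_volume` with fields `p_gm`,
#'   `p_wm`, `mask`, `grid_shape`, `voxel_size_mm`.
#' @export
tissue_fraction_volume <- function(p_gm, p_wm, voxel_size_mm = c(3, 3, 3),
                                   mask = NULL) {
  if (!is.array(p_gm) || !is.array(p_wm) || length(dim(p_gm)) != 3L ||
      !identical(dim(p_gm), dim(p_wm))) {
    stop("p_gm and p_wm must be 3D arrays of identical shape", call. = FALSE)
  }
  if (anyNA(p_gm) || anyNA(p_wm) ||
      min(p_gm) < 0 || min(p_wm) < 0 || max(p_gm) > 1 || max(p_wm) > 1) {
    stop("tissue proportions must be finite and within [0, 1]", call. = FALSE)
  }
  if (max(p_gm + p_wm) > 1 + 1e-6) {
    stop("p_gm + p_wm exceeds 1 beyond tolerance 1e-6", call. = FALSE)
  }
  if (is.null(mask)) mask <- (p_gm + p_wm) > 0
  if (!identical(dim(mask), dim(p_gm))) {
    stop("mask shape must match probability volumes", call. = FALSE)
  }
  structure(
    list(p_gm = p_gm, p_wm = p_wm, mask = mask,
         grid_shape = dim(p_gm),
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "tissue_fraction_volume")
}

#' Label/control difference series
#'
#' Wraps the 4D stack of T label/control difference volumes \eqn{Y_{it}}
#' (arbitrary signal units). All volumes must be co-registered with the
#' tissue fraction maps they are analysed against.
#'
#' @param data 4D array `(x, y, z, t)` of difference magnetization.
#' @param voxel_size_mm Numeric length-3 voxel size in millimetres.
#' @return An object of class `difference_series` with fields `data`,
#'   `n_measurements`, `grid_shape`, `voxel_size_mm`.
#' @export
difference_series <- function(data, voxel_size_mm = c(3, 3, 3)) {
  if (!is.array(data) || length(dim(data)) != 4L) {
    stop("data must be a 4D array (x, y, z, t)", call. = FALSE)
  }
  if (dim(data)[4] < 2L) {
    stop("a difference series needs at least 2 measurements", call. = FALSE)
  }
  structure(
    list(data = data, n_measurements = dim(data)[4],
         grid_shape = dim(data)[1:3],
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "difference_series")
}

#' Keep the first `n_pairs` measurements of a difference series
#'
#' Used by the reduced-pair-count experiments: the full 40-pair series is
#' generated once and truncated, so shorter acquisitions share the same
#' noise realization prefix.
#'
#' @param series A [difference_series()].
#' @param n_pairs Number of leading measurements to keep (>= 2).
#' @return A [difference_series()] with `n_pairs` volumes.
#' @export
truncate_series <- function(series, n_pairs) {
  stopifnot(inherits(series, "difference_series"))
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 2L || n_pairs > series$n_measurements) {
    stop("n_pairs must be in [2, T]", call. = FALSE)
  }
  difference_series(series$data[, , , seq_len(n_pairs), drop = FALSE],
                    voxel_size_mm = series$voxel_size_mm)
}

#' EM estimator configuration
#'
#' @param max_iter Maximum (or, under `fixed_iterations`, exact) number of
#'   EM iterations. Default 100, the value used to guarantee convergence in
#'   the method-comparison protocol.
#' @param tol Convergence tolerance in signal units for the `param_change`
#'   stopping rule: stop when the largest absolute change across the four
#'   per-voxel parameters between successive iterations falls below `tol`.
#'   Default 0.001.
#' @param stop_rule `"fixed_iterations"` (run exactly `max_iter` iterations)
#'   or `"param_change"` (stop early once the parameter change drops below
#'   `tol`; `max_iter` still caps the run).
#' @param variance_floor Lower clamp for the variance parameters S (a.u.^2),
#'   preventing degenerate E-step weights on noiseless data. Default 1e-8.
#' @param m_step_variant `"as_printed"` keeps the previous mean iterate
#'   inside the variance update; `"joint_update"` uses the freshly updated
#'   mean (textbook EM; guarantees monotone likelihood ascent). The two
#'   coincide at any EM fixed point.
#' @param pure_tissue_threshold Voxels whose smaller tissue proportion is at
#'   or below this value are fitted with the single-tissue closed form
#'   instead of EM. Default 0 (only exactly-absent tissues).
#' @return An object of class `em_config`.
#' @export
em_config <- function(max_iter = 100L, tol = 1e-3,
                      stop_rule = c("fixed_iterations", "param_change"),
                      variance_floor = 1e-8,
                      m_step_variant = c("as_printed", "joint_update"),
                      pure_tissue_threshold = 0) {
  stop_rule <- match.arg(stop_rule)
  m_step_variant <- match.arg(m_step_variant)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  if (variance_floor <= 0) stop("variance_floor must be > 0", call. = FALSE)
  if (pure_tissue_threshold < 0 || pure_tissue_threshold >= 1) {
    stop("pure_tissue_threshold must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(max_iter = max_iter, tol = tol, stop_rule = stop_rule,
         variance_floor = variance_floor, m_step_variant = m_step_variant,
         pure_tissue_threshold = pure_tissue_threshold),
    class = "em_config")
}

#' Per-voxel model parameters
#'
#' The four parameters of the mixed-voxel perfusion model: GM and WM
#' difference magnetizations (a.u.) and the corresponding per-unit-tissue
#' variance parameters (a.u.^2).
#'
#' @param dm_gm,dm_wm Difference magnetization of GM / WM.
#' @param s_gm,s_wm Variance parameters of GM / WM (must be >= 0, `NA`
#'   allowed for an absent tissue).
#' @return An object of class `voxel_params`.
#' @export
voxel_params <- function(dm_gm, dm_wm, s_gm, s_wm) {
  if ((!is.na(s_gm) && s_gm < 0) || (!is.na(s_wm) && s_wm < 0)) {
    stop("variance parameters must be nonnegative", call. = FALSE)
  }
  structure(list(dm_gm = dm_gm, dm_wm = dm_wm, s_gm = s_gm, s_wm = s_wm),
            class = "voxel_params")
}

#' Linear-regression comparator configuration
#'
#' @param kernel_x,kernel_y Odd in-plane kernel extents; default 5, the
#'   kernel size reported to best balance smoothing against PV correction.
#' @param kernel_z Through-plane extent, fixed at 1 (in-plane kernels only).
#' @param min_valid_voxels Minimum number of in-mask voxels a kernel must
#'   contain for a regression to be attempted; below it the centre voxel
#'   gets a missing result. Default 2 (a two-parameter model).
#' @param rank_deficiency_policy `"single_tissue_fallback"` (default)
#'   regresses on the dominant present tissue when the two-column design is
#'   rank deficient; `"pseudo_inverse"` returns the minimum-norm solution.
#' @return An object of class `lr_config`.
#' @export
lr_config <- function(kernel_x = 5L, kernel_y = 5L, kernel_z = 1L,
                      min_valid_voxels = 2L,
                      rank_deficiency_policy = c("single_tissue_fallback",
                                                 "pseudo_inverse")) {
  rank_deficiency_policy <- match.arg(rank_deficiency_policy)
  kernel_x <- as.integer(kernel_x); kernel_y <- as.integer(kernel_y)
  kernel_z <- as.integer(kernel_z)
  if (kernel_x < 1L || kernel_y < 1L || kernel_x %% 2L == 0L ||
      kernel_y %% 2L == 0L) {
    stop("kernel_x and kernel_y must be odd and >= 1", call. = FALSE)
  }
  if (kernel_z != 1L) stop("kernel_z is fixed at 1", call. = FALSE)
  if (min_valid_voxels < 2L) stop("min_valid_voxels must be >= 2", call. = FALSE)
  structure(
    list(kernel_x = kernel_x, kernel_y = kernel_y, kernel_z = kernel_z,
         min_valid_voxels = as.integer(min_valid_voxels),
         rank_deficiency_policy = rank_deficiency_policy),
    class = "lr_config")
}

#' CBF calibration constants
#'
#' Tissue-specific conversion factors and the equilibrium magnetization
#' volume used to convert difference magnetization into cerebral blood flow
#' (mL/100 g/min). The phantom convention `f_gm = f_wm = 1`, `m0 = 1` makes
#' CBF numerically equal to the difference magnetization.
#'
#' @param f_gm,f_wm Positive conversion factors for GM and WM.
#' @param m0 Equilibrium magnetization: the scalar 1 or a positive 3D array.
#' @return An object of class `calibration_constants`.
#' @export
calibration_constants <- function(f_gm = 1, f_wm = 1, m0 = 1) {
  if (f_gm <= 0 || f_wm <= 0) stop("f_gm and f_wm must be > 0", call. = FALSE)
  structure(list(f_gm = f_gm, f_wm = f_wm, m0 = m0),
            class = "calibration_constants")
}

# internal: empty parameter-map container defined on a grid
new_param_maps <- function(grid_shape) {
  blank <- array(NA_real_, dim = grid_shape)
  structure(
    list(dm_gm = blank, dm_wm = blank, s_gm = blank, s_wm = blank,
         n_iter = array(NA_integer_, dim = grid_shape),
         converged = array(NA, dim = grid_shape),
         grid_shape = grid_shape),
    class = "param_maps")
}

check_same_grid <- function(series, fractions) {
  if (!identical(as.integer(series$grid_shape),
                 as.integer(fractions$grid_shape))) {
    stop("series and tissue fractions have different grid shapes",
         call. = FALSE)
  }
  invisible(TRUE)
}
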