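# Evaluation statistics: RMSE against truth, GM-probability ROI curves,
# CBF ratio dispersion, and the simulation-table experiments.

time_average <- function(series) {
  avg <- rowMeans(matrix(series$data, ncol = series$n_measurements))
  dim(avg) <- series$grid_shape
  avg
}

#' Run one PV-correction method end to end
#'
#' Dispatches the four comparison methods on a difference series:
#' \describe{
#'   \item{`none`}{the time-averaged image itself, taken as the GM CBF
#'     estimate (no separation).}
#'   \item{`lr`}{kernel-wise linear regression on the averaged image.}
#'   \item{`sem`}{EM initialized from the uncorrected averaged image
#'     (global pure-region means).}
#'   \item{`sem_lr`}{EM initialized from per-measurement LR corrections.}
#' }
#'
#' @param series A [difference_series()].
#' @param fractions A masked [tissue_fraction_volume()].
#' @param method One of `"none"`, `"lr"`, `"sem"`, `"sem_lr"`.
#' @param em An [em_config()].
#' @param lr An [lr_config()].
#' @param calib A [calibration_constants()].
#' @return List with `method`, `maps` (a `param_maps`), and `cbf`
#'   (a `cbf_maps`).
#' @export
pv_correct <- function(series, fractions,
                       method = c("sem_lr", "sem", "lr", "none"),
                       em = em_config(), lr = lr_config(),
                       calib = calibration_constants()) {
  method <- match.arg(method)
  check_same_grid(series, fractions)
  maps <- switch(method,
    none = {
      avg <- time_average(series)
      m <- new_param_maps(fractions$grid_shape)
      msk <- fractions$mask
      m$dm_gm[msk] <- avg[msk]
      m$dm_wm[msk] <- avg[msk]
      m
    },
    lr = lr_correct_volume(time_average(series), fractions, lr),
    sem = fit_volume(series, fractions,
                     init_from_uncorrected(series, fractions), em),
    sem_lr = fit_volume(series, fractions,
                        init_from_lr(series, fractions, lr), em))
  list(method = method, maps = maps,
       cbf = quantify_cbf(maps, fractions, calib))
}

#' RMSE of the GM CBF estimate against phantom truth
#'
#' Root mean squared difference between the per-unit-GM CBF estimate
#' (`cbf_gm_pure`) and the true GM perfusion map, over the GM region
#' (`p_gm >= 0.1`, default) or the whole mask. Voxels without an estimate
#' are excluded; their count is attached as attribute `n_excluded`.
#'
#' @param estimate A `cbf_maps` (or the list returned by [pv_correct()]).
#' @param truth A `phantom_truth`.
#' @param region `"gm_mask"` or `"whole_mask"`.
#' @return RMSE in mL/100 g/min.
#' @export
rmse_gm <- function(estimate, truth, region = c("gm_mask", "whole_mask")) {
  region <- match.arg(region)
  if (!is.null(estimate[["cbf"]])) estimate <- estimate[["cbf"]]
  fr <- truth$fractions
  sel <- if (region == "gm_mask") fr$mask & fr$p_gm >= 0.1 else fr$mask
  if (!any(sel)) stop("empty evaluation region", call. = FALSE)
  est <- estimate$cbf_gm_pure[sel]
  tru <- truth$gm_cbf_true[sel]
  ok <- is.finite(est)
  if (!any(ok)) stop("no valid estimates in region", call. = FALSE)
  out <- sqrt(mean((est[ok] - tru[ok])^2))
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' GM-probability ROI curve
#'
#' Splits the GM region into nine probability bins, `[0.1, 0.2)` up to
#' `[0.9, 1.0]`, and averages the per-unit-GM CBF estimate within each.
#' A flat curve across bins indicates GM CBF estimates independent of the
#' GM probability, i.e. successful PV correction; uncorrected data slope
#' upward because low-probability voxels are diluted by WM and background.
#'
#' @param estimate A `cbf_maps` (or the list returned by [pv_correct()]).
#' @param fractions A masked [tissue_fraction_volume()].
#' @return An object of class `roi_summary`: list with `bin_edges`
#'   (0.1, ..., 1.0), `mean_cbf_per_bin` (length 9, `NA` for empty bins),
#'   and `n_voxels_per_bin`.
#' @export
roi_curve <- function(estimate, fractions) {
  if (!is.null(estimate[["cbf"]])) estimate <- estimate[["cbf"]]
  edges <- seq(0.1, 1.0, by = 0.1)
  est <- estimate$cbf_gm_pure
  sel <- fractions$mask & fractions$p_gm >= 0.1 & is.finite(est)
  p <- fractions$p_gm[sel]
  v <- est[sel]
  bin <- pmin(findInterval(p, edges), 9L)
  means <- rep(NA_real_, 9L)
  counts <- integer(9L)
  for (b in seq_len(9L)) {
    inb <- bin == b
    counts[b] <- sum(inb)
    if (counts[b] > 0L) means[b] <- mean(v[inb])
  }
  structure(list(bin_edges = edges, mean_cbf_per_bin = means,
                 n_voxels_per_bin = counts),
            class = "roi_summary")
}

#' Mean GM CBF of the uncorrected (averaged) image
#'
#' Reference denominator of the CBF ratio: the mean of the time-averaged
#' difference image over the GM region (`p_gm >= 0.1`).
#'
#' @param series A [difference_series()].
#' @param fractions A masked [tissue_fraction_volume()].
#' @return Scalar mean (a.u. = mL/100 g/min under the phantom convention).
#' @export
uncorrected_mean_gm <- function(series, fractions) {
  avg <- time_average(series)
  sel <- fractions$mask & fractions$p_gm >= 0.1
  if (!any(sel)) stop("empty GM region", call. = FALSE)
  mean(avg[sel])
}

#' GM CBF ratio and its dispersion across probability bins
#'
#' Voxel-wise ratio of the estimated per-unit-GM CBF to the mean GM CBF of
#' the uncorrected maps, plus the standard deviation of the nine ROI-bin
#' mean ratios. The ratio removes calibration-scale differences; a low
#' bin-to-bin standard deviation means GM CBF estimates independent of GM
#' probability.
#'
#' @param estimate A `cbf_maps` (or the list returned by [pv_correct()]).
#' @param fractions A masked [tissue_fraction_volume()].
#' @param uncorrected_mean_gm Positive reference mean (see
#'   [uncorrected_mean_gm()]).
#' @return List with `ratio` (3D array), `bin_mean_ratio` (length 9), and
#'   `sd_ratio` (sample standard deviation over the non-empty bins).
#' @export
cbf_ratio <- function(estimate, fractions, uncorrected_mean_gm) {
  if (uncorrected_mean_gm <= 0) {
    stop("uncorrected_mean_gm must be > 0", call. = FALSE)
  }
  if (!is.null(estimate[["cbf"]])) estimate <- estimate[["cbf"]]
  ratio <- estimate$cbf_gm_pure / uncorrected_mean_gm
  scaled <- estimate
  scaled$cbf_gm_pure <- ratio
  rc <- roi_curve(scaled, fractions)
  bins <- rc$mean_cbf_per_bin
  list(ratio = ratio, bin_mean_ratio = bins,
       sd_ratio = stats::sd(bins[is.finite(bins)]))
}

#' Mean estimated GM CBF inside each phantom lesion
#'
#' @param estimate A `cbf_maps` (or the list returned by [pv_correct()]).
#' @param truth A `phantom_truth` with lesions.
#' @return Numeric vector, one mean per lesion (over in-mask lesion voxels
#'   with a finite estimate).
#' @export
lesion_means <- function(estimate, truth) {
  if (!is.null(estimate[["cbf"]])) estimate <- estimate[["cbf"]]
  vapply(seq_along(truth$lesions), function(i) {
    m <- lesion_mask(truth, i) & truth$fractions$mask
    v <- estimate$cbf_gm_pure[m]
    mean(v[is.finite(v)])
  }, numeric(1))
}

# deterministic per-cell noise seed, kept below 2^31
cell_seed <- function(seed, noise_std) {
  as.integer(seed * 100003L + round(noise_std))
}

#' Simulation-1 RMSE experiment across noise levels and methods
#'
#' Builds the Simulation-1 phantom once (anatomy fixed by
#' `config$seed`), then, for every noise level and seed, renders a fresh
#' noisy series and scores each requested correction method by
#' [rmse_gm()].
#'
#' @param seeds Integer vector of noise-realization seeds.
#' @param noise_levels Noise standard deviations, default `c(5, 10, 15)`.
#' @param methods Subset of `c("none", "lr", "sem", "sem_lr")`.
#' @param config A [phantom_config()].
#' @param em An [em_config()].
#' @param lr An [lr_config()].
#' @param truth Optional pre-built `phantom_truth` (overrides `config`).
#' @return data.frame with columns `noise_std`, `method`, `seed`, `rmse`.
#' @export
run_table1_experiment <- function(seeds = 1:5, noise_levels = c(5, 10, 15),
                                  methods = c("none", "lr", "sem", "sem_lr"),
                                  config = phantom_config(),
                                  em = em_config(), lr = lr_config(),
                                  truth = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(truth)) {
    fr <- synth_fractions(config$grid_shape, seed = config$seed,
                          voxel_size_mm = config$voxel_size_mm,
                          prob_floor = config$prob_floor)
    truth <- build_truth_sim1(fr, config)
  }
  rows <- list()
  for (ns in noise_levels) {
    for (sd_seed in seeds) {
      series <- render_series(truth, noise_std = ns,
                              n_pairs = config$n_pairs,
                              seed = cell_seed(sd_seed, ns))
      for (m in methods) {
        fit <- pv_correct(series, truth$fractions, method = m,
                          em = em, lr = lr)
        rows[[length(rows) + 1L]] <- data.frame(
          noise_std = ns, method = m, seed = sd_seed,
          rmse = as.numeric(rmse_gm(fit, truth)))
      }
    }
  }
  do.call(rbind, rows)
}

#' Reduced-pair-count RMSE experiment (sEM-LR)
#'
#' For every noise level and seed, renders the full series once and scores
#' the sEM-LR method on its leading `n_pairs` measurements for each pair
#' count, so shorter acquisitions are true prefixes of the full one.
#'
#' @param seeds Integer vector of noise-realization seeds.
#' @param noise_levels Noise standard deviations.
#' @param pair_counts Numbers of label/control pairs, default
#'   `c(10, 20, 30, 40)`.
#' @inheritParams run_table1_experiment
#' @return data.frame with columns `noise_std`, `n_pairs`, `seed`, `rmse`.
#' @export
run_table2_experiment <- function(seeds = 1:5, noise_levels = c(5, 10, 15),
                                  pair_counts = c(10, 20, 30, 40),
                                  config = phantom_config(),
                                  em = em_config(), lr = lr_config(),
                                  truth = NULL) {
  if (is.null(truth)) {
    fr <- synth_fractions(config$grid_shape, seed = config$seed,
                          voxel_size_mm = config$voxel_size_mm,
                          prob_floor = config$prob_floor)
    truth <- build_truth_sim1(fr, config)
  }
  n_max <- max(pair_counts)
  rows <- list()
  for (ns in noise_levels) {
    for (sd_seed in seeds) {
      series <- render_series(truth, noise_std = ns, n_pairs = n_max,
                              seed = cell_seed(sd_seed, ns))
      for (np in pair_counts) {
        sub <- if (np == n_max) series else truncate_series(series, np)
        fit <- pv_correct(sub, truth$fractions, method = "sem_lr",
                          em = em, lr = lr)
        rows[[length(rows) + 1L]] <- data.frame(
          noise_std = ns, n_pairs = np, seed = sd_seed,
          rmse = as.numeric(rmse_gm(fit, truth)))
      }
    }
  }
  do.call(rbind, rows)
}
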