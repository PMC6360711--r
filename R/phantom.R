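# Digital head phantom: procedural anatomy stand-in, ground-truth CBF,
# lesions, and noisy multi-measurement difference series.

#' Phantom configuration
#'
#' Defaults state the simulated world: a 60 x 72 x 60 grid at 3 mm
#' isotropic resolution, GM perfusion 60 and WM perfusion 20 mL/100 g/min,
#' Gaussian measurement noise with standard deviation 5, 10 or 15 a.u.,
#' and 40 label/control pairs. The signal convention sets F/M0 = 1 so that
#' difference-signal units equal mL/100 g/min.
#'
#' @param grid_shape Integer length-3 grid size.
#' @param voxel_size_mm Voxel size in millimetres.
#' @param gm_cbf,wm_cbf Baseline tissue perfusion (mL/100 g/min).
#' @param noise_std Gaussian noise standard deviation (a.u.).
#' @param n_pairs Number of label/control difference measurements.
#' @param seed Seed for the procedural anatomy.
#' @param prob_floor Probability mask threshold, default 0.1.
#' @param lesions Optional list of [lesion_spec()]; `NULL` picks the
#'   simulation's default lesion set automatically.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(60L, 72L, 60L),
                           voxel_size_mm = c(3, 3, 3),
                           gm_cbf = 60, wm_cbf = 20,
                           noise_std = 10, n_pairs = 40L, seed = 1L,
                           prob_floor = 0.1, lesions = NULL) {
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  if (n_pairs < 1L) stop("n_pairs must be >= 1", call. = FALSE)
  structure(
    list(grid_shape = as.integer(grid_shape),
         voxel_size_mm = as.numeric(voxel_size_mm),
         gm_cbf = gm_cbf, wm_cbf = wm_cbf, noise_std = noise_std,
         n_pairs = as.integer(n_pairs), seed = as.integer(seed),
         prob_floor = prob_floor, lesions = lesions),
    class = "phantom_config")
}

#' Lesion geometry specification
#'
#' @param shape `"sphere"` (size = radius in voxels, membership by voxel
#'   centre within the radius) or `"cube"` (size = edge length in voxels;
#'   the block starts at `center - floor((size - 1) / 2)`).
#' @param center Integer voxel triple (1-based).
#' @param size Positive radius / edge length in voxels.
#' @param cbf_value Perfusion inside the lesion (mL/100 g/min), >= 0.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(shape = c("sphere", "cube"), center, size, cbf_value) {
  shape <- match.arg(shape)
  if (size <= 0) stop("lesion size must be > 0", call. = FALSE)
  if (cbf_value < 0) stop("lesion cbf_value must be >= 0", call. = FALSE)
  structure(list(shape = shape, center = as.numeric(center),
                 size = size, cbf_value = cbf_value),
            class = "lesion_spec")
}

# periodic FFT Gaussian smoothing; fields of interest vanish near edges
gauss_smooth3 <- function(a, sigma) {
  d <- dim(a)
  tf <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n
    exp(-0.5 * (2 * pi * k * sigma / n)^2)
  }
  g <- outer(outer(tf(d[1]), tf(d[2])), tf(d[3]))
  dim(g) <- d
  Re(stats::fft(stats::fft(a) * g, inverse = TRUE)) / prod(d)
}

#' Synthesize a brain-like tissue probability volume
#'
#' Procedural stand-in for segmented structural MRI: an ellipsoidal brain
#' whose outer surface carries a thin cortical GM ribbon (thickness varying
#' around 1--3 voxels at the default 3 mm resolution, i.e. 3--9 mm) over a
#' WM core, plus a central CSF cavity and two deep GM nuclei. Both ribbon
#' surfaces are wrinkled by a smooth random "folding" field so that
#' regression kernels straddle curved GM/WM/background interfaces, as they
#' do in real cortex. Tissue indicators are blurred by about one voxel to
#' create the partial-volume mixtures of a resampled probability map. The
#' result is masked at `prob_floor` (default 0.1).
#'
#' @param grid_shape Integer length-3 grid, at least 16 voxels per axis.
#' @param seed Integer seed; identical seeds give identical volumes.
#' @param voxel_size_mm Voxel size stored with the volume.
#' @param prob_floor Probability mask threshold.
#' @return A masked [tissue_fraction_volume()]. At least 20 percent of
#'   in-mask voxels are mixed (0.1 < p_gm < 0.9); violation is an error.
#' @export
synth_fractions <- function(grid_shape = c(60L, 72L, 60L), seed = 1L,
                            voxel_size_mm = c(3, 3, 3), prob_floor = 0.1) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 16L)) {
    stop("grid must be at least 16 voxels per axis", call. = FALSE)
  }
  set.seed(as.integer(seed))
  d <- grid_shape
  cx <- (d + 1) / 2
  u1 <- (seq_len(d[1]) - cx[1]) / (d[1] / 2)
  u2 <- (seq_len(d[2]) - cx[2]) / (d[2] / 2)
  u3 <- (seq_len(d[3]) - cx[3]) / (d[3] / 2)
  U1 <- array(u1, d)
  U2 <- array(rep(u2, each = d[1]), d)
  U3 <- array(rep(u3, each = d[1] * d[2]), d)
  r <- sqrt((U1 / 0.82)^2 + (U2 / 0.88)^2 + (U3 / 0.78)^2)
  rnd_field <- function(sigma, amp) {
    f <- gauss_smooth3(array(stats::rnorm(prod(d)), d), sigma = sigma)
    f / stats::sd(f) * amp
  }
  # large-scale asymmetry plus gyral-scale folding of the brain surface
  bump <- rnd_field(4, 0.03)
  fold <- rnd_field(2.2, 0.045)
  rr <- r + bump + fold
  # cortical thickness field, ~1-3 voxels in normalized radial units
  th <- pmin(pmax(0.085 + rnd_field(3, 0.03), 0.045), 0.13)
  outer_r <- 0.88
  gm0 <- rr < outer_r & rr >= outer_r - th
  wm0 <- rr < outer_r - th
  # central CSF cavity (ventricles): neither tissue
  rv <- sqrt((U1 / 0.16)^2 + (U2 / 0.26)^2 + (U3 / 0.14)^2)
  csf <- rv + 2 * bump < 1
  gm0 <- gm0 & !csf
  wm0 <- wm0 & !csf
  # two deep GM nuclei flanking the cavity
  for (s in c(-1, 1)) {
    rn <- sqrt(((U1 - s * 0.32) / 0.14)^2 + (U2 / 0.16)^2 + (U3 / 0.13)^2)
    nuc <- rn < 1
    gm0[nuc] <- TRUE
    wm0[nuc] <- FALSE
  }
  p_gm <- gauss_smooth3(wm0 * 0 + gm0, sigma = 0.6)
  p_wm <- gauss_smooth3(gm0 * 0 + wm0, sigma = 0.6)
  p_gm <- pmin(pmax(p_gm, 0), 1)
  p_wm <- pmin(pmax(p_wm, 0), 1)
  tot <- p_gm + p_wm
  over <- tot > 1
  p_gm[over] <- p_gm[over] / tot[over]
  p_wm[over] <- p_wm[over] / tot[over]
  out <- apply_probability_mask(
    tissue_fraction_volume(p_gm, p_wm, voxel_size_mm = voxel_size_mm),
    threshold = prob_floor)
  mixed <- out$mask & out$p_gm > 0.1 & out$p_gm < 0.9
  if (sum(mixed) < 0.2 * sum(out$mask)) {
    stop("degenerate anatomy: fewer than 20% mixed voxels", call. = FALSE)
  }
  out
}

lesion_voxels <- function(lesion, grid_shape) {
  d <- grid_shape
  m <- array(FALSE, d)
  c0 <- lesion$center
  if (lesion$shape == "sphere") {
    r <- lesion$size
    rng <- lapply(1:3, function(k) {
      max(1, floor(c0[k] - r)):min(d[k], ceiling(c0[k] + r))
    })
    for (z in rng[[3]]) for (y in rng[[2]]) {
      dx <- rng[[1]] - c0[1]
      dd <- sqrt(dx^2 + (y - c0[2])^2 + (z - c0[3])^2)
      m[rng[[1]][dd <= r], y, z] <- TRUE
    }
  } else {
    e <- round(lesion$size)
    lo <- c0 - floor((e - 1) / 2)
    for (k in 1:3) {
      if (lo[k] < 1 || lo[k] + e - 1 > d[k]) {
        stop("lesion does not fit inside the grid", call. = FALSE)
      }
    }
    m[lo[1]:(lo[1] + e - 1), lo[2]:(lo[2] + e - 1),
      lo[3]:(lo[3] + e - 1)] <- TRUE
  }
  if (!any(m)) stop("lesion does not fit inside the grid", call. = FALSE)
  m
}

# deterministic lesion placement: centres in high-GM territory on the
# central axial slice, spread along x, pairwise separated
pick_lesion_centers <- function(fractions, n, min_sep) {
  d <- fractions$grid_shape
  zc <- round(d[3] / 2)
  slab <- abs(slice.index(fractions$p_gm, 3) - zc) <= 2
  for (cut in c(0.95, 0.9, 0.8)) {
    cand <- which(slab & fractions$p_gm >= cut, arr.ind = TRUE)
    if (nrow(cand) >= n * 50) break
  }
  if (nrow(cand) < n) stop("not enough high-GM voxels for lesions",
                           call. = FALSE)
  targets <- seq(0.15, 0.85, length.out = n)
  centers <- vector("list", n)
  taken <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    tx <- stats::quantile(cand[, 1], targets[i], type = 1)
    sc <- cand[order(abs(cand[, 1] - tx),
                     abs(cand[, 2] - d[2] / 2)), , drop = FALSE]
    picked <- FALSE
    for (j in seq_len(nrow(sc))) {
      p <- sc[j, ]
      if (nrow(taken) == 0 ||
          all(sqrt(rowSums(sweep(taken, 2, p)^2)) >= min_sep)) {
        centers[[i]] <- as.numeric(p)
        taken <- rbind(taken, p)
        picked <- TRUE
        break
      }
    }
    if (!picked) stop("could not place lesions with requested separation",
                      call. = FALSE)
  }
  centers
}

build_truth <- function(fractions, config, lesions) {
  d <- fractions$grid_shape
  gm_true <- array(config$gm_cbf, d)
  wm_true <- array(config$wm_cbf, d)
  seen <- array(FALSE, d)
  for (les in lesions) {
    m <- lesion_voxels(les, d)
    if (any(seen & m)) stop("overlapping lesions", call. = FALSE)
    seen <- seen | m
    gm_true[m] <- les$cbf_value
  }
  clean <- fractions$p_gm * gm_true + fractions$p_wm * wm_true
  structure(
    list(fractions = fractions, gm_cbf_true = gm_true,
         wm_cbf_true = wm_true, clean_signal = clean,
         lesions = lesions, config = config),
    class = "phantom_truth")
}

#' Ground truth for Simulation 1 (hypo- and hyper-perfused lesions)
#'
#' GM perfusion is 60 mL/100 g/min everywhere except a hypo-perfused
#' sphere (radius 5 voxels, 30 mL/100 g/min) and a hyper-perfused sphere
#' (radius 5, 90 mL/100 g/min); WM is 20 mL/100 g/min. The clean signal is
#' the proportion-weighted tissue mixture.
#'
#' @param fractions A masked [tissue_fraction_volume()], e.g. from
#'   [synth_fractions()].
#' @param config A [phantom_config()]. `config$lesions`, when non-`NULL`,
#'   overrides the default lesion set.
#' @return An object of class `phantom_truth` with fields `fractions`,
#'   `gm_cbf_true`, `wm_cbf_true`, `clean_signal`, `lesions`, `config`.
#' @export
build_truth_sim1 <- function(fractions, config = phantom_config()) {
  lesions <- config$lesions
  if (is.null(lesions)) {
    ctr <- pick_lesion_centers(fractions, 2, min_sep = 14)
    lesions <- list(
      lesion_spec("sphere", ctr[[1]], 5, 30),
      lesion_spec("sphere", ctr[[2]], 5, 90))
  }
  build_truth(fractions, config, lesions)
}

#' Ground truth for Simulation 2 (small-lesion detectability)
#'
#' Three GM lesions against the 60 mL/100 g/min baseline: a sphere of
#' radius 5 at 75, a 3 x 3 x 3 cube at 45, and a 2 x 2 x 2 cube at 75.
#' The lesion contrasts (15) equal the highest simulated noise level.
#'
#' @inheritParams build_truth_sim1
#' @return An object of class `phantom_truth`.
#' @export
build_truth_sim2 <- function(fractions, config = phantom_config(noise_std = 15)) {
  lesions <- config$lesions
  if (is.null(lesions)) {
    ctr <- pick_lesion_centers(fractions, 3, min_sep = 14)
    lesions <- list(
      lesion_spec("sphere", ctr[[1]], 5, 75),
      lesion_spec("cube", ctr[[2]], 3, 45),
      lesion_spec("cube", ctr[[3]], 2, 75))
  }
  build_truth(fractions, config, lesions)
}

#' Render a noisy multi-measurement difference series from a phantom
#'
#' Each of the `n_pairs` volumes equals the clean mixture signal plus
#' i.i.d. Gaussian noise of standard deviation `noise_std`, drawn per
#' in-mask voxel and measurement. Off-mask voxels carry 0 and receive no
#' noise. Identical `(truth, noise_std, n_pairs, seed)` give bit-identical
#' series.
#'
#' @param truth A `phantom_truth`.
#' @param noise_std Noise standard deviation; defaults to the config value.
#' @param n_pairs Number of measurements; defaults to the config value.
#' @param seed Integer seed for the noise stream.
#' @return A [difference_series()].
#' @export
render_series <- function(truth, noise_std = NULL, n_pairs = NULL,
                          seed = 1L) {
  if (is.null(noise_std)) noise_std <- truth$config$noise_std
  if (is.null(n_pairs)) n_pairs <- truth$config$n_pairs
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  d <- truth$fractions$grid_shape
  idx <- which(truth$fractions$mask)
  nvox <- prod(d)
  data <- array(0, dim = c(d, n_pairs))
  set.seed(as.integer(seed))
  clean <- truth$clean_signal[idx]
  for (t in seq_len(n_pairs)) {
    noise <- if (noise_std > 0) stats::rnorm(length(idx), 0, noise_std) else 0
    data[idx + (t - 1) * nvox] <- clean + noise
  }
  difference_series(data, voxel_size_mm = truth$fractions$voxel_size_mm)
}

#' Logical mask of one phantom lesion
#'
#' @param truth A `phantom_truth`.
#' @param i Lesion index in `truth$lesions`.
#' @return 3D logical array.
#' @export
lesion_mask <- function(truth, i) {
  lesion_voxels(truth$lesions[[i]], truth$fractions$grid_shape)
}
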