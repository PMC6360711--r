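test_that("voxel sufficient stats: mean and population variance", {
  expect_equal(voxel_sufficient_stats(c(44, 44, 44)),
               list(mean = 44, variance = 0))
  expect_equal(voxel_sufficient_stats(c(40, 48)),
               list(mean = 44, variance = 16))
  expect_error(voxel_sufficient_stats(44), "at least 2")
  expect_error(voxel_sufficient_stats(c(1, NA)), "finite")
  set.seed(11)
  y <- rnorm(1000, 60, 15)
  st <- voxel_sufficient_stats(y)
  expect_lt(abs(st$mean - 60), 1.5)
  expect_lt(abs(st$variance - 225), 25)
})

test_that("E-step: zero innovation, additivity, second-moment bound", {
  pars <- voxel_params(60, 20, 25, 25)
  mu <- 0.6 * 60 + 0.4 * 20
  mom <- e_step(mu, pars, 0.6, 0.4)
  expect_equal(mom$x_gm, 0.6 * 60)
  expect_equal(mom$x_wm, 0.4 * 20)
  set.seed(21)
  for (i in 1:25) {
    pg <- runif(1, 0.05, 0.95)
    pw <- runif(1, 0.02, 1 - pg)
    pars <- voxel_params(rnorm(1, 50, 30), rnorm(1, 20, 15),
                         runif(1, 0.1, 400), runif(1, 0.1, 400))
    y <- rnorm(7, 40, 25)
    mom <- e_step(y, pars, pg, pw)
    expect_equal(mom$x_gm + mom$x_wm, y, tolerance = 1e-12)
    cv <- (pg * pars$s_gm) * (pw * pars$s_wm) /
      (pg * pars$s_gm + pw * pars$s_wm)
    expect_equal(mom$x2_gm - mom$x_gm^2, rep(cv, 7))
    expect_equal(mom$x2_wm - mom$x_wm^2, rep(cv, 7))
    expect_true(all(mom$x2_gm >= mom$x_gm^2))
  }
})

test_that("E-step matches the bivariate-Gaussian conditioning oracle", {
  or <- oracle_conditional_moments(50, 60, 20, 25, 25, 0.6, 0.4)
  mom <- e_step(50, voxel_params(60, 20, 25, 25), 0.6, 0.4)
  expect_equal(mom$x_gm, or$x_gm, tolerance = 1e-6)
  expect_equal(mom$x_wm, or$x_wm, tolerance = 1e-6)
  expect_equal(mom$x2_gm, or$x2_gm, tolerance = 1e-6)
  expect_equal(mom$x2_wm, or$x2_wm, tolerance = 1e-6)
  set.seed(31)
  for (i in 1:20) {
    pg <- runif(1, 0.1, 0.9)
    pw <- runif(1, 0.05, 1 - pg)
    dm_g <- runif(1, -20, 90)
    dm_w <- runif(1, -10, 50)
    s_g <- runif(1, 1, 200)
    s_w <- runif(1, 1, 200)
    y <- runif(1, -30, 100)
    or <- oracle_conditional_moments(y, dm_g, dm_w, s_g, s_w, pg, pw)
    mom <- e_step(y, voxel_params(dm_g, dm_w, s_g, s_w), pg, pw)
    expect_equal(mom$x_gm, or$x_gm, tolerance = 1e-6)
    expect_equal(mom$x2_gm, or$x2_gm, tolerance = 1e-6)
    expect_equal(mom$x2_wm, or$x2_wm, tolerance = 1e-6)
  }
})

test_that("M-step: constant latent series and degenerate-proportion guard", {
  cv <- 3.5
  mom <- list(x_gm = rep(12, 5), x_wm = rep(8, 5),
              x2_gm = rep(144 + cv, 5), x2_wm = rep(64 + cv, 5))
  prev <- voxel_params(0, 0, 1, 1)
  up <- m_step(mom, prev, 0.6, 0.4, variant = "joint_update")
  expect_equal(up$dm_gm, 12 / 0.6)
  expect_equal(up$dm_wm, 8 / 0.4)
  # with constant latents only the conditional-variance term survives
  expect_equal(up$s_gm, cv / 0.6)
  expect_equal(up$s_wm, cv / 0.4)
  expect_error(m_step(mom, prev, 0, 0.4), "fit_pure_voxel")
})

test_that("M-step matches grid-search maximization of Q", {
  set.seed(41)
  pg <- 0.6; pw <- 0.4
  pars <- voxel_params(55, 25, 60, 40)
  y <- rnorm(5, 45, 8)
  mom <- e_step(y, pars, pg, pw)
  up <- m_step(mom, pars, pg, pw, variant = "joint_update")
  og <- oracle_q_argmax(mom$x_gm, mom$x2_gm, pg,
                        dm_range = c(0, 120), s_range = c(1e-3, 300))
  ow <- oracle_q_argmax(mom$x_wm, mom$x2_wm, pw,
                        dm_range = c(-40, 100), s_range = c(1e-3, 300))
  expect_equal(up$dm_gm, og[1], tolerance = 2e-3)
  expect_equal(up$s_gm, og[2], tolerance = 2e-3)
  expect_equal(up$dm_wm, ow[1], tolerance = 2e-3)
  expect_equal(up$s_wm, ow[2], tolerance = 2e-3)
})

test_that("M-step variants coincide at an EM fixed point", {
  set.seed(51)
  y <- rnorm(40, 44, 5)
  fit <- fit_voxel(y, 0.6, 0.4, voxel_params(60, 20, 25, 25),
                   em_config(max_iter = 500, tol = 1e-12,
                             stop_rule = "param_change"))
  mom <- e_step(y, fit$params, 0.6, 0.4)
  a <- m_step(mom, fit$params, 0.6, 0.4, variant = "as_printed")
  b <- m_step(mom, fit$params, 0.6, 0.4, variant = "joint_update")
  expect_equal(unclass(a), unclass(b), tolerance = 1e-6)
})

test_that("fit_voxel: constant data, conservation identities at convergence", {
  fit <- fit_voxel(rep(44, 10), 0.6, 0.4, voxel_params(60, 20, 25, 25),
                   em_config(max_iter = 200, tol = 1e-10,
                             stop_rule = "param_change"))
  p <- fit$params
  expect_lt(abs(0.6 * p$dm_gm + 0.4 * p$dm_wm - 44), 1e-4)
  expect_equal(p$s_gm, 1e-8)
  expect_equal(p$s_wm, 1e-8)

  set.seed(61)
  y <- rnorm(40, 44, 5)
  st <- voxel_sufficient_stats(y)
  for (variant in c("as_printed", "joint_update")) {
    fit <- fit_voxel(y, 0.6, 0.4, voxel_params(60, 20, 25, 25),
                     em_config(max_iter = 500, tol = 1e-8,
                               stop_rule = "param_change",
                               m_step_variant = variant))
    p <- fit$params
    expect_true(fit$converged)
    expect_lt(abs(0.6 * p$dm_gm + 0.4 * p$dm_wm - st$mean) /
                abs(st$mean), 1e-4)
    expect_lt(abs(0.6 * p$s_gm + 0.4 * p$s_wm - st$variance) /
                st$variance, 1e-4)
  }
})

test_that("fit_voxel: label symmetry and scale equivariance are exact", {
  set.seed(71)
  y <- rnorm(15, 30, 6)
  cfg <- em_config(max_iter = 40)
  a <- fit_voxel(y, 0.7, 0.25, voxel_params(55, 18, 30, 12), cfg)
  b <- fit_voxel(y, 0.25, 0.7, voxel_params(18, 55, 12, 30), cfg)
  expect_identical(a$params$dm_gm, b$params$dm_wm)
  expect_identical(a$params$dm_wm, b$params$dm_gm)
  expect_identical(a$params$s_gm, b$params$s_wm)
  expect_identical(a$params$s_wm, b$params$s_gm)

  c0 <- 2.5
  sc <- fit_voxel(c0 * y, 0.7, 0.25,
                  voxel_params(c0 * 55, c0 * 18, c0^2 * 30, c0^2 * 12), cfg)
  expect_equal(sc$params$dm_gm, c0 * a$params$dm_gm, tolerance = 1e-12)
  expect_equal(sc$params$dm_wm, c0 * a$params$dm_wm, tolerance = 1e-12)
  expect_equal(sc$params$s_gm, c0^2 * a$params$s_gm, tolerance = 1e-12)
  expect_equal(sc$params$s_wm, c0^2 * a$params$s_wm, tolerance = 1e-12)
})

test_that("fit_voxel stopping rules and input contracts", {
  set.seed(81)
  y <- rnorm(12, 40, 4)
  f <- fit_voxel(y, 0.5, 0.5, voxel_params(50, 30, 20, 20),
                 em_config(max_iter = 7, stop_rule = "fixed_iterations"))
  expect_identical(f$n_iter, 7L)
  g <- fit_voxel(y, 0.5, 0.5, voxel_params(50, 30, 20, 20),
                 em_config(max_iter = 100, tol = 1e-3,
                           stop_rule = "param_change"))
  expect_lt(g$n_iter, 100L)
  expect_true(g$converged)
  expect_error(fit_voxel(c(1, NA, 3), 0.5, 0.5,
                         voxel_params(1, 1, 1, 1)), "finite")
  expect_error(fit_voxel(y, 0, 0, voxel_params(1, 1, 1, 1)), "mask")
  expect_error(fit_voxel(y, 0.5, 0, voxel_params(1, 1, 1, 1)), "pure")
})

test_that("fit_pure_voxel closed form and continuity towards fit_voxel", {
  p <- fit_pure_voxel(c(30, 30), 1, "gm")
  expect_equal(p$dm_gm, 30)
  expect_equal(p$s_gm, 1e-8)
  expect_identical(attr(p, "absent"), "wm")
  q <- fit_pure_voxel(c(40, 48), 0.8, "gm")
  expect_equal(q$dm_gm, 55)
  expect_equal(q$s_gm, 20)
  w <- fit_pure_voxel(c(40, 48), 0.8, "wm")
  expect_equal(w$dm_wm, 55)
  expect_error(fit_pure_voxel(c(1, 2), 0), "mask")

  set.seed(91)
  y <- rnorm(30, 36, 5)
  pure <- fit_pure_voxel(y, 0.8, "gm")
  near <- fit_voxel(y, 0.8, 1e-6, voxel_params(pure$dm_gm, 0,
                                               pure$s_gm, 1),
                    em_config(max_iter = 300, tol = 1e-10,
                              stop_rule = "param_change"))
  expect_equal(near$params$dm_gm, pure$dm_gm, tolerance = 1e-3)
  expect_equal(near$params$s_gm, pure$s_gm, tolerance = 1e-2)
})

test_that("log-likelihood: closed form, ridge invariance, init-determined split", {
  fr <- tissue_fraction_volume(array(0.6, c(1, 1, 1)),
                               array(0.4, c(1, 1, 1)),
                               mask = array(TRUE, c(1, 1, 1)))
  sr <- difference_series(array(c(44, 44), c(1, 1, 1, 2)))
  maps <- sempvc:::new_param_maps(c(1, 1, 1))
  maps$dm_gm[1] <- 60; maps$dm_wm[1] <- 20
  maps$s_gm[1] <- 25; maps$s_wm[1] <- 25
  # both measurements sit at the model mean 44, variance 25
  expect_equal(compute_gaussian_loglik(sr, fr, maps)[1],
               2 * dnorm(44, 44, 5, log = TRUE))
  # ridge: shifts with p_gm*d_gm + p_wm*d_wm unchanged leave it invariant
  m2 <- maps
  eps <- 3
  m2$dm_gm[1] <- maps$dm_gm[1] + eps / 0.6
  m2$dm_wm[1] <- maps$dm_wm[1] - eps / 0.4
  expect_equal(compute_gaussian_loglik(sr, fr, maps)[1],
               compute_gaussian_loglik(sr, fr, m2)[1])

  # two inits on the ridge: same final likelihood, different splits
  set.seed(101)
  y <- rnorm(40, 44, 5)
  cfg <- em_config(max_iter = 300, tol = 1e-10, stop_rule = "param_change",
                   m_step_variant = "joint_update")
  f1 <- fit_voxel(y, 0.6, 0.4, voxel_params(60, 20, 25, 25), cfg)
  f2 <- fit_voxel(y, 0.6, 0.4, voxel_params(40, 50, 25, 25), cfg)
  expect_equal(oracle_loglik(y, f1$params, 0.6, 0.4),
               oracle_loglik(y, f2$params, 0.6, 0.4), tolerance = 1e-8)
  expect_gt(abs(f1$params$dm_gm - f2$params$dm_gm), 1)
})

test_that("joint_update EM ascends the observed-data likelihood", {
  set.seed(111)
  worst <- 0
  for (i in 1:100) {
    pg <- runif(1, 0.1, 0.9)
    pw <- runif(1, 0.05, 1 - pg)
    y <- rnorm(12, runif(1, 10, 70), runif(1, 2, 15))
    pars <- voxel_params(runif(1, 0, 90), runif(1, 0, 60),
                         runif(1, 1, 100), runif(1, 1, 100))
    ll_prev <- oracle_loglik(y, pars, pg, pw)
    for (it in 1:25) {
      pars <- m_step(e_step(y, pars, pg, pw), pars, pg, pw,
                     variant = "joint_update")
      ll <- oracle_loglik(y, pars, pg, pw)
      worst <- min(worst, ll - ll_prev)
      ll_prev <- ll
    }
  }
  expect_gte(worst, -1e-9)
})
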