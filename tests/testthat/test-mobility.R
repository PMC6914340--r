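test_that("MSD closed forms: stationary, ballistic, Brownian", {
  still <- as_track_set(data.frame(track_id = 1L, frame = 0:19,
                                   x_nm = 100, y_nm = 200, intensity = 1))
  msd0 <- compute_msd(still, max_lag = 5)
  expect_true(all(msd0$msd_nm2 == 0))

  ball <- ballistic_track(30, step_nm = 12)
  msd1 <- compute_msd(ball, max_lag = 6)
  expect_equal(msd1$msd_nm2, (msd1$lag * 12)^2)

  steps <- sample_mixture_steps(10000, 1, c(0.1, 0.1), dt = 0.032, seed = 3)
  # one long synthetic Brownian track from sampled steps
  ang <- smcotrack:::with_seed(4, stats::runif(10000, 0, 2 * pi))
  tr <- as_track_set(data.frame(track_id = 1L, frame = 0:10000,
                                x_nm = c(0, cumsum(steps * cos(ang))),
                                y_nm = c(0, cumsum(steps * sin(ang))),
                                intensity = 1))
  msd2 <- compute_msd(tr, max_lag = 4)
  expected <- 4 * 0.1 * msd2$t_s * 1e6
  expect_true(all(abs(msd2$msd_nm2 - expected) / expected < 0.05))

  expect_error(compute_msd(still, max_lag = 0), "max_lag")
})

test_that("MSD excludes lags spanning a gap", {
  df <- data.frame(track_id = 1L, frame = c(0L, 1L, 3L),
                   x_nm = c(0, 10, 30), y_nm = 0, intensity = 1)
  msd <- compute_msd(as_track_set(df), max_lag = 3)
  expect_identical(msd$n_pairs, c(1L, 1L, 1L))   # lags 1 (0->1), 2 (1->3), 3 (0->3)
  expect_equal(msd$msd_nm2, c(100, 400, 900))
})

test_that("diffusion fit recovers slope/4 and the localization-error intercept", {
  dt <- 0.032
  lags <- 1:10
  exact <- data.frame(lag = lags, t_s = lags * dt,
                      msd_nm2 = 4 * 0.1 * 1e6 * lags * dt, n_pairs = 100L)
  class(exact) <- c("msd_curve", "data.frame")
  de <- fit_diffusion_constant(exact)
  expect_equal(de$D_um2_s, 0.1, tolerance = 1e-12)
  expect_equal(de$intercept_nm2, 0, tolerance = 1e-6)

  # adding a constant 4 sigma^2 offset moves only the intercept
  exact$msd_nm2 <- exact$msd_nm2 + 4 * 30^2
  de2 <- fit_diffusion_constant(exact)
  expect_equal(de2$D_um2_s, 0.1, tolerance = 1e-12)
  expect_equal(de2$intercept_nm2, 3600, tolerance = 1e-6)

  expect_error(fit_diffusion_constant(exact, lag_range = c(11, 12)), "usable lags")
  exact$msd_nm2 <- 100 - exact$msd_nm2
  expect_warning(de3 <- fit_diffusion_constant(exact), "negative")
  expect_identical(de3$D_um2_s, 0)
  expect_true(de3$negative_slope)
})

test_that("diffusion estimates are invariant under rigid motions", {
  cfg <- sim_config(n_receptors = 80, n_frames = 80, d_monomer = 0.12,
                    roi_width_um = 40, roi_height_um = 40, sigma_loc_nm = 20,
                    dimer_fraction = 0, seed = 17)
  loc <- render_localizations(simulate_membrane(cfg))
  tr <- filter_min_steps(link_localizations(loc$a), 10)
  d0 <- fit_diffusion_constant(compute_msd(tr))$D_um2_s
  th <- 0.7
  rot <- tr
  x <- tr$x_nm; y <- tr$y_nm
  rot$x_nm <- cos(th) * x - sin(th) * y + 5000
  rot$y_nm <- sin(th) * x + cos(th) * y - 2000
  d1 <- fit_diffusion_constant(compute_msd(rot))$D_um2_s
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("step-length mixture EM recovers single and two-component truths", {
  # single component, alpha forced 1
  st1 <- sample_mixture_steps(10000, 1, c(0.1, 0.1), dt = 0.032, seed = 51)
  fit1 <- fit_step_length_mixture(st1, dt = 0.032, components = 1)
  expect_identical(fit1$alpha, 1)
  expect_lt(abs(fit1$D_um2_s - 0.1) / 0.1, 0.05)

  # two components
  st2 <- sample_mixture_steps(10000, 0.7, c(0.15, 0.02), dt = 0.032, seed = 52)
  fit2 <- fit_step_length_mixture(st2, dt = 0.032, seed = 52)
  expect_true(fit2$converged)
  expect_lt(abs(fit2$alpha - 0.7), 0.1)
  expect_lt(abs(fit2$D_um2_s[1] - 0.15) / 0.15, 0.2)
  expect_lt(abs(fit2$D_um2_s[2] - 0.02) / 0.02, 0.2)
  expect_gte(fit2$D_um2_s[1], fit2$D_um2_s[2])
  # EM log-likelihood is non-decreasing across iterations
  expect_true(all(diff(fit2$loglik_trace) > -1e-6))

  # degenerate equal components: unidentifiable alpha is flagged
  expect_warning(fit_step_length_mixture(st1, dt = 0.032, seed = 53),
                 "unidentifiable")

  expect_error(fit_step_length_mixture(c(-1, 2, 3), dt = 0.032), "positive")
  expect_error(fit_step_length_mixture(st1, dt = 0), "dt")
  expect_warning(fit_step_length_mixture(st1[1:10], dt = 0.032, components = 1),
                 "unstable")
})

test_that("immobile tracks are flagged by clustering, mobile ones are not", {
  set.seed(61)
  jitter_track <- data.frame(track_id = 1L, frame = 0:149,
                             x_nm = stats::rnorm(150, 0, 8),
                             y_nm = stats::rnorm(150, 0, 8), intensity = 1)
  steps <- sample_mixture_steps(149, 1, c(0.1, 0.1), dt = 0.032, seed = 62)
  ang <- stats::runif(149, 0, 2 * pi)
  fast_track <- data.frame(track_id = 2L, frame = 0:149,
                           x_nm = c(0, cumsum(steps * cos(ang))) + 5e4,
                           y_nm = c(0, cumsum(steps * sin(ang))), intensity = 1)
  flags <- find_immobile(as_track_set(rbind(jitter_track, fast_track)),
                         eps_nm = 50, min_pts = 5)
  expect_identical(unname(flags), c(TRUE, FALSE))
  expect_identical(length(find_immobile(as_track_set(
    data.frame(track_id = integer(0), frame = integer(0), x_nm = numeric(0),
               y_nm = numeric(0), intensity = numeric(0))))), 0L)
})

test_that("bleach-step counting finds downward level changes", {
  expect_identical(count_bleach_steps(c(rep(2, 40), rep(1, 40), rep(0, 70)))$n_steps,
                   2L)
  expect_identical(count_bleach_steps(rep(5, 60))$n_steps, 0L)
  expect_error(count_bleach_steps(rep(NaN, 10)), "all-NA|non-finite")
  expect_error(count_bleach_steps(c(1, 2)), "at least 3")

  # known change point at SNR 5: correct in >= 95% of replicates
  set.seed(63)
  hits <- replicate(200, {
    t0 <- sample(20:130, 1)
    trc <- c(rep(1, t0), rep(0, 150 - t0)) + stats::rnorm(150, 0, 0.2)
    r <- count_bleach_steps(trc)
    r$n_steps == 1 && abs(r$change_points[1] - (t0 + 1)) <= 2
  })
  expect_gte(mean(hits), 0.95)
})

test_that("mixture-informed slow fraction tracks the dimer fraction across scenarios", {
  # with dimers slower than monomers, the fitted slow fraction is monotone in
  # the true dimer fraction (qualitative mobility-shift readout)
  fr <- c(0.1, 0.5, 0.9)
  alphas <- vapply(seq_along(fr), function(i) {
    cfg <- sim_config(n_receptors = 300, n_frames = 60, dimer_fraction = fr[i],
                      d_monomer = 0.15, d_dimer = 0.02,
                      roi_width_um = 35, roi_height_um = 35, seed = 70 + i)
    loc <- render_localizations(simulate_membrane(cfg))
    steps <- c(step_lengths(filter_min_steps(link_localizations(loc$a), 5)),
               step_lengths(filter_min_steps(link_localizations(loc$b), 5)))
    fit <- fit_step_length_mixture(steps, dt = 0.032, seed = 1)
    1 - fit$alpha          # slow-component weight
  }, numeric(1))
  expect_true(all(diff(alphas) > 0))
})
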