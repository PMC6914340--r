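test_that("configuration validation rejects mode/parameter mismatches", {
  expect_error(sim_config(dimer_fraction = 1.2), "dimer_fraction")
  expect_error(sim_config(p_label_a = 0.6, p_label_b = 0.6), "exceed")
  expect_error(sim_config(k_on_2d = 0.1), "static_fraction")
  expect_error(sim_config(mode = "kinetic", k_on_2d = 0.1), "requires both")
  expect_error(sim_config(mode = "kinetic", k_on_2d = 0.1, k_off = 1,
                          dimer_fraction = 0.5), "kinetic mode")
  cfg <- sim_config()
  expect_identical(cfg$frame_time_s, 0.032)
  expect_identical(cfg$n_frames, 150L)
})

test_that("static mode realizes the requested dimer fraction and pair geometry", {
  gt0 <- simulate_membrane(small_cfg(dimer_fraction = 0))
  expect_true(all(is.na(gt0$positions$partner_id)))
  expect_true(all(gt0$dimer_fraction_by_frame == 0))

  cfg <- sim_config(n_receptors = 200, dimer_fraction = 0.4, n_frames = 25, seed = 5)
  gt <- simulate_membrane(cfg)
  expect_equal(gt$dimer_fraction_by_frame, rep(0.4, 25))
  pos <- gt$positions
  # partner relation symmetric and irreflexive
  paired <- pos[!is.na(pos$partner_id), ]
  expect_true(all(paired$partner_id != paired$molecule_id))
  key <- paste(paired$frame, paired$molecule_id, paired$partner_id)
  rev <- paste(paired$frame, paired$partner_id, paired$molecule_id)
  expect_true(all(rev %in% key))
  # co-diffusing unit: partners share one true position in every frame
  idx <- match(rev, key)
  expect_equal(paired$x_nm, paired$x_nm[idx])
  expect_equal(paired$y_nm, paired$y_nm[idx])
  # reflective boundaries keep positions inside the ROI
  expect_true(all(pos$x_nm >= 0 & pos$x_nm <= cfg$roi_width_um * 1000))
  expect_true(all(pos$y_nm >= 0 & pos$y_nm <= cfg$roi_height_um * 1000))
})

test_that("simulations are bit-identical under one seed and differ across seeds", {
  a <- simulate_membrane(small_cfg(dimer_fraction = 0.3))
  b <- simulate_membrane(small_cfg(dimer_fraction = 0.3))
  expect_identical(a$positions, b$positions)
  c <- simulate_membrane(sim_config(n_receptors = 40, n_frames = 30,
                                    dimer_fraction = 0.3, seed = 100))
  expect_false(identical(a$positions$x_nm, c$positions$x_nm))
})

test_that("monomer ensemble MSD follows the Brownian closed form", {
  # ~40k steps; MSD(t) = 4 D t within 5%
  cfg <- sim_config(n_receptors = 400, n_frames = 100, d_monomer = 0.1,
                    roi_width_um = 60, roi_height_um = 60,
                    dimer_fraction = 0, sigma_loc_nm = 0, seed = 21)
  gt <- simulate_membrane(cfg)
  tr <- as_track_set(data.frame(track_id = gt$positions$molecule_id,
                                frame = gt$positions$frame,
                                x_nm = gt$positions$x_nm,
                                y_nm = gt$positions$y_nm,
                                intensity = 0))
  msd <- compute_msd(tr, max_lag = 5, frame_time_s = cfg$frame_time_s)
  expected <- 4 * 0.1 * msd$t_s * 1e6       # nm^2
  expect_true(all(abs(msd$msd_nm2 - expected) / expected < 0.05))
})

test_that("kinetic mode: no association without k_on, mean-field fixed point otherwise", {
  gt0 <- simulate_membrane(sim_config(mode = "kinetic", k_on_2d = 0, k_off = 1,
                                      n_receptors = 60, n_frames = 40, seed = 3))
  expect_true(all(gt0$dimer_fraction_by_frame == 0))

  cfg <- sim_config(mode = "kinetic", k_on_2d = 0.05, k_off = 0.2,
                    n_frames = 2000, seed = 2)
  gt <- simulate_membrane(cfg)
  observed <- mean(gt$dimer_fraction_by_frame[1001:2000])
  oracle <- meanfield_dimer_fraction(
    n = cfg$n_receptors, area_um2 = cfg$roi_width_um * cfg$roi_height_um,
    capture_radius_um = cfg$capture_radius_nm / 1000,
    k_on_2d = cfg$k_on_2d, k_off = cfg$k_off, dt = cfg$frame_time_s)
  # Monte-Carlo + short-range pair-depletion slack around the mean-field value
  expect_lt(abs(observed - oracle) / oracle, 0.20)
})

test_that("kinetic mode: mean pair lifetime approximates 1/k_off", {
  cfg <- sim_config(mode = "kinetic", k_on_2d = 0.2, k_off = 1,
                    n_frames = 1500, seed = 8)
  gt <- simulate_membrane(cfg)
  pos <- gt$positions
  paired <- !is.na(pos$partner_id)
  # measure bout lengths of the paired state per molecule
  bouts <- unlist(lapply(split(paired, pos$molecule_id), function(z) {
    r <- rle(z); r$lengths[r$values]
  }), use.names = FALSE)
  expect_gt(length(bouts), 100)
  mean_lifetime_s <- mean(bouts) * cfg$frame_time_s
  expect_lt(abs(mean_lifetime_s - 1 / cfg$k_off), 0.25 / cfg$k_off)
})

test_that("rendering reproduces truth exactly in the noise-free limit", {
  cfg <- sim_config(n_receptors = 30, n_frames = 20, sigma_loc_nm = 0,
                    detection_eff = 1, bleach_rate = 0,
                    p_label_a = 1, p_label_b = 0, dimer_fraction = 0, seed = 4)
  gt <- simulate_membrane(cfg)
  loc <- render_localizations(gt, cfg)
  expect_identical(nrow(loc$b), 0L)
  expect_identical(nrow(loc$a), nrow(gt$positions))
  ord <- order(loc$a$frame, loc$a$molecule_id)
  ord_gt <- order(gt$positions$frame, gt$positions$molecule_id)
  expect_equal(loc$a$x_nm[ord], gt$positions$x_nm[ord_gt])
  expect_equal(loc$a$y_nm[ord], gt$positions$y_nm[ord_gt])
})

test_that("labeling and detection follow the binomial model", {
  # balanced labeling without dark fraction: half of all dimers are two-color
  cfg <- sim_config(n_receptors = 10000, n_frames = 1, dimer_fraction = 1,
                    p_label_a = 0.5, p_label_b = 0.5,
                    roi_width_um = 100, roi_height_um = 100, seed = 6)
  gt <- simulate_membrane(cfg)
  loc <- render_localizations(gt, cfg)
  sp <- loc$labels$species
  pos <- gt$positions
  lead <- pos[!is.na(pos$partner_id) & pos$molecule_id < pos$partner_id, ]
  two_color <- sp[lead$molecule_id] != sp[lead$partner_id]
  expect_lt(abs(mean(two_color) - 0.5), 0.02)

  # detection efficiency thins localizations binomially
  cfg2 <- sim_config(n_receptors = 10000, n_frames = 3, dimer_fraction = 0,
                     detection_eff = 0.8, p_label_a = 1, p_label_b = 0,
                     roi_width_um = 100, roi_height_um = 100, seed = 7)
  loc2 <- render_localizations(simulate_membrane(cfg2), cfg2)
  per_frame <- table(loc2$a$frame)
  expect_true(all(abs(per_frame / 10000 - 0.8) < 0.02))
})

test_that("fiducial bead rendering realizes the requested transform", {
  b0 <- simulate_fiducial_beads(10, affine2d(), noise_nm = 0, seed = 1)
  expect_equal(b0$xa, b0$xb)
  expect_equal(b0$ya, b0$yb)
  tt <- affine2d(diag(2), c(50, -20))
  b1 <- simulate_fiducial_beads(10, tt, noise_nm = 0, seed = 1)
  expect_equal(b1$xb, b1$xa + 50)
  expect_equal(b1$yb, b1$ya - 20)
  expect_error(simulate_fiducial_beads(0), "n_beads")
})

test_that("intensity traces are stepwise with geometric bleach times", {
  tr <- simulate_intensity_trace(2, bleach_rate = 0.05, noise_sd = 0,
                                 n_frames = 400, seed = 42)
  expect_true(all(tr %in% c(2, 1, 0)))
  expect_identical(sum(diff(tr) < 0), 2L)
  expect_true(all(diff(tr) <= 0))   # bleaching is irreversible

  z <- simulate_intensity_trace(0, 0.05, noise_sd = 0, n_frames = 50, seed = 1)
  expect_true(all(z == 0))

  # mean bleach frame of a single fluorophore ~ 1/rate
  first_dark <- vapply(1:400, function(s)
    attr(simulate_intensity_trace(1, 0.05, 0, 600, seed = s), "bleach_frames")[1],
    numeric(1))
  expect_lt(abs(mean(first_dark - 1) - 20), 2)
})

test_that("affinity series construction is labelled, ordered and reproducible", {
  base <- small_cfg()
  ser <- make_affinity_series(base, c(0, 0.05, 0.15, 0.45, 0.5),
                              c("unstim", "A1", "C7", "Mut3", "HyIL6"))
  expect_named(ser, c("unstim", "A1", "C7", "Mut3", "HyIL6"))
  expect_identical(vapply(ser, `[[`, numeric(1), "dimer_fraction"),
                   c(unstim = 0, A1 = 0.05, C7 = 0.15, Mut3 = 0.45, HyIL6 = 0.5))
  expect_identical(length(make_affinity_series(base, numeric(0), character(0))), 0L)
  ser2 <- make_affinity_series(base, c(0, 0.05, 0.15, 0.45, 0.5),
                               c("unstim", "A1", "C7", "Mut3", "HyIL6"))
  expect_identical(ser$HyIL6$loc_a, ser2$HyIL6$loc_a)
  expect_error(make_affinity_series(base, c(0.5, 1.5)), "\\[0, 1\\]")
})
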