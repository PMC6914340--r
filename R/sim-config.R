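#' Simulation configuration for membrane monomer-dimer dynamics
#'
#' Bundles the generative parameters of the membrane simulator: field of view,
#' receptor number, monomer and dimer diffusion constants, the dimerization
#' model (a fixed dimer fraction or explicit association/dissociation
#' kinetics), acquisition settings, stochastic two-color labeling, and the
#' measurement model (localization error, detection efficiency, bleaching).
#'
#' Defaults reflect a sparse single-molecule TIRF acquisition: 150 frames at
#' 32 ms/frame over a 20 x 20 um field of view at 0.5 receptors/um^2, balanced
#' two-color labeling with probability 0.45 per species (10% of receptors
#' unlabeled), and 25 nm localization precision.
#'
#' @param roi_width_um,roi_height_um field of view size in micrometers.
#' @param n_receptors number of receptor molecules in the field of view.
#' @param d_monomer,d_dimer diffusion constants (um^2/s); dimers diffuse as a
#'   single unit, typically slower than monomers.
#' @param mode `"static_fraction"` (a fixed fraction of receptors is dimeric
#'   for the whole movie) or `"kinetic"` (per-frame association/dissociation).
#' @param dimer_fraction fraction of receptor molecules residing in dimers
#'   (static mode only).
#' @param k_on_2d two-dimensional association rate constant (um^2/s; kinetic
#'   mode only).
#' @param k_off dissociation rate (1/s; kinetic mode only); `1/k_off` is the
#'   mean complex dwell time.
#' @param capture_radius_nm distance below which a monomer pair is an
#'   association candidate (kinetic mode; a simulator knob, not a measured
#'   quantity).
#' @param frame_time_s exposure interval in seconds.
#' @param n_frames number of frames in the movie.
#' @param p_label_a,p_label_b per-receptor probability of carrying a label of
#'   species A resp. B; the remainder is dark. `p_label_a + p_label_b <= 1`.
#' @param sigma_loc_nm localization error standard deviation per axis (nm).
#' @param detection_eff per-frame probability that a labeled, unbleached
#'   molecule is detected.
#' @param bleach_rate per-frame probability that an active fluorophore
#'   bleaches (irreversibly).
#' @param boundary `"reflective"` (default; keeps density constant) or
#'   `"periodic"`.
#' @param seed RNG seed; all stochastic stages derive their streams from it.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(dimer_fraction = 0.3, seed = 1)
#' cfg$n_frames
#' @export
sim_config <- function(roi_width_um = 20,
                       roi_height_um = 20,
                       n_receptors = 200,
                       d_monomer = 0.15,
                       d_dimer = 0.05,
                       mode = c("static_fraction", "kinetic"),
                       dimer_fraction = 0,
                       k_on_2d = NULL,
                       k_off = NULL,
                       capture_radius_nm = 100,
                       frame_time_s = 0.032,
                       n_frames = 150,
                       p_label_a = 0.45,
                       p_label_b = 0.45,
                       sigma_loc_nm = 25,
                       detection_eff = 1,
                       bleach_rate = 0,
                       boundary = c("reflective", "periodic"),
                       seed = 1) {
  mode <- match.arg(mode)
  boundary <- match.arg(boundary)
  num1 <- function(x, name, min = 0) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min)
      stopf("'%s' must be a single finite number >= %g", name, min)
    as.numeric(x)
  }
  cfg <- list(
    roi_width_um = num1(roi_width_um, "roi_width_um"),
    roi_height_um = num1(roi_height_um, "roi_height_um"),
    n_receptors = as.integer(num1(n_receptors, "n_receptors")),
    d_monomer = num1(d_monomer, "d_monomer"),
    d_dimer = num1(d_dimer, "d_dimer"),
    mode = mode,
    dimer_fraction = num1(dimer_fraction, "dimer_fraction"),
    k_on_2d = if (!is.null(k_on_2d)) num1(k_on_2d, "k_on_2d"),
    k_off = if (!is.null(k_off)) num1(k_off, "k_off"),
    capture_radius_nm = num1(capture_radius_nm, "capture_radius_nm"),
    frame_time_s = num1(frame_time_s, "frame_time_s"),
    n_frames = as.integer(num1(n_frames, "n_frames", min = 1)),
    p_label_a = num1(p_label_a, "p_label_a"),
    p_label_b = num1(p_label_b, "p_label_b"),
    sigma_loc_nm = num1(sigma_loc_nm, "sigma_loc_nm"),
    detection_eff = num1(detection_eff, "detection_eff"),
    bleach_rate = num1(bleach_rate, "bleach_rate"),
    boundary = boundary,
    seed = if (!is.null(seed)) as.integer(seed)
  )
  if (cfg$dimer_fraction > 1) stopf("'dimer_fraction' must lie in [0, 1]")
  if (cfg$p_label_a + cfg$p_label_b > 1 + 1e-12)
    stopf("p_label_a + p_label_b must not exceed 1")
  if (cfg$detection_eff > 1) stopf("'detection_eff' must lie in [0, 1]")
  if (cfg$bleach_rate > 1) stopf("'bleach_rate' must lie in [0, 1]")
  if (mode == "static_fraction" && (!is.null(cfg$k_on_2d) || !is.null(cfg$k_off)))
    stopf("kinetic parameters (k_on_2d, k_off) are not valid in static_fraction mode")
  if (mode == "kinetic") {
    if (is.null(cfg$k_on_2d) || is.null(cfg$k_off))
      stopf("kinetic mode requires both k_on_2d and k_off")
    if (cfg$dimer_fraction != 0)
      stopf("dimer_fraction is not valid in kinetic mode (simulations start all-monomeric)")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$mode, "\n")
  cat(sprintf("  ROI %g x %g um, %d receptors, %d frames @ %g ms\n",
              x$roi_width_um, x$roi_height_um, x$n_receptors,
              x$n_frames, x$frame_time_s * 1000))
  cat(sprintf("  D(monomer) = %g, D(dimer) = %g um^2/s\n",
              x$d_monomer, x$d_dimer))
  if (x$mode == "static_fraction") {
    cat(sprintf("  dimer_fraction = %g\n", x$dimer_fraction))
  } else {
    cat(sprintf("  k_on_2d = %g um^2/s, k_off = %g /s (dwell %.2g s)\n",
                x$k_on_2d, x$k_off, 1 / x$k_off))
  }
  cat(sprintf("  labels: p(A) = %g, p(B) = %g, dark = %g; sigma_loc = %g nm\n",
              x$p_label_a, x$p_label_b, 1 - x$p_label_a - x$p_label_b,
              x$sigma_loc_nm))
  cat(sprintf("  detection_eff = %g, bleach_rate = %g, boundary = %s, seed = %s\n",
              x$detection_eff, x$bleach_rate, x$boundary,
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}
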