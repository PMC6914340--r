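#' Simulate membrane monomer-dimer dynamics
#'
#' Monte-Carlo simulation of receptors diffusing in the plasma membrane.
#' Monomers perform 2D Brownian motion with diffusion constant `d_monomer`;
#' dimers diffuse as a single unit (both partners at the same true position)
#' with `d_dimer`. Per-frame displacements are Gaussian with standard
#' deviation `sqrt(2 * D * dt)` per axis. In `static_fraction` mode a fixed
#' set of receptor pairs is dimeric for the whole movie; in `kinetic` mode
#' monomer pairs closer than the capture radius associate with per-frame
#' probability `1 - exp(-k_on_2d * dt / (pi * r_c^2))` and dimers dissociate
#' with probability `1 - exp(-k_off * dt)`. On dissociation the partners are
#' placed two capture radii apart to avoid immediate geminate recapture.
#'
#' @param config a [sim_config()].
#' @return a `ground_truth` object: a list with `positions` (data.frame of
#'   `frame` (0-based), `molecule_id`, `partner_id` (`NA` for monomers),
#'   `x_nm`, `y_nm`), `dimer_fraction_by_frame`, and the `config`.
#' @examples
#' gt <- simulate_membrane(sim_config(n_receptors = 50, dimer_fraction = 0.4,
#'                                    n_frames = 20, seed = 7))
#' head(gt$positions)
#' @export
simulate_membrane <- function(config) {
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  with_seed(child_seed(config$seed, 1L), simulate_membrane_impl(config))
}

simulate_membrane_impl <- function(config) {
  n <- config$n_receptors
  w <- config$roi_width_um
  h <- config$roi_height_um
  dt <- config$frame_time_s
  nf <- config$n_frames
  sd_mono <- sqrt(2 * config$d_monomer * dt)
  sd_dim <- sqrt(2 * config$d_dimer * dt)
  rc <- config$capture_radius_nm / 1000      # um

  x <- stats::runif(n, 0, w)
  y <- stats::runif(n, 0, h)
  partner <- rep(NA_integer_, n)

  if (config$mode == "static_fraction" && n >= 2) {
    n_pairs <- round(n * config$dimer_fraction / 2)
    if (n_pairs > 0) {
      members <- sample.int(n, 2L * n_pairs)
      i1 <- members[seq_len(n_pairs)]
      i2 <- members[n_pairs + seq_len(n_pairs)]
      partner[i1] <- i2
      partner[i2] <- i1
      x[i2] <- x[i1]; y[i2] <- y[i1]
    }
  }

  p_off <- if (config$mode == "kinetic") 1 - exp(-config$k_off * dt) else 0
  p_on <- if (config$mode == "kinetic")
    1 - exp(-config$k_on_2d * dt / (pi * rc^2)) else 0

  reflect <- function(z, lim) {
    # fold into [0, lim] (handles multiple reflections)
    z <- z %% (2 * lim)
    ifelse(z > lim, 2 * lim - z, z)
  }
  wrap <- function(z, lim) z %% lim

  pos_x <- matrix(NA_real_, nf, n)
  pos_y <- matrix(NA_real_, nf, n)
  part_rec <- matrix(NA_integer_, nf, n)

  record <- function(t) {
    pos_x[t, ] <<- x
    pos_y[t, ] <<- y
    part_rec[t, ] <<- partner
  }
  record(1L)

  if (nf > 1L) for (t in 2:nf) {
    # move diffusing units: each monomer and each pair-leader draws one step
    leader <- is.na(partner) | seq_len(n) < partner
    idx <- which(leader)
    sds <- ifelse(is.na(partner[idx]), sd_mono, sd_dim)
    dx <- stats::rnorm(length(idx), 0, sds)
    dy <- stats::rnorm(length(idx), 0, sds)
    x[idx] <- x[idx] + dx
    y[idx] <- y[idx] + dy
    followers <- idx[!is.na(partner[idx])]
    x[partner[followers]] <- x[followers]
    y[partner[followers]] <- y[followers]
    if (config$boundary == "reflective") {
      x <- reflect(x, w); y <- reflect(y, h)
    } else {
      x <- wrap(x, w); y <- wrap(y, h)
    }

    if (config$mode == "kinetic") {
      # dissociation
      leaders <- which(!is.na(partner) & seq_len(n) < partner)
      if (length(leaders)) {
        off <- leaders[stats::runif(length(leaders)) < p_off]
        for (i in off) {
          j <- partner[i]
          ang <- stats::runif(1, 0, 2 * pi)
          sep <- rc         # each partner rc from center: 2*rc apart
          x[i] <- x[i] + sep * cos(ang); y[i] <- y[i] + sep * sin(ang)
          x[j] <- x[j] - sep * cos(ang); y[j] <- y[j] - sep * sin(ang)
          partner[i] <- NA_integer_; partner[j] <- NA_integer_
        }
        if (config$boundary == "reflective") {
          x <- reflect(x, w); y <- reflect(y, h)
        } else {
          x <- wrap(x, w); y <- wrap(y, h)
        }
      }
      # association among current monomers
      mono <- which(is.na(partner))
      if (length(mono) >= 2) {
        d <- as.matrix(stats::dist(cbind(x[mono], y[mono])))
        d[lower.tri(d, diag = TRUE)] <- Inf
        cand <- which(d <= rc, arr.ind = TRUE)
        if (nrow(cand)) {
          ord <- order(d[cand])
          cand <- cand[ord, , drop = FALSE]
          taken <- rep(FALSE, length(mono))
          for (r in seq_len(nrow(cand))) {
            a <- cand[r, 1]; b <- cand[r, 2]
            if (taken[a] || taken[b]) next
            if (stats::runif(1) < p_on) {
              taken[a] <- TRUE; taken[b] <- TRUE
              i <- mono[a]; j <- mono[b]
              partner[i] <- j; partner[j] <- i
              mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
              x[i] <- mx; x[j] <- mx; y[i] <- my; y[j] <- my
            }
          }
        }
      }
    }
    record(t)
  }

  positions <- data.frame(
    frame = rep(0:(nf - 1L), each = n),
    molecule_id = rep(seq_len(n), times = nf),
    partner_id = as.integer(t(part_rec)),
    x_nm = as.numeric(t(pos_x)) * 1000,
    y_nm = as.numeric(t(pos_y)) * 1000
  )
  dimer_frac <- rowMeans(!is.na(part_rec))
  structure(list(positions = positions,
                 dimer_fraction_by_frame = dimer_frac,
                 config = config),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  nf <- x$config$n_frames
  cat(sprintf("ground_truth: %d molecules x %d frames (%s mode)\n",
              x$config$n_receptors, nf, x$config$mode))
  cat(sprintf("  mean true dimer fraction: %.3f\n",
              mean(x$dimer_fraction_by_frame)))
  invisible(x)
}

#' Render two-color localization streams from ground truth
#'
#' The measurement model of the simulator. Each receptor is stochastically and
#' permanently assigned a label: species A with probability `p_label_a`,
#' species B with `p_label_b`, otherwise dark. Fluorophores bleach
#' irreversibly with per-frame probability `bleach_rate`; a labeled, unbleached
#' molecule is detected in a frame with probability `detection_eff`, at its
#' true position plus isotropic Gaussian localization error of SD
#' `sigma_loc_nm`. Note that both members of a dimer carrying two same-species
#' labels yield two (nearly coincident) localizations, as two fluorophores do.
#'
#' @param truth a `ground_truth` from [simulate_membrane()].
#' @param config the [sim_config()] used to generate `truth` (or a modified
#'   copy sharing its geometry).
#' @return list with `a` and `b` ([localization_table()] per channel, carrying
#'   a ground-truth `molecule_id` column) and `labels` (data.frame
#'   `molecule_id`, `species`, `bleach_frame`; `bleach_frame` is the 0-based
#'   first frame in which the fluorophore is dark, `Inf` if it never bleaches).
#' @export
render_localizations <- function(truth, config = truth$config) {
  if (!inherits(truth, "ground_truth")) stopf("'truth' must be a ground_truth")
  if (!inherits(config, "sim_config")) stopf("'config' must be a sim_config")
  with_seed(child_seed(config$seed, 2L), {
    n <- config$n_receptors
    species <- sample(c("A", "B", "dark"), n, replace = TRUE,
                      prob = c(config$p_label_a, config$p_label_b,
                               max(0, 1 - config$p_label_a - config$p_label_b)))
    bleach_frame <- if (config$bleach_rate > 0) {
      stats::rgeom(n, config$bleach_rate) + 1
    } else rep(Inf, n)
    bleach_frame[species == "dark"] <- NA_real_

    pos <- truth$positions
    sp <- species[pos$molecule_id]
    active <- sp != "dark" & pos$frame < ifelse(is.na(bleach_frame[pos$molecule_id]),
                                                Inf, bleach_frame[pos$molecule_id])
    detected <- active & stats::runif(nrow(pos)) < config$detection_eff
    make_table <- function(ch) {
      rows <- pos[detected & sp == ch, , drop = FALSE]
      m <- nrow(rows)
      localization_table(
        frame = rows$frame,
        x_nm = rows$x_nm + stats::rnorm(m, 0, config$sigma_loc_nm),
        y_nm = rows$y_nm + stats::rnorm(m, 0, config$sigma_loc_nm),
        intensity = stats::rnorm(m, 1000, 100),
        channel = ch,
        registered = TRUE,           # both streams are born in one frame
        molecule_id = rows$molecule_id
      )
    }
    list(a = make_table("A"), b = make_table("B"),
         labels = data.frame(molecule_id = seq_len(n), species = species,
                             bleach_frame = bleach_frame))
  })
}

#' Simulate paired fiducial bead localizations for channel registration
#'
#' Renders the same physical bead positions in both spectral channels: channel
#' A observes the true positions, channel B observes them mapped through
#' `true_transform` plus Gaussian localization noise, so the registration
#' residual RMS converges to `noise_nm` for large bead counts.
#'
#' @param n_beads number of beads (>= 3 for a full affine fit downstream).
#' @param true_transform an [affine2d()] mapping channel A coordinates to
#'   channel B; identity by default.
#' @param noise_nm localization noise SD per axis (nm).
#' @param seed RNG seed.
#' @param roi_width_um,roi_height_um field of view (um).
#' @return data.frame with columns `xa`, `ya`, `xb`, `yb` (nm), suitable for
#'   [fit_affine()].
#' @export
simulate_fiducial_beads <- function(n_beads, true_transform = affine2d(),
                                    noise_nm = 0, seed = NULL,
                                    roi_width_um = 20, roi_height_um = 20) {
  if (n_beads < 1) stopf("'n_beads' must be at least 1")
  with_seed(seed, {
    px <- stats::runif(n_beads, 0, roi_width_um * 1000)
    py <- stats::runif(n_beads, 0, roi_height_um * 1000)
    b <- apply_transform(cbind(px, py), true_transform)
    data.frame(
      xa = px,
      ya = py,
      xb = b[, 1] + stats::rnorm(n_beads, 0, noise_nm),
      yb = b[, 2] + stats::rnorm(n_beads, 0, noise_nm)
    )
  })
}

#' Simulate a single-spot photobleaching intensity trace
#'
#' Piecewise-constant trace with unit intensity per active fluorophore.
#' Each fluorophore survives a geometric number of frames (per-frame bleaching
#' probability `bleach_rate`) and then switches off irreversibly; Gaussian
#' noise is added to every frame. Used to emulate stepwise bleaching of
#' receptor dimers for stoichiometry counting.
#'
#' @param n_fluorophores number of fluorophores in the spot (>= 0).
#' @param bleach_rate per-frame bleaching probability (0 = no bleaching).
#' @param noise_sd additive Gaussian noise SD (units of one fluorophore).
#' @param n_frames trace length.
#' @param seed RNG seed.
#' @return numeric intensity trace of length `n_frames` with attribute
#'   `bleach_frames` (1-based first dark frame of each fluorophore).
#' @export
simulate_intensity_trace <- function(n_fluorophores, bleach_rate,
                                     noise_sd = 0, n_frames = 150,
                                     seed = NULL) {
  if (n_fluorophores < 0) stopf("'n_fluorophores' must be >= 0")
  with_seed(seed, {
    lifetimes <- if (n_fluorophores == 0) numeric(0)
      else if (bleach_rate > 0) stats::rgeom(n_fluorophores, bleach_rate) + 1
      else rep(Inf, n_fluorophores)
    t_idx <- seq_len(n_frames)
    level <- vapply(t_idx, function(t) sum(lifetimes >= t), numeric(1))
    trace <- level + stats::rnorm(n_frames, 0, noise_sd)
    attr(trace, "bleach_frames") <- sort(lifetimes + 1)
    trace
  })
}

#' Build a ligand-affinity scenario series
#'
#' Maps a series of true dimer fractions (emulating ligands of decreasing
#' receptor-dimerization potency) to simulated scenario bundles: ground truth
#' plus the two rendered localization streams. Scenario `i` uses a seed
#' derived deterministically from `base_config$seed` and `i`, so the whole
#' series is reproducible from one base seed while scenarios stay independent.
#'
#' @param base_config a [sim_config()] in `static_fraction` mode; its
#'   `dimer_fraction` is overridden per scenario.
#' @param dimer_fractions numeric vector of true dimer fractions in `[0, 1]`.
#' @param labels optional scenario names (default `"scenario_<i>"`).
#' @return named list of bundles, each a list with `label`, `dimer_fraction`,
#'   `config`, `truth`, `loc_a`, `loc_b`.
#' @export
make_affinity_series <- function(base_config, dimer_fractions, labels = NULL) {
  if (!inherits(base_config, "sim_config")) stopf("'base_config' must be a sim_config")
  if (base_config$mode != "static_fraction")
    stopf("affinity series requires static_fraction mode")
  if (any(dimer_fractions < 0 | dimer_fractions > 1))
    stopf("dimer fractions must lie in [0, 1]")
  if (is.null(labels)) labels <- sprintf("scenario_%d", seq_along(dimer_fractions))
  if (length(labels) != length(dimer_fractions))
    stopf("'labels' must match 'dimer_fractions' in length")
  out <- vector("list", length(dimer_fractions))
  names(out) <- labels
  for (i in seq_along(dimer_fractions)) {
    cfg <- base_config
    cfg$dimer_fraction <- dimer_fractions[i]
    cfg$seed <- as.integer(child_seed(base_config$seed, 100L + i))
    truth <- simulate_membrane(cfg)
    loc <- render_localizations(truth, cfg)
    out[[i]] <- list(label = labels[i], dimer_fraction = dimer_fractions[i],
                     config = cfg, truth = truth,
                     loc_a = loc$a, loc_b = loc$b)
  }
  out
}
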