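# Independent oracles used across tests.

# Exhaustive maximum-cardinality, minimum-total-distance one-to-one matching
# between two small point sets under a distance gate.
brute_force_match <- function(xy1, xy2, gate, squared = FALSE) {
  m <- nrow(xy1); n <- nrow(xy2)
  d <- sqrt(outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2)
  w <- if (squared) d^2 else d
  best <- list(card = 0L, tot = 0)
  rec <- function(i, used, card, tot) {
    if (i > m) {
      if (card > best$card || (card == best$card && tot < best$tot - 1e-12))
        best <<- list(card = card, tot = tot)
      return()
    }
    rec(i + 1L, used, card, tot)
    for (j in seq_len(n)) {
      if (!used[j] && d[i, j] <= gate)
        rec(i + 1L, replace(used, j, TRUE), card + 1L, tot + w[i, j])
    }
  }
  rec(1L, rep(FALSE, n), 0L, 0)
  best
}

# Deterministic mean-field recursion for the kinetic simulator's per-frame
# association/dissociation scheme; returns the fixed-point fraction of
# molecules residing in pairs.
meanfield_dimer_fraction <- function(n, area_um2, capture_radius_um,
                                     k_on_2d, k_off, dt, iters = 10000) {
  p_on <- 1 - exp(-k_on_2d * dt / (pi * capture_radius_um^2))
  p_off <- 1 - exp(-k_off * dt)
  d <- 0
  for (t in seq_len(iters)) {
    m <- n - 2 * d
    d <- d * (1 - p_off) + (m * (m - 1) / 2) * (pi * capture_radius_um^2 / area_um2) * p_on
  }
  2 * d / n
}

# Track set built directly from a data.frame (bypassing the linker) so that
# mobility functions can be fed exactly known trajectories.
as_track_set <- function(df, channel = "A") {
  structure(df, class = c("track_set", "data.frame"),
            channel = channel, registered = TRUE)
}

# A straight-line ("ballistic") single track.
ballistic_track <- function(n, step_nm) {
  as_track_set(data.frame(track_id = 1L, frame = 0:(n - 1),
                          x_nm = step_nm * (0:(n - 1)), y_nm = 0,
                          intensity = 1000))
}

small_cfg <- function(...) {
  sim_config(n_receptors = 40, n_frames = 30, seed = 99, ...)
}
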