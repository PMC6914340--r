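#' Ensemble mean squared displacement of a track set
#'
#' Time-averaged MSD pooled across tracks: for each lag, all squared
#' displacements between localizations whose frame indices differ by exactly
#' that lag are pooled (this equals averaging per-track MSD curves weighted by
#' their pair counts). Displacement pairs spanning a closed gap contribute to
#' the lag equal to their true frame difference, so gaps never bias a lag.
#'
#' @param tracks a `track_set` (or any data.frame with `track_id`, `frame`,
#'   `x_nm`, `y_nm`).
#' @param max_lag largest lag, in frames (>= 1).
#' @param frame_time_s frame interval in seconds.
#' @return an `msd_curve`: data.frame with `lag` (frames), `t_s` (seconds),
#'   `msd_nm2`, and `n_pairs` per lag.
#' @export
compute_msd <- function(tracks, max_lag = 10, frame_time_s = 0.032) {
  if (max_lag < 1) stopf("'max_lag' must be >= 1")
  ss <- rep(0, max_lag)
  nn <- rep(0L, max_lag)
  if (nrow(tracks) > 0) {
    by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
    for (rows in by_track) {
      if (length(rows) < 2) next
      f <- tracks$frame[rows]
      o <- order(f)
      f <- f[o]
      x <- tracks$x_nm[rows][o]
      y <- tracks$y_nm[rows][o]
      for (lag in seq_len(max_lag)) {
        j <- match(f + lag, f)
        ok <- which(!is.na(j))
        if (!length(ok)) next
        dx <- x[j[ok]] - x[ok]
        dy <- y[j[ok]] - y[ok]
        ss[lag] <- ss[lag] + sum(dx * dx + dy * dy)
        nn[lag] <- nn[lag] + length(ok)
      }
    }
  }
  msd <- ifelse(nn > 0, ss / nn, NA_real_)
  structure(data.frame(lag = seq_len(max_lag),
                       t_s = seq_len(max_lag) * frame_time_s,
                       msd_nm2 = msd, n_pairs = nn),
            class = c("msd_curve", "data.frame"),
            frame_time_s = frame_time_s)
}

#' Fit a diffusion constant to an MSD curve
#'
#' Ordinary least-squares line through the MSD over the stated lag range
#' (default lags 2-10). For 2D Brownian motion `MSD(t) = 4 D t + 4 sigma^2`,
#' so the diffusion constant is the slope divided by 4 and the intercept
#' absorbs the localization-error offset `4 sigma^2`.
#'
#' @param msd an `msd_curve` from [compute_msd()].
#' @param lag_range integer vector of length 2, first and last lag (frames).
#' @return a `diffusion_estimate`: list with `D_um2_s`, `se_um2_s`,
#'   `intercept_nm2`, `lag_range`, and `negative_slope` flag (a negative
#'   fitted slope is reported as D = 0 with the flag set and a warning).
#' @export
fit_diffusion_constant <- function(msd, lag_range = c(2, 10)) {
  sel <- msd$lag >= lag_range[1] & msd$lag <= lag_range[2] &
    is.finite(msd$msd_nm2) & msd$n_pairs > 0
  if (sum(sel) < 2)
    stopf("fewer than 2 usable lags in range [%d, %d]", lag_range[1], lag_range[2])
  fit <- stats::lm(msd_nm2 ~ t_s, data = msd[sel, ])
  slope <- unname(stats::coef(fit)[2])        # nm^2 / s
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  negative <- slope < 0
  if (negative) warnf("negative MSD slope (%.3g nm^2/s); reporting D = 0", slope)
  structure(list(D_um2_s = max(slope, 0) / 4 * 1e-6,
                 se_um2_s = se / 4 * 1e-6,
                 intercept_nm2 = unname(stats::coef(fit)[1]),
                 lag_range = lag_range,
                 negative_slope = negative),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("D = %.4g +/- %.2g um^2/s (lags %d-%d), intercept %.1f nm^2%s\n",
              x$D_um2_s, x$se_um2_s, x$lag_range[1], x$lag_range[2],
              x$intercept_nm2,
              if (x$negative_slope) " [negative slope flagged]" else ""))
  invisible(x)
}

#' Step lengths of a track set
#'
#' Euclidean displacement lengths between consecutive localizations exactly one
#' frame apart (steps across closed gaps are excluded, since they span more
#' than one frame interval).
#'
#' @param tracks a `track_set`.
#' @return numeric vector of step lengths (nm).
#' @export
step_lengths <- function(tracks) {
  if (nrow(tracks) == 0) return(numeric(0))
  out <- numeric(0)
  by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  for (rows in by_track) {
    if (length(rows) < 2) next
    o <- order(tracks$frame[rows])
    f <- tracks$frame[rows][o]
    x <- tracks$x_nm[rows][o]
    y <- tracks$y_nm[rows][o]
    one <- which(diff(f) == 1L)
    if (length(one))
      out <- c(out, sqrt(diff(x)[one]^2 + diff(y)[one]^2))
  }
  out
}

# Mixture density machinery: 2D Brownian step lengths are Rayleigh with
# E[r^2] = 4 D dt; parameterize each component by s = 4 D dt.
rayleigh_dens <- function(r, s, log = FALSE) {
  ld <- log(2 * r / s) - r * r / s
  if (log) ld else exp(ld)
}

#' Sample step lengths from a two-component Brownian mixture
#'
#' @param n number of steps.
#' @param alpha weight of the first component.
#' @param D length-2 diffusion constants (um^2/s).
#' @param dt frame interval (s).
#' @param seed RNG seed.
#' @return numeric vector of step lengths (nm).
#' @export
sample_mixture_steps <- function(n, alpha, D, dt, seed = NULL) {
  with_seed(seed, {
    comp <- 1L + (stats::runif(n) >= alpha)
    s <- 4 * D[comp] * dt * 1e6          # nm^2
    sqrt(-s * log(stats::runif(n)))
  })
}

#' Fit a two-fraction Brownian step-length mixture by EM
#'
#' Maximum-likelihood fit of the step-length density
#' `p(r) = alpha * f(r; D1) + (1 - alpha) * f(r; D2)` where
#' `f(r; D) = (r / (2 D dt)) * exp(-r^2 / (4 D dt))` is the 2D Brownian
#' (Rayleigh-form) law, via expectation-maximization with multiple random
#' restarts. Components are reported sorted `D1 >= D2` with `alpha` the weight
#' of the faster component. The log-likelihood is non-decreasing across EM
#' iterations; the full trace is returned.
#'
#' @param steps step lengths in nm (positive).
#' @param dt frame interval in seconds.
#' @param components 1 or 2. With 1 component the closed-form MLE
#'   `D = mean(r^2) / (4 dt)` is returned with `alpha = 1`.
#' @param n_starts number of random EM restarts (best log-likelihood wins).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @param seed RNG seed for the restarts.
#' @return a `steplength_fit`: list with `alpha`, `D_um2_s` (length 2, sorted
#'   decreasing), `loglik`, `loglik_trace`, `converged`, `n_steps`, `dt`.
#'   If the two components coincide (within 5% relative), an
#'   unidentifiable-alpha warning is raised.
#' @export
fit_step_length_mixture <- function(steps, dt, components = 2, n_starts = 5,
                                    tol = 1e-8, max_iter = 500, seed = 1) {
  steps <- as.numeric(steps)
  if (any(!is.finite(steps)) || any(steps <= 0))
    stopf("step lengths must be positive and finite")
  if (!is.numeric(dt) || dt <= 0) stopf("'dt' must be > 0")
  n <- length(steps)
  if (n < 50) warnf("only %d steps; mixture fit may be unstable (>= 50 recommended)", n)
  r2 <- steps^2
  if (components == 1) {
    s <- mean(r2)
    ll <- sum(rayleigh_dens(steps, s, log = TRUE))
    return(structure(list(alpha = 1, D_um2_s = s / (4 * dt) * 1e-6,
                          loglik = ll, loglik_trace = ll, converged = TRUE,
                          n_steps = n, dt = dt),
                     class = "steplength_fit"))
  }
  if (components != 2) stopf("'components' must be 1 or 2")
  s_hat <- mean(r2)
  run_em <- function(s1, s2, a) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      l1 <- log(a) + rayleigh_dens(steps, s1, log = TRUE)
      l2 <- log(1 - a) + rayleigh_dens(steps, s2, log = TRUE)
      m <- pmax(l1, l2)
      ll <- sum(m + log(exp(l1 - m) + exp(l2 - m)))
      trace <- c(trace, ll)
      w1 <- 1 / (1 + exp(l2 - l1))
      a <- mean(w1)
      a <- min(max(a, 1e-8), 1 - 1e-8)
      s1 <- sum(w1 * r2) / sum(w1)
      s2 <- sum((1 - w1) * r2) / sum(1 - w1)
      s1 <- max(s1, 1e-12); s2 <- max(s2, 1e-12)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(s = c(s1, s2), alpha = a, loglik = trace[length(trace)],
         trace = trace, converged = converged)
  }
  best <- NULL
  with_seed(seed, {
    for (k in seq_len(n_starts)) {
      s1 <- s_hat * stats::runif(1, 1, 4)
      s2 <- s_hat * stats::runif(1, 0.05, 1)
      a <- stats::runif(1, 0.2, 0.8)
      fit <- run_em(s1, s2, a)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
  })
  D <- best$s / (4 * dt) * 1e-6
  alpha <- best$alpha
  if (D[2] > D[1]) { D <- rev(D); alpha <- 1 - alpha }
  if (abs(D[1] - D[2]) < 0.05 * max(D[1], 1e-12))
    warnf("mixture components nearly equal (D1 ~ D2); alpha is unidentifiable")
  structure(list(alpha = alpha, D_um2_s = D, loglik = best$loglik,
                 loglik_trace = best$trace, converged = best$converged,
                 n_steps = n, dt = dt),
            class = "steplength_fit")
}

#' @export
print.steplength_fit <- function(x, ...) {
  if (length(x$D_um2_s) == 1) {
    cat(sprintf("single-component Brownian fit: D = %.4g um^2/s (n = %d)\n",
                x$D_um2_s, x$n_steps))
  } else {
    cat(sprintf(
      "two-fraction Brownian mixture (n = %d steps):\n  alpha = %.3f, D1 = %.4g, D2 = %.4g um^2/s [%s]\n",
      x$n_steps, x$alpha, x$D_um2_s[1], x$D_um2_s[2],
      if (x$converged) "converged" else "NOT converged"))
  }
  invisible(x)
}

#' Flag immobile tracks by density-based clustering
#'
#' A surface-stuck molecule revisits the same spot, so its localizations form
#' one dense cluster. Each track is clustered over its own points with DBSCAN;
#' the track is flagged immobile when at least 80% of its localizations fall
#' into a single cluster. Immobile tracks are conventionally excluded from
#' mobility and co-tracking analyses.
#'
#' @param tracks a `track_set`.
#' @param eps_nm DBSCAN neighborhood radius; default 50 nm = twice the default
#'   localization precision.
#' @param min_pts DBSCAN core-point threshold (>= 2).
#' @param frac fraction of a track's localizations that must share one cluster
#'   for the track to be called immobile.
#' @return named logical vector, one entry per track id.
#' @export
find_immobile <- function(tracks, eps_nm = 50, min_pts = 5, frac = 0.8) {
  if (eps_nm <= 0) stopf("'eps_nm' must be > 0")
  if (min_pts < 2) stopf("'min_pts' must be >= 2")
  if (nrow(tracks) == 0) return(stats::setNames(logical(0), character(0)))
  by_track <- split(seq_len(nrow(tracks)), tracks$track_id)
  flags <- vapply(by_track, function(rows) {
    xy <- cbind(tracks$x_nm[rows], tracks$y_nm[rows])
    labels <- dbscan_labels(xy, eps = eps_nm, min_pts = min_pts)
    if (!any(labels > 0)) return(FALSE)
    max(tabulate(labels)) >= frac * nrow(xy)
  }, logical(1))
  flags
}

#' Count photobleaching steps in an intensity trace
#'
#' Segments the trace into a piecewise-constant model by penalized
#' least-squares change-point detection (optimal partitioning with a BIC-style
#' per-change-point penalty and a minimum segment length), then counts the
#' downward level changes. A dimer carrying two fluorophores bleaches in two
#' downward steps; the step count therefore reads out labeled stoichiometry.
#'
#' @param trace numeric intensity trace (length >= 3, finite values).
#' @param penalty per-change-point penalty; default is the modified-BIC value
#'   `3 * sigma^2 * log(n)` with the noise variance estimated robustly from
#'   first differences.
#' @param min_segment minimum segment length in frames.
#' @return list with `n_steps` (downward level changes), `change_points`
#'   (1-based first frame of each new segment), and `levels` (segment means).
#' @export
count_bleach_steps <- function(trace, penalty = NULL, min_segment = 3) {
  trace <- as.numeric(trace)
  n <- length(trace)
  if (n < 3) stopf("trace must have at least 3 frames")
  if (all(is.na(trace))) stopf("trace is all-NA")
  if (any(!is.finite(trace))) stopf("trace contains non-finite values")
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(trace)) / sqrt(2)
    penalty <- max(3 * sigma^2 * log(n), 1e-12)
  }
  if (min_segment > n) min_segment <- n
  cs <- cumsum(trace)
  cs2 <- cumsum(trace^2)
  seg_cost <- function(i, j) {            # SSE of trace[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s * s / (j - i + 1)
  }
  f <- rep(Inf, n + 1)                    # f[j+1] = best cost of trace[1..j]
  f[1] <- -penalty
  last <- integer(n)                      # start index of final segment
  for (j in seq_len(n)) {
    if (j < min_segment) next
    for (i in seq_len(j - min_segment + 1)) {
      if (i > 1 && i - 1 < min_segment) next
      cand <- f[i] + penalty + seg_cost(i, j)
      if (cand < f[j + 1]) { f[j + 1] <- cand; last[j] <- i }
    }
  }
  # backtrack segment starts
  starts <- integer(0)
  j <- n
  while (j >= 1) {
    i <- last[j]
    starts <- c(i, starts)
    j <- i - 1
  }
  ends <- c(starts[-1] - 1L, n)
  levels <- mapply(function(i, j) mean(trace[i:j]), starts, ends)
  down <- if (length(levels) > 1) diff(levels) < -1e-9 else logical(0)
  list(n_steps = sum(down),
       change_points = starts[-1],
       levels = unname(levels))
}
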