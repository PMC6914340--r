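#' Per-frame dual-color co-localization
#'
#' Within every frame, localizations of channel A are paired one-to-one with
#' localizations of channel B lying within the co-localization radius
#' (100 nm by default). The pairing maximizes the number of pairs and, among
#' maximum pairings, minimizes the total pair distance (exact assignment).
#' Channels must share a coordinate frame; tables that have not passed through
#' [apply_transform()] and carry no `registered` attribute trigger a warning
#' for channel B (simulated data are born registered).
#'
#' @param table_a,table_b [localization_table()]s (or track sets with
#'   `frame`, `x_nm`, `y_nm` columns) for channels A and B.
#' @param radius_nm co-localization distance threshold (nm).
#' @param warn_unregistered warn when channel B lacks the `registered` flag
#'   (simulated streams and tables passed through [apply_transform()] carry
#'   it; raw channel-B files do not).
#' @return data.frame of pairs: `frame`, `xa`, `ya`, `xb`, `yb`, `dist_nm`,
#'   plus `x_nm`/`y_nm` midpoint columns used for co-trajectory linking, and
#'   source track ids (`track_a`, `track_b`) when the inputs carry `track_id`.
#' @export
pair_colocalizations <- function(table_a, table_b, radius_nm = 100,
                                 warn_unregistered = TRUE) {
  if (radius_nm <= 0) stopf("'radius_nm' must be > 0")
  if (warn_unregistered && is.null(attr(table_b, "registered")))
    warnf("channel B table carries no 'registered' flag; co-localization assumes a common coordinate frame")
  empty <- data.frame(frame = integer(0), xa = numeric(0), ya = numeric(0),
                      xb = numeric(0), yb = numeric(0), dist_nm = numeric(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      track_a = integer(0), track_b = integer(0))
  if (nrow(table_a) == 0 || nrow(table_b) == 0) return(empty)
  has_id_a <- "track_id" %in% names(table_a)
  has_id_b <- "track_id" %in% names(table_b)
  frames <- intersect(unique(table_a$frame), unique(table_b$frame))
  out <- vector("list", length(frames))
  rows_a <- split(seq_len(nrow(table_a)), table_a$frame)
  rows_b <- split(seq_len(nrow(table_b)), table_b$frame)
  for (k in seq_along(frames)) {
    f <- frames[k]
    ia <- rows_a[[as.character(f)]]
    ib <- rows_b[[as.character(f)]]
    xya <- cbind(table_a$x_nm[ia], table_a$y_nm[ia])
    xyb <- cbind(table_b$x_nm[ib], table_b$y_nm[ib])
    pr <- match_points(xya, xyb, gate = radius_nm, squared = FALSE)
    if (nrow(pr) == 0) next
    out[[k]] <- data.frame(
      frame = f,
      xa = xya[pr$i, 1], ya = xya[pr$i, 2],
      xb = xyb[pr$j, 1], yb = xyb[pr$j, 2],
      dist_nm = pr$dist,
      x_nm = (xya[pr$i, 1] + xyb[pr$j, 1]) / 2,
      y_nm = (xya[pr$i, 2] + xyb[pr$j, 2]) / 2,
      track_a = if (has_id_a) table_a$track_id[ia][pr$i] else NA_integer_,
      track_b = if (has_id_b) table_b$track_id[ib][pr$j] else NA_integer_
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$frame), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "radius_nm") <- radius_nm
  res
}

#' Reconstruct co-locomotion trajectories from per-frame co-localizations
#'
#' The pair midpoints (a channel-symmetric representative coordinate) are
#' linked across frames with the same trajectory linker used for the single
#' channels, and co-trajectories shorter than `min_steps` are discarded.
#' Only persistently correlated motion of a two-color pair survives this
#' filter; transient chance encounters of independent molecules do not.
#'
#' @param pairs output of [pair_colocalizations()].
#' @param linking a [linking_params()].
#' @param min_steps minimum number of steps per co-trajectory (default 10,
#'   ~320 ms at 32 ms/frame).
#' @return a `cotrajectory_set`: data.frame of retained co-localizations with
#'   a `co_id` column, attributes `n_cotrajectories` and `min_steps`.
#' @export
build_cotrajectories <- function(pairs, linking = linking_params(),
                                 min_steps = 10) {
  if (nrow(pairs) == 0) {
    out <- cbind(pairs, co_id = integer(0))
  } else {
    mid <- localization_table(frame = pairs$frame, x_nm = pairs$x_nm,
                              y_nm = pairs$y_nm,
                              intensity = rep(0, nrow(pairs)), channel = "A",
                              pair_row = seq_len(nrow(pairs)))
    tracks <- link_localizations(mid, linking)
    kept <- filter_min_steps(tracks, min_steps)
    out <- pairs[kept$pair_row, , drop = FALSE]
    out$co_id <- as.integer(factor(kept$track_id))
    out <- out[order(out$co_id, out$frame), , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, class = c("cotrajectory_set", "data.frame"),
            n_cotrajectories = length(unique(out$co_id)),
            min_steps = min_steps)
}

#' @export
print.cotrajectory_set <- function(x, ...) {
  cat(sprintf("cotrajectory_set: %d co-trajectories (min %d steps), %d co-localizations\n",
              attr(x, "n_cotrajectories"), attr(x, "min_steps"), nrow(x)))
  invisible(x)
}

#' Correct co-trajectory counts for stochastic double-labeling
#'
#' Under stochastic two-color labeling only the dimers carrying one label of
#' each species are observable as two-color co-trajectories; dimers carrying
#' two same-species labels are invisible to co-tracking. With per-trajectory
#' channel proportions `A/(A+B)` and `B/(A+B)`, the expected observable
#' fraction of labeled dimers is `2 * (A/(A+B)) * (B/(A+B))`, so the corrected
#' dimer count and the relative co-locomotion are
#'
#' `AB* = AB / (2 * (A/(A+B)) * (B/(A+B)))`,  `rel = 2 * AB* / (A + B)`.
#'
#' For a fully dimeric, fully labeled sample with balanced labeling the
#' relative co-locomotion is 1. Values above 1 can arise from sampling noise
#' at extreme channel imbalance and are reported as-is with a warning, never
#' clipped.
#'
#' @param A,B numbers of single-channel trajectories in channels A and B.
#' @param AB number of observed two-color co-trajectories.
#' @return a `dimerization_result`: list with `A`, `B`, `AB`, `AB_star`,
#'   `rel_colocomotion`.
#' @export
correct_double_labeling <- function(A, B, AB) {
  if (A < 0 || B < 0 || AB < 0) stopf("counts must be non-negative")
  if (A + B == 0) stopf("A + B = 0: correction ratio undefined")
  if ((A == 0 || B == 0) && AB > 0)
    stopf("inconsistent counts: co-trajectories observed with an empty channel")
  factor <- 2 * (A / (A + B)) * (B / (A + B))
  ab_star <- if (AB == 0) 0 else AB / factor
  rel <- 2 * ab_star / (A + B)
  if (rel > 1)
    warnf("relative co-locomotion %.3f exceeds 1 (sampling noise at channel imbalance); reported unclipped", rel)
  structure(list(A = A, B = B, AB = AB, AB_star = ab_star,
                 rel_colocomotion = rel),
            class = "dimerization_result")
}

#' @export
print.dimerization_result <- function(x, ...) {
  cat("dimerization_result:\n")
  cat(sprintf("  trajectories: A = %d, B = %d; co-trajectories AB = %d\n",
              x$A, x$B, x$AB))
  cat(sprintf("  corrected AB* = %.2f; relative co-locomotion = %.4f\n",
              x$AB_star, x$rel_colocomotion))
  if (!is.null(x$params))
    cat(sprintf("  radius = %g nm, min_steps = %d, immobile excluded: %s\n",
                x$params$radius_nm, x$params$min_steps,
                x$params$exclude_immobile))
  invisible(x)
}

#' Quantify receptor dimerization from dual-color localization tables
#'
#' The full co-tracking chain: link both channels into trajectories, exclude
#' immobile tracks, apply the minimum-steps filter, count single-channel
#' trajectories A and B, pair the surviving localizations frame-by-frame
#' within the co-localization radius, reconstruct co-trajectories, apply the
#' same minimum-steps filter, and correct the co-trajectory count for
#' stochastic double-labeling. Inputs must share a coordinate frame
#' (register channel B with [apply_transform()] first when needed).
#'
#' @param table_a,table_b registered [localization_table()]s.
#' @param linking a [linking_params()].
#' @param radius_nm co-localization radius (nm, default 100).
#' @param min_steps minimum steps per (co-)trajectory (default 10).
#' @param exclude_immobile drop immobile tracks before counting and
#'   co-localization.
#' @param eps_nm,min_pts immobile-detection DBSCAN parameters (see
#'   [find_immobile()]).
#' @param warn_unregistered see [pair_colocalizations()].
#' @param chance_baseline also estimate the chance-coincidence floor by
#'   scrambling the frame labels of channel B (destroying temporal
#'   correlation while preserving spatial density) and re-running
#'   co-localization and co-tracking; reported as `chance_rel_colocomotion`.
#'   Off by default: the >=10-step persistence filter is the standard
#'   chance-coincidence control.
#' @param seed seed for the chance-baseline scramble.
#' @return a `dimerization_result` with counts, corrected `AB_star`,
#'   `rel_colocomotion`, a `params` record, and a `log` of intermediate counts.
#' @examples
#' cfg <- sim_config(n_receptors = 60, dimer_fraction = 0.5, n_frames = 60,
#'                   seed = 11)
#' loc <- render_localizations(simulate_membrane(cfg))
#' quantify_dimerization(loc$a, loc$b)
#' @export
quantify_dimerization <- function(table_a, table_b,
                                  linking = linking_params(),
                                  radius_nm = 100, min_steps = 10,
                                  exclude_immobile = TRUE,
                                  eps_nm = 50, min_pts = 5,
                                  warn_unregistered = TRUE,
                                  chance_baseline = FALSE, seed = 1) {
  tr_a <- link_localizations(table_a, linking)
  tr_b <- link_localizations(table_b, linking)
  log <- list(n_tracks_a_raw = n_tracks(tr_a), n_tracks_b_raw = n_tracks(tr_b))
  if (exclude_immobile) {
    drop_immobile <- function(tr) {
      fl <- find_immobile(tr, eps_nm = eps_nm, min_pts = min_pts)
      keep <- as.integer(names(fl)[!fl])
      out <- tr[tr$track_id %in% keep, , drop = FALSE]
      for (a in c("class", "channel", "params", "registered"))
        attr(out, a) <- attr(tr, a)
      out
    }
    tr_a <- drop_immobile(tr_a)
    tr_b <- drop_immobile(tr_b)
    log$n_tracks_a_mobile <- n_tracks(tr_a)
    log$n_tracks_b_mobile <- n_tracks(tr_b)
  }
  tr_a <- filter_min_steps(tr_a, min_steps)
  tr_b <- filter_min_steps(tr_b, min_steps)
  A <- n_tracks(tr_a)
  B <- n_tracks(tr_b)
  log$n_tracks_a <- A
  log$n_tracks_b <- B
  pairs <- pair_colocalizations(tr_a, tr_b, radius_nm = radius_nm,
                                warn_unregistered = warn_unregistered)
  log$n_colocalizations <- nrow(pairs)
  cotr <- build_cotrajectories(pairs, linking = linking, min_steps = min_steps)
  AB <- attr(cotr, "n_cotrajectories")
  log$n_cotrajectories <- AB
  res <- correct_double_labeling(A, B, AB)
  res$params <- list(radius_nm = radius_nm, min_steps = as.integer(min_steps),
                     exclude_immobile = exclude_immobile,
                     max_step_nm = linking$max_step_nm,
                     max_gap = linking$max_gap,
                     assignment = linking$assignment)
  res$log <- log
  res$cotrajectories <- cotr
  if (chance_baseline) {
    scr <- tr_b
    frames <- sort(unique(scr$frame))
    perm <- with_seed(seed, sample(frames))
    scr$frame <- perm[match(scr$frame, frames)]
    pairs0 <- pair_colocalizations(tr_a, scr, radius_nm = radius_nm,
                                   warn_unregistered = FALSE)
    ab0 <- attr(build_cotrajectories(pairs0, linking = linking,
                                     min_steps = min_steps),
                "n_cotrajectories")
    base <- correct_double_labeling(A, B, ab0)
    res$chance_rel_colocomotion <- base$rel_colocomotion
    res$log$n_cotrajectories_scrambled <- ab0
  }
  res
}
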