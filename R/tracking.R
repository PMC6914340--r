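#' Linking parameters for trajectory reconstruction
#'
#' @param max_step_nm per-frame search radius (nm). The default
#'   `3 * sqrt(4 * 0.3 * 0.032) * 1000` ~ 588 nm is three times the RMS
#'   displacement of a Brownian walker at D = 0.3 um^2/s and 32 ms frames,
#'   covering >99% of steps at plausible membrane-receptor mobility.
#' @param max_gap number of consecutive missed frames tolerated inside one
#'   track (gap closing); the search radius grows as
#'   `max_step_nm * sqrt(gap + 1)`.
#' @param assignment `"greedy"` (closest admissible pair first; order-stable,
#'   common SMLM practice) or `"optimal"` (per-frame assignment minimizing
#'   total squared link distance, maximum cardinality under the gate).
#' @return a `linking_params` object.
#' @export
linking_params <- function(max_step_nm = 3 * sqrt(4 * 0.3 * 0.032) * 1000,
                           max_gap = 1,
                           assignment = c("greedy", "optimal")) {
  assignment <- match.arg(assignment)
  if (!is.numeric(max_step_nm) || max_step_nm <= 0)
    stopf("'max_step_nm' must be > 0")
  if (max_gap < 0) stopf("'max_gap' must be >= 0")
  structure(list(max_step_nm = as.numeric(max_step_nm),
                 max_gap = as.integer(max_gap),
                 assignment = assignment),
            class = "linking_params")
}

#' Link localizations into single-molecule trajectories
#'
#' Distance-gated frame-to-frame assignment with gap closing, in the spirit of
#' multiple-target tracing: localizations in frame t are linked to the active
#' track whose last known position lies within `max_step_nm * sqrt(gap + 1)`,
#' where `gap` counts missed frames. Each localization joins at most one
#' track; unlinked localizations seed new tracks; tracks unseen for more than
#' `max_gap` frames are closed. With `assignment = "greedy"` admissible links
#' are taken closest-first (ties broken by lower localization index, then
#' lower track id); with `"optimal"` the per-frame assignment maximizes the
#' number of links and minimizes total squared distance (Jonker-Volgenant).
#' Deterministic given the input order and parameters.
#'
#' @param table a [localization_table()].
#' @param params a [linking_params()].
#' @return a `track_set`: data.frame with columns `track_id`, `frame`,
#'   `x_nm`, `y_nm`, `intensity`, sorted by track and frame, with the channel
#'   and parameters as attributes. Singleton localizations form tracks with
#'   zero steps, so every input localization appears in exactly one track.
#' @export
link_localizations <- function(table, params = linking_params()) {
  if (!inherits(params, "linking_params")) stopf("'params' must be linking_params")
  validate_localizations(table)
  df <- as.data.frame(table)
  df <- df[order(df$frame), , drop = FALSE]
  n <- nrow(df)
  track_id <- integer(n)
  if (n > 0) {
    frames <- unique(df$frame)
    row_by_frame <- split(seq_len(n), factor(df$frame, levels = frames))
    # active track registry
    act_id <- integer(0)      # track id
    act_x <- numeric(0); act_y <- numeric(0); act_frame <- integer(0)
    next_id <- 1L
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      rows <- row_by_frame[[fi]]
      # retire tracks whose gap would exceed max_gap
      keep <- (f - act_frame - 1L) <= params$max_gap
      act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
      act_frame <- act_frame[keep]
      m <- length(act_id)
      pts <- cbind(df$x_nm[rows], df$y_nm[rows])
      assigned <- rep(NA_integer_, length(rows))   # index into active tracks
      if (m > 0 && length(rows) > 0) {
        gaps <- f - act_frame - 1L
        gate <- params$max_step_nm * sqrt(gaps + 1)
        trk_xy <- cbind(act_x, act_y)
        pairs <- if (params$assignment == "greedy") {
          match_points_greedy(trk_xy, pts, gate)
        } else {
          match_points(trk_xy, pts, gate, squared = TRUE)
        }
        if (nrow(pairs)) assigned[pairs$j] <- pairs$i
      }
      # extend matched tracks
      hit <- which(!is.na(assigned))
      for (k in hit) {
        ti <- assigned[k]
        track_id[rows[k]] <- act_id[ti]
        act_x[ti] <- pts[k, 1]; act_y[ti] <- pts[k, 2]; act_frame[ti] <- f
      }
      # new tracks for unmatched localizations
      new <- which(is.na(assigned))
      if (length(new)) {
        ids <- next_id:(next_id + length(new) - 1L)
        next_id <- next_id + length(new)
        track_id[rows[new]] <- ids
        act_id <- c(act_id, ids)
        act_x <- c(act_x, pts[new, 1]); act_y <- c(act_y, pts[new, 2])
        act_frame <- c(act_frame, rep(f, length(new)))
      }
    }
  }
  out <- df
  out$track_id <- track_id
  out <- out[order(out$track_id, out$frame),
             c("track_id", setdiff(names(out), "track_id")), drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("track_set", "data.frame"),
            channel = loc_channel(table), params = params,
            registered = attr(table, "registered"))
}

#' @export
print.track_set <- function(x, ...) {
  ns <- track_lengths(x)
  cat(sprintf("track_set: %d tracks, %d localizations (channel %s)\n",
              length(ns), nrow(x), attr(x, "channel") %||% "?"))
  if (length(ns))
    cat(sprintf("  steps per track: median %g, max %d\n",
                stats::median(ns), max(ns)))
  invisible(x)
}

#' Number of steps (inter-localization links) per track
#' @param tracks a `track_set`.
#' @return named integer vector, one entry per track id.
#' @export
track_lengths <- function(tracks) {
  if (nrow(tracks) == 0) return(stats::setNames(integer(0), character(0)))
  tab <- table(tracks$track_id)
  stats::setNames(as.integer(tab) - 1L, names(tab))
}

#' Filter tracks by minimum number of steps
#'
#' Retains tracks with at least `min_steps` inter-localization links. At the
#' default acquisition (32 ms/frame) the default `min_steps = 10` corresponds
#' to trajectories of at least ~320 ms.
#'
#' @param tracks a `track_set` from [link_localizations()].
#' @param min_steps minimum number of steps (>= 0).
#' @return the filtered `track_set`, with attribute `n_removed` recording how
#'   many tracks were dropped.
#' @export
filter_min_steps <- function(tracks, min_steps = 10) {
  if (min_steps < 0) stopf("'min_steps' must be >= 0")
  ns <- track_lengths(tracks)
  keep_ids <- as.integer(names(ns)[ns >= min_steps])
  out <- tracks[tracks$track_id %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  attrs <- attributes(tracks)
  structure(as.data.frame(out), class = c("track_set", "data.frame"),
            channel = attrs$channel, params = attrs$params,
            registered = attrs$registered,
            n_removed = length(ns) - length(keep_ids))
}

#' Count tracks in a track set
#' @param tracks a `track_set`.
#' @return number of distinct tracks.
#' @export
n_tracks <- function(tracks) length(unique(tracks$track_id))
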