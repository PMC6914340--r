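#' Pipeline configuration
#'
#' Gathers all stage parameters of the co-tracking pipeline. Defaults
#' reproduce the standard analysis constants: 100 nm co-localization radius,
#' 10-step minimum trajectory length, 32 ms frames, 150-frame movies.
#'
#' @param scenario a [sim_config()] to simulate inputs from, or `NULL` when
#'   reading localization files.
#' @param loc_a_path,loc_b_path localization CSV paths (used when `scenario`
#'   is `NULL`).
#' @param beads_path optional fiducial-bead CSV (`xa, ya, xb, yb` in nm); when
#'   given, channel B is registered into channel A's frame before
#'   co-localization.
#' @param linking a [linking_params()].
#' @param radius_nm co-localization radius (nm, > 0).
#' @param min_steps minimum trajectory steps.
#' @param exclude_immobile,eps_nm,min_pts immobile-track exclusion settings.
#' @param max_lag,lag_range MSD settings (frames).
#' @param frame_time_s frame interval (s).
#' @param seed seed recorded in reports; drives simulation when `scenario`
#'   carries no seed.
#' @param out_dir directory for JSON/CSV reports (`NULL` = no files written).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = NULL, loc_a_path = NULL,
                            loc_b_path = NULL, beads_path = NULL,
                            linking = linking_params(), radius_nm = 100,
                            min_steps = 10, exclude_immobile = TRUE,
                            eps_nm = 50, min_pts = 5, max_lag = 10,
                            lag_range = c(2, 10), frame_time_s = 0.032,
                            seed = 1, out_dir = NULL) {
  if (radius_nm <= 0) stopf("'radius_nm' must be > 0")
  if (min_steps < 0) stopf("'min_steps' must be >= 0")
  if (is.null(scenario) && (is.null(loc_a_path) || is.null(loc_b_path)))
    stopf("provide either a simulation 'scenario' or both localization paths")
  structure(list(scenario = scenario, loc_a_path = loc_a_path,
                 loc_b_path = loc_b_path, beads_path = beads_path,
                 linking = linking, radius_nm = radius_nm,
                 min_steps = as.integer(min_steps),
                 exclude_immobile = exclude_immobile, eps_nm = eps_nm,
                 min_pts = min_pts, max_lag = as.integer(max_lag),
                 lag_range = lag_range, frame_time_s = frame_time_s,
                 seed = if (!is.null(seed)) as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# Order-independent content hash (FNV-1a over the serialized config).
config_hash <- function(config) {
  bytes <- serialize(config, NULL, version = 2)
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full co-tracking pipeline
#'
#' Simulates (or reads) the two localization streams, registers channel B when
#' bead calibration data are supplied, quantifies dimerization via
#' [quantify_dimerization()], and computes per-channel mobility statistics
#' (ensemble MSD diffusion estimates and the two-fraction step-length mixture
#' over pooled channels). Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: list with `dimerization`, `diffusion` (per
#'   channel), `mixture` (pooled channels; `NULL` if too few steps),
#'   `config`, `config_hash`, `seed`. When `config$out_dir` is set, a JSON
#'   summary and co-trajectory CSV are written there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("'config' must be a pipeline_config")
  if (!is.null(config$scenario)) {
    scen <- config$scenario
    if (is.null(scen$seed)) scen$seed <- config$seed
    truth <- simulate_membrane(scen)
    loc <- render_localizations(truth, scen)
    loc_a <- loc$a; loc_b <- loc$b
  } else {
    if (!file.exists(config$loc_a_path) || !file.exists(config$loc_b_path))
      stopf("input stage: localization file not found")
    loc_a <- read_localizations(config$loc_a_path)
    loc_b <- read_localizations(config$loc_b_path)
  }
  if (!is.null(config$beads_path)) {
    if (!file.exists(config$beads_path))
      stopf("registration stage: bead file '%s' not found", config$beads_path)
    tf <- fit_affine(utils::read.csv(config$beads_path, comment.char = "#"))
    loc_b <- apply_transform(loc_b, tf)
  } else {
    tf <- NULL
  }
  dim_res <- quantify_dimerization(
    loc_a, loc_b, linking = config$linking, radius_nm = config$radius_nm,
    min_steps = config$min_steps, exclude_immobile = config$exclude_immobile,
    eps_nm = config$eps_nm, min_pts = config$min_pts)

  mobility_of <- function(tab) {
    tr <- filter_min_steps(link_localizations(tab, config$linking),
                           config$min_steps)
    if (n_tracks(tr) == 0) return(NULL)
    msd <- compute_msd(tr, max_lag = config$max_lag,
                       frame_time_s = config$frame_time_s)
    list(tracks = tr,
         diffusion = fit_diffusion_constant(msd, config$lag_range),
         msd = msd)
  }
  mob_a <- mobility_of(loc_a)
  mob_b <- mobility_of(loc_b)
  steps <- c(if (!is.null(mob_a)) step_lengths(mob_a$tracks),
             if (!is.null(mob_b)) step_lengths(mob_b$tracks))
  mixture <- if (length(steps) >= 50) {
    fit_step_length_mixture(steps, dt = config$frame_time_s,
                            seed = config$seed)
  } else NULL

  res <- structure(list(
    dimerization = dim_res,
    diffusion = list(A = if (!is.null(mob_a)) mob_a$diffusion,
                     B = if (!is.null(mob_b)) mob_b$diffusion),
    mixture = mixture,
    config = config,
    config_hash = config_hash(config),
    seed = config$seed
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(
      config_hash = res$config_hash, seed = res$seed,
      A = dim_res$A, B = dim_res$B, AB = dim_res$AB,
      AB_star = dim_res$AB_star,
      rel_colocomotion = dim_res$rel_colocomotion,
      D_A_um2_s = if (!is.null(mob_a)) mob_a$diffusion$D_um2_s,
      D_B_um2_s = if (!is.null(mob_b)) mob_b$diffusion$D_um2_s,
      mixture = if (!is.null(mixture)) list(alpha = mixture$alpha,
                                            D1 = mixture$D_um2_s[1],
                                            D2 = mixture$D_um2_s[2]),
      params = dim_res$params, log = dim_res$log
    )
    jsonlite::write_json(summary, file.path(config$out_dir, "result.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    utils::write.csv(as.data.frame(dim_res$cotrajectories),
                     file.path(config$out_dir, "cotrajectories.csv"),
                     row.names = FALSE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result [config %s, seed %s]\n", x$config_hash,
              x$seed %||% "none"))
  print(x$dimerization)
  if (!is.null(x$diffusion$A))
    cat(sprintf("  D(A) = %.4g um^2/s, D(B) = %.4g um^2/s\n",
                x$diffusion$A$D_um2_s,
                if (!is.null(x$diffusion$B)) x$diffusion$B$D_um2_s else NA))
  invisible(x)
}

#' Summarize pipeline results as a table
#'
#' @param results a `pipeline_result` or a (optionally named) list of them.
#' @param sort_by_label order rows by scenario label.
#' @return data.frame with one row per result: label, trajectory counts,
#'   corrected counts, relative co-locomotion and per-channel diffusion
#'   constants.
#' @export
report <- function(results, sort_by_label = TRUE) {
  if (inherits(results, "pipeline_result")) results <- list(results)
  if (!length(results)) {
    return(data.frame(label = character(0), A = integer(0), B = integer(0),
                      AB = integer(0), AB_star = numeric(0),
                      rel_colocomotion = numeric(0), D_A_um2_s = numeric(0),
                      D_B_um2_s = numeric(0), config_hash = character(0),
                      seed = integer(0)))
  }
  labels <- names(results) %||% sprintf("result_%d", seq_along(results))
  if (is.null(names(results)) || any(names(results) == ""))
    labels <- sprintf("result_%d", seq_along(results))
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    d <- r$dimerization
    data.frame(label = labels[i], A = d$A, B = d$B, AB = d$AB,
               AB_star = d$AB_star, rel_colocomotion = d$rel_colocomotion,
               D_A_um2_s = if (!is.null(r$diffusion$A)) r$diffusion$A$D_um2_s else NA_real_,
               D_B_um2_s = if (!is.null(r$diffusion$B)) r$diffusion$B$D_um2_s else NA_real_,
               config_hash = r$config_hash,
               seed = r$seed %||% NA_integer_)
  })
  out <- do.call(rbind, rows)
  if (sort_by_label) out <- out[order(out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
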