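## Orchestration layer: simulate -> work -> pmf -> entropy -> contacts.
## These functions are the programmatic interface; inst/cli/steerpmf.R wraps
## them for shell use.

## internal: schedule from a run_config
config_schedule <- function(config) {
  pull_schedule(config$lambda0, config$velocity, config$kappa,
                config$duration, config$dt_sample, "forward")
}

## internal: Langevin parameters from a run_config
config_langevin <- function(config, seed = NULL) {
  langevin_params(friction = config$friction,
                  temperature = config$temperature,
                  dt = config$langevin_dt, seed = seed %||% config$seed)
}

#' Simulate a bidirectional pulling study and write it to disk
#'
#' Generates the configured ensemble on an analytic potential, writes one
#' pull record per realization plus a YAML manifest, and returns the
#' ensemble.  Re-running with the same config produces identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param potential An [analytic_potential()]; default [gorge_potential()].
#' @return The [trajectory_ensemble()], invisibly, with the manifest path in
#'   attribute `"manifest"`.
#' @export
run_simulate <- function(config = run_config(), out_dir,
                         potential = gorge_potential()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ens <- generate_bidirectional_ensemble(
    potential, config_schedule(config), n_F = config$n_forward,
    n_R = config$n_reverse, params = config_langevin(config))
  fw_paths <- sprintf("forward_%02d.tsv", seq_along(ens$forward))
  rv_paths <- sprintf("reverse_%02d.tsv", seq_along(ens$reverse))
  for (i in seq_along(ens$forward))
    write_pull_record(ens$forward[[i]], file.path(out_dir, fw_paths[i]))
  for (j in seq_along(ens$reverse))
    write_pull_record(ens$reverse[[j]], file.path(out_dir, rv_paths[j]))
  manifest <- file.path(out_dir, "manifest.yaml")
  write_ensemble_manifest(manifest, fw_paths, rv_paths, config$kappa,
                          config$velocity, config$temperature)
  attr(ens, "manifest") <- manifest
  invisible(ens)
}

#' Reconstruct a PMF from a manifest or ensemble
#'
#' @param x Manifest path or [trajectory_ensemble()].
#' @param method `"ma"`, `"cp"`, `"hs_forward"` or `"hs_reverse"`.
#' @param bin_width PMF bin width (nm).
#' @param min_prominence Basin/barrier prominence threshold (kJ/mol).
#' @param out Optional output path for the PMF table.
#' @return List with `profile` ([pmf_profile()]) and `report`
#'   ([locate_basins_barriers()] result).
#' @export
run_pmf <- function(x, method = c("ma", "cp", "hs_forward", "hs_reverse"),
                    bin_width = 0.025, min_prominence = 1.0, out = NULL) {
  method <- match.arg(method)
  ens <- if (is.character(x)) read_ensemble_manifest(x) else x
  n_F <- length(ens$forward); n_R <- length(ens$reverse)
  if (method %in% c("ma", "cp") && (n_F == 0L || n_R == 0L))
    stop(sprintf(
      "method '%s' needs both directions (n_F = %d, n_R = %d); fall back to %s",
      method, n_F, n_R, if (n_F > 0) "'hs_forward'" else "'hs_reverse'"))
  if (method == "hs_forward" && n_F == 0L)
    stop("no forward realizations; fall back to 'hs_reverse'")
  if (method == "hs_reverse" && n_R == 0L)
    stop("no reverse realizations; fall back to 'hs_forward'")
  profile <- switch(method,
                    ma = bidirectional_pmf(ens, "ma", bin_width = bin_width),
                    cp = bidirectional_pmf(ens, "cp", bin_width = bin_width),
                    hs_forward = hs_pmf(ens, "forward",
                                        bin_width = bin_width),
                    hs_reverse = hs_pmf(ens, "reverse",
                                        bin_width = bin_width))
  report <- locate_basins_barriers(profile, min_prominence)
  if (!is.null(out)) write_pmf_table(profile, out)
  list(profile = profile, report = report)
}

#' Windowed relative entropy profile of coordinate ensembles
#'
#' @param trajectories List of [coordinate_ensemble()] objects (or `.xyz`
#'   paths) sharing the frame grid.
#' @param reference The bound-state reference: a [coordinate_ensemble()], an
#'   `.xyz` path, or `"first_window"` to use the first window of the data.
#'   Required; there is no silent default.
#' @param window_len,window_stride Window geometry (frames).
#' @param temperature Temperature (K).
#' @param formula `"quantum_qh"` or `"schlitter"`.
#' @param schedule Optional [pull_schedule()] to attach a lambda axis.
#' @param out Optional output path for the entropy table.
#' @return An [relative_entropy_profile()] result.
#' @export
run_entropy <- function(trajectories, reference, window_len = 400,
                        window_stride = 20, temperature = 300,
                        formula = c("quantum_qh", "schlitter"),
                        schedule = NULL, out = NULL) {
  formula <- match.arg(formula)
  if (missing(reference) || is.null(reference))
    stop("an entropy reference must be designated (no silent default)")
  load1 <- function(x) if (is.character(x)) read_xyz_ensemble(x) else x
  if (inherits(trajectories, "coordinate_ensemble") ||
      is.character(trajectories))
    trajectories <- list(trajectories)
  trajectories <- lapply(trajectories, load1)
  n_frames <- dim(trajectories[[1]]$frames)[1]
  spec <- window_spec(n_frames, window_len, window_stride)
  prof <- windowed_entropy_profile(trajectories, spec, temperature, formula)
  min_dim <- 3L * length(trajectories[[1]]$masses)
  if (any(prof$n_retained < min_dim))
    warning("rank-deficient covariance in some windows; ",
            "spectrum truncated to n_retained modes")
  ref <- if (identical(reference, "first_window")) {
    w <- make_windows(spec)[[1]]
    lapply(trajectories, function(e) {
      coordinate_ensemble(e$frames[w[1]:w[2], , , drop = FALSE], e$masses,
                          e$frame_period)
    })
  } else if (is.list(reference) && !inherits(reference,
                                             "coordinate_ensemble")) {
    lapply(reference, load1)
  } else {
    load1(reference)
  }
  lam_axis <- if (!is.null(schedule))
    window_lambda_axis(spec, schedule, trajectories[[1]]$frame_period)
  res <- relative_entropy_profile(prof, ref, temperature, formula,
                                  lam_axis = lam_axis)
  if (!is.null(out)) write_entropy_table(res, out)
  res
}

#' Contact profile of tagged frames
#'
#' @param frames List of atom data frames (or a [planted_scene()], whose
#'   single frame is profiled at one lambda).
#' @param lambda Control-parameter tag per frame (nm).
#' @param bin_width Bin width (nm).
#' @param criteria A [hbond_criteria()].
#' @param hydrophobic_cutoff Cutoff (nm).
#' @return A `contact_profile` data frame (see [profile_vs_lambda()]).
#' @export
run_contacts <- function(frames, lambda, bin_width = 0.025,
                         criteria = hbond_criteria(),
                         hydrophobic_cutoff = 0.45) {
  if (inherits(frames, "planted_scene")) frames <- list(frames$atoms)
  bins <- make_xi_bins(range(lambda), bin_width)
  profile_vs_lambda(frames, lambda, bins, criteria, hydrophobic_cutoff)
}
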