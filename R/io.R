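## Plain-text, XVG-compatible file formats: tab-separated columns with
## '#'-prefixed header lines, YAML manifests, extended-XYZ coordinate
## ensembles with a sidecar atom table.

## internal: '#'-prefixed provenance header lines
provenance_header <- function(fields) {
  c("# steerpmf output",
    sprintf("# created: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    vapply(names(fields), function(k)
      sprintf("# %s: %s", k, format(fields[[k]])), ""))
}

#' Write / read one pulling realization record
#'
#' Tab-separated columns `time_ps  lambda_nm  xi_nm  force_kJ_mol_nm`
#' plus an accumulated-work column `work_kJ_mol`, with `#`-prefixed header
#' lines carrying the schedule and temperature so the record round-trips
#' losslessly (12 significant digits).  The work column preserves the
#' simulator's finely accumulated contour integral; when a record lacks it
#' (e.g. ingested from external pulling output) the work is recomputed from
#' the sampled frames with [accumulate_work()].
#'
#' @param traj A [pull_trajectory()].
#' @param path Output file.
#' @return `write_pull_record` returns `path` invisibly; `read_pull_record`
#'   returns a [pull_trajectory()].
#' @export
write_pull_record <- function(traj, path) {
  stopifnot(inherits(traj, "pull_trajectory"))
  s <- traj$schedule
  hdr <- provenance_header(list(
    format = "pull_record", direction = s$direction,
    lambda0_nm = sprintf("%.12g", s$lambda0),
    velocity_nm_ps = sprintf("%.12g", s$velocity),
    kappa_kJ_mol_nm2 = sprintf("%.12g", s$kappa),
    duration_ps = sprintf("%.12g", s$duration),
    dt_sample_ps = sprintf("%.12g", s$dt_sample),
    temperature_K = sprintf("%.12g", traj$temperature)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("# time_ps\tlambda_nm\txi_nm\tforce_kJ_mol_nm\twork_kJ_mol", con)
  writeLines(sprintf("%.12g\t%.12g\t%.12g\t%.12g\t%.12g",
                     traj$time, traj$lam, traj$xi, traj$force, traj$work),
             con)
  invisible(path)
}

## internal: parse '# key: value' header lines
read_header_fields <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^#\\s*([A-Za-z0-9_]+):\\s*(.*)$", lines))
  kv <- kv[vapply(kv, length, 0L) == 3L]
  stats::setNames(lapply(kv, `[`, 3L), vapply(kv, `[`, "", 2L))
}

#' @rdname write_pull_record
#' @export
read_pull_record <- function(path) {
  h <- read_header_fields(path)
  need <- c("direction", "lambda0_nm", "velocity_nm_ps", "kappa_kJ_mol_nm2",
            "duration_ps", "dt_sample_ps", "temperature_K")
  if (!all(need %in% names(h)))
    stop("not a pull_record file: missing header fields in ", path)
  d <- utils::read.table(path, comment.char = "#", sep = "\t")
  names(d) <- c("time", "lam", "xi", "force", "work")[seq_len(ncol(d))]
  sch <- pull_schedule(as.numeric(h$lambda0_nm), as.numeric(h$velocity_nm_ps),
                       as.numeric(h$kappa_kJ_mol_nm2),
                       as.numeric(h$duration_ps), as.numeric(h$dt_sample_ps),
                       h$direction)
  pull_trajectory(sch, d$time, d$xi,
                  temperature = as.numeric(h$temperature_K),
                  force = d$force, work = d$work)
}

#' Write / read an ensemble manifest
#'
#' YAML file listing the forward and reverse record paths together with the
#' shared protocol parameters (kappa, velocity, temperature).
#'
#' @param ensemble A [trajectory_ensemble()] already written with
#'   [write_pull_record()]; alternatively supply `forward`/`reverse` paths.
#' @param path Manifest file path.
#' @param forward,reverse Character vectors of record paths.
#' @param kappa,velocity,temperature Protocol parameters stored for
#'   validation on read.
#' @return `write_ensemble_manifest` returns `path` invisibly;
#'   `read_ensemble_manifest` returns a [trajectory_ensemble()].
#' @export
write_ensemble_manifest <- function(path, forward, reverse, kappa, velocity,
                                    temperature) {
  obj <- list(format = "steerpmf_manifest",
              kappa_kJ_mol_nm2 = kappa, velocity_nm_ps = velocity,
              temperature_K = temperature,
              forward = as.list(forward), reverse = as.list(reverse))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_ensemble_manifest
#' @export
read_ensemble_manifest <- function(path) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "steerpmf_manifest"))
    stop("not a steerpmf manifest: ", path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  fw <- lapply(obj$forward, function(p) read_pull_record(resolve(p)))
  rv <- lapply(obj$reverse, function(p) read_pull_record(resolve(p)))
  trajectory_ensemble(fw, rv, temperature = obj$temperature_K)
}

#' Write / read a coordinate ensemble as extended XYZ
#'
#' Per-frame blocks: atom count, a comment line `time=<ps>`, then
#' `element x y z` (nm).  Masses, roles and hydrogen-parent links travel in
#' a sidecar tab-separated table `<path>.atoms.tsv` (columns element,
#' mass_amu, role, molecule, h_parent).
#'
#' @param ensemble A [coordinate_ensemble()].
#' @param path Output `.xyz` path.
#' @param elements,roles,molecules,h_parent Optional per-atom annotations for
#'   the sidecar (defaults: element "C", role "none", molecule "none", no
#'   parent).
#' @return `write_xyz_ensemble` returns `path` invisibly;
#'   `read_xyz_ensemble` returns a [coordinate_ensemble()] with the sidecar
#'   table attached as attribute `"atoms"`.
#' @export
write_xyz_ensemble <- function(ensemble, path, elements = NULL, roles = NULL,
                               molecules = NULL, h_parent = NULL) {
  stopifnot(inherits(ensemble, "coordinate_ensemble"))
  d <- dim(ensemble$frames)
  elements <- elements %||% rep("C", d[2])
  roles <- roles %||% rep("none", d[2])
  molecules <- molecules %||% rep("none", d[2])
  h_parent <- h_parent %||% rep(NA_integer_, d[2])
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1])) {
    writeLines(as.character(d[2]), con)
    writeLines(sprintf("time=%.12g", (f - 1) * ensemble$frame_period), con)
    writeLines(sprintf("%s %.12g %.12g %.12g", elements,
                       ensemble$frames[f, , 1], ensemble$frames[f, , 2],
                       ensemble$frames[f, , 3]), con)
  }
  utils::write.table(
    data.frame(element = elements, mass_amu = ensemble$masses, role = roles,
               molecule = molecules, h_parent = h_parent),
    paste0(path, ".atoms.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}

#' @rdname write_xyz_ensemble
#' @export
read_xyz_ensemble <- function(path) {
  lines <- readLines(path)
  n_atoms <- as.integer(lines[1])
  block <- n_atoms + 2L
  n_frames <- length(lines) %/% block
  if (n_frames * block != length(lines))
    stop("malformed extended-XYZ file: ragged frame blocks")
  frames <- array(NA_real_, c(n_frames, n_atoms, 3L))
  times <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    off <- (f - 1L) * block
    if (as.integer(lines[off + 1L]) != n_atoms)
      stop("malformed extended-XYZ file: varying atom count")
    times[f] <- as.numeric(sub("^time=", "", lines[off + 2L]))
    rows <- strsplit(lines[off + 2L + seq_len(n_atoms)], "\\s+")
    m <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[f, , ] <- m
  }
  atoms <- utils::read.table(paste0(path, ".atoms.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  period <- if (n_frames > 1L) times[2] - times[1] else 1
  out <- coordinate_ensemble(frames, atoms$mass_amu, frame_period = period)
  attr(out, "atoms") <- atoms
  out
}

#' Write a PMF profile as a tab-separated table
#'
#' Columns `xi_nm  G_kJ_mol  G_kcal_mol  n_samples`, with a header recording
#' estimator, beta, bin width and realization counts.  Masked bins are
#' written as `NA` (optionally linearly interpolated, clearly labelled in
#' the header).
#'
#' @param profile A [pmf_profile()].
#' @param path Output file.
#' @param interpolate_empty Fill masked bins by linear interpolation
#'   (default FALSE; recorded in the header when used).
#' @return `path`, invisibly.
#' @export
write_pmf_table <- function(profile, path, interpolate_empty = FALSE) {
  stopifnot(inherits(profile, "pmf_profile"))
  G <- profile$G
  if (interpolate_empty && anyNA(G)) {
    ok <- is.finite(G)
    G <- stats::approx(profile$xi_bins[ok], G[ok], xout = profile$xi_bins,
                       rule = 1)$y
  }
  hdr <- provenance_header(list(
    format = "pmf_profile", estimator = profile$estimator,
    beta_mol_kJ = sprintf("%.12g", profile$beta),
    bin_width_nm = sprintf("%.12g", profile$bin_width),
    n_F = profile$n_F, n_R = profile$n_R,
    empty_bins = if (interpolate_empty) "interpolated" else "masked"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("# xi_nm\tG_kJ_mol\tG_kcal_mol\tn_samples", con)
  writeLines(sprintf("%.12g\t%.12g\t%.12g\t%d", profile$xi_bins, G,
                     kj_to_kcal(G), profile$n_samples), con)
  invisible(path)
}

#' Write an entropy profile as a tab-separated table
#'
#' Columns `axis_value  TdS_kcal_mol  n_modes_retained`.
#'
#' @param profile An [relative_entropy_profile()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_entropy_table <- function(profile, path) {
  stopifnot(inherits(profile, "entropy_profile"))
  axis <- profile$lambda_nm %||% profile$window
  hdr <- provenance_header(list(
    format = "entropy_profile", formula = attr(profile, "formula"),
    temperature_K = attr(profile, "temperature"),
    S_ref_kJ_mol_K = sprintf("%.12g", attr(profile, "S_ref_kJ_mol_K"))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("# axis_value\tTdS_kcal_mol\tn_modes_retained", con)
  writeLines(sprintf("%.12g\t%.12g\t%d", axis, profile$TdS_kcal_mol,
                     profile$n_retained), con)
  invisible(path)
}

#' Study configuration with the reference protocol defaults
#'
#' The defaults reproduce the reference pulling protocol: spring constant
#' 1686.75 kJ/mol/nm^2, velocity 5e-4 nm/ps, 5 ns pulls sampled every ps
#' (5000 frames), 10 realizations per direction at 300 K, 0.025 nm PMF bins
#' and 400/20-frame entropy windows.
#'
#' @param temperature Temperature (K).
#' @param kappa Spring constant (kJ/mol/nm^2).
#' @param velocity Pulling velocity (nm/ps).
#' @param duration Pull duration (ps).
#' @param dt_sample Sampling period (ps).
#' @param n_forward,n_reverse Realization counts.
#' @param lambda0 Control-parameter start (nm).
#' @param bin_width PMF bin width (nm).
#' @param window_len,window_stride Entropy window length and stride (frames).
#' @param friction Langevin friction (amu/ps); see [langevin_params()].
#' @param langevin_dt Integration step (ps).
#' @param seed Root seed.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(temperature = 300, kappa = 1686.75,
                       velocity = 5e-4, duration = 5000, dt_sample = 1,
                       n_forward = 10, n_reverse = 10, lambda0 = 0,
                       bin_width = 0.025, window_len = 400,
                       window_stride = 20, friction = 2500,
                       langevin_dt = 0.05, seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %-13s %s\n", k, format(x[[k]])))
  invisible(x)
}
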