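#' Cartesian coordinate ensemble
#'
#' Frames-by-atoms-by-3 array of coordinates with per-atom masses, the basic
#' input to the covariance-based entropy machinery (e.g. the atoms defining
#' a drug-protein binding entity, sampled once per ps along a pull).
#'
#' @param frames Numeric array `[n_frames, n_atoms, 3]` (nm).
#' @param masses Atomic masses (amu), length `n_atoms`, all > 0.
#' @param frame_period Time between frames (ps).
#' @param atom_labels Optional identifiers, length `n_atoms`.
#' @return Object of class `coordinate_ensemble`.
#' @export
coordinate_ensemble <- function(frames, masses, frame_period = 1,
                                atom_labels = NULL) {
  stopifnot(is.array(frames), length(dim(frames)) == 3L, dim(frames)[3] == 3L)
  n_frames <- dim(frames)[1]; n_atoms <- dim(frames)[2]
  if (n_frames < 2L) stop("need n_frames >= 2")
  if (length(masses) != n_atoms || any(masses <= 0))
    stop("masses must be positive, one per atom")
  structure(list(frames = frames, masses = as.numeric(masses),
                 frame_period = frame_period,
                 atom_labels = atom_labels %||%
                   paste0("atom", seq_len(n_atoms))),
            class = "coordinate_ensemble")
}

#' @export
print.coordinate_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("coordinate_ensemble: %d frames x %d atoms (%g ps/frame)\n",
              d[1], d[2], x$frame_period))
  invisible(x)
}

#' Sliding-window specification
#'
#' Divides `n_frames` frames into overlapping windows of `window_len` frames
#' advanced by `stride` frames.  The window count follows the convention
#' `floor((n_frames - window_len) / stride)` (clamped to at least 1 when the
#' window fits), so 5000 frames with 400-frame windows and stride 20 give
#' 230 windows.
#'
#' @param n_frames Total frames available.
#' @param window_len Window length (frames), `<= n_frames`.
#' @param stride Advance between windows (frames), `>= 1`.
#' @return Object of class `window_spec`.
#' @export
window_spec <- function(n_frames, window_len = 400L, stride = 20L) {
  stopifnot(n_frames >= 2, window_len >= 2, stride >= 1)
  if (window_len > n_frames) stop("window_len must be <= n_frames")
  structure(list(n_frames = as.integer(n_frames),
                 window_len = as.integer(window_len),
                 stride = as.integer(stride)),
            class = "window_spec")
}

#' Frame-index ranges of the sliding windows
#'
#' @param spec A [window_spec()].
#' @return List of integer vectors `c(start, end)`, 1-based inclusive.
#' @examples
#' length(make_windows(window_spec(5000, 400, 20)))  # 230
#' @export
make_windows <- function(spec) {
  stopifnot(inherits(spec, "window_spec"))
  n <- max(1L, (spec$n_frames - spec$window_len) %/% spec$stride)
  lapply(seq_len(n), function(i) {
    s <- (i - 1L) * spec$stride + 1L
    c(start = s, end = s + spec$window_len - 1L)
  })
}

#' Map window index to the control parameter of a pulling schedule
#'
#' Each window is labelled by the control-parameter position at its midpoint
#' frame.  At the standard protocol (frame period 1 ps, v = 5e-4 nm/ps,
#' 400/20-frame windows) consecutive windows are displaced by 0.01 nm and a
#' single window spans 0.2 nm of the control parameter.
#'
#' @param spec A [window_spec()].
#' @param schedule A [pull_schedule()].
#' @param frame_period Time per frame (ps).
#' @return Numeric vector of lambda values, one per window.
#' @export
window_lambda_axis <- function(spec, schedule, frame_period = 1) {
  wins <- make_windows(spec)
  mid_t <- vapply(wins, function(w) (w[1] + w[2]) / 2 - 1, 0) * frame_period
  control_position(schedule, mid_t)
}

#' Mass-weighted covariance of a coordinate subensemble
#'
#' sigma = M^(1/2) cov(x) M^(1/2), where cov is taken about the subensemble
#' mean over the selected frames and M is the diagonal mass matrix with each
#' atom's mass repeated for its x, y, z coordinates.  Coordinates are
#' flattened atom-major, (x1, y1, z1, x2, ...), matching the covariance
#' convention of [gaussian_ensemble_spec()].
#'
#' @param ensemble A [coordinate_ensemble()] or a list of them (frames pooled
#'   across realizations).
#' @param frame_range Optional `c(start, end)`; default all frames.
#' @return Symmetric 3N x 3N matrix (amu nm^2).
#' @export
mass_weighted_covariance <- function(ensemble, frame_range = NULL) {
  if (inherits(ensemble, "coordinate_ensemble")) ensemble <- list(ensemble)
  stopifnot(all(vapply(ensemble, inherits, TRUE, "coordinate_ensemble")))
  m <- ensemble[[1]]$masses
  flat <- lapply(ensemble, function(e) {
    if (length(e$masses) != length(m) || any(abs(e$masses - m) > 1e-9))
      stop("inconsistent atom sets across realizations")
    d <- dim(e$frames)
    fr <- if (is.null(frame_range)) seq_len(d[1]) else
      seq.int(frame_range[1], frame_range[2])
    if (length(fr) < 1L || max(fr) > d[1]) stop("frame_range out of bounds")
    ## flatten atom-major: columns (x1, y1, z1, x2, y2, z2, ...)
    matrix(aperm(e$frames[fr, , , drop = FALSE], c(1L, 3L, 2L)),
           nrow = length(fr))
  })
  X <- do.call(rbind, flat)
  if (nrow(X) < 2L) stop("need at least 2 frames for a covariance")
  w <- sqrt(rep(m, each = 3L))
  C <- stats::cov(X)
  C * tcrossprod(w)
}

#' Eigenvalue spectrum of a mass-weighted covariance
#'
#' @param sigma Matrix from [mass_weighted_covariance()].
#' @param floor Numerical floor (amu nm^2); eigenvalues at or below it are
#'   treated as frozen modes and excluded from `n_retained`.
#' @param window_index Optional provenance tag.
#' @return Object of class `covariance_spectrum`: `eigenvalues` (descending,
#'   above floor), `n_retained`, `n_total`, `window_index`.
#' @export
covariance_spectrum <- function(sigma, floor = 1e-12, window_index = NA) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev, decreasing = TRUE)
  keep <- ev > floor
  structure(list(eigenvalues = ev[keep], n_retained = sum(keep),
                 n_total = length(ev), window_index = window_index),
            class = "covariance_spectrum")
}

#' Quantum quasiharmonic entropy from a covariance spectrum
#'
#' Treats each covariance eigenvalue lambda_i (amu nm^2) as a quasiharmonic
#' mode of frequency `omega_i = sqrt(kB T / lambda_i)` and sums the quantum
#' harmonic-oscillator entropy:
#' `S = kB sum_i [ a_i / (e^{a_i} - 1) - log(1 - e^{-a_i}) ]`,
#' `a_i = hbar omega_i / (kB T)`.  Every mode contributes non-negatively and
#' a frozen mode (lambda_i -> 0) contributes nothing.
#'
#' @param spectrum A [covariance_spectrum()] (or numeric eigenvalues).
#' @param temperature Temperature (K).
#' @return Entropy in kJ/mol/K.
#' @export
quantum_qh_entropy <- function(spectrum, temperature = 300) {
  ev <- if (inherits(spectrum, "covariance_spectrum"))
    spectrum$eigenvalues else spectrum
  if (length(ev) == 0L) stop("empty spectrum")
  pc <- phys_constants()
  kT <- pc$kB * temperature
  a <- pc$hbar * sqrt(kT / ev) / kT
  term <- ifelse(a > 700, 0, a / expm1(a) - log1p(-exp(-a)))
  pc$kB * sum(term)
}

#' Schlitter entropy bound from a covariance spectrum
#'
#' `S = (kB/2) sum_i log(1 + kB T e^2 lambda_i / hbar^2)`, an upper bound to
#' the quantum quasiharmonic entropy on the same spectrum (e is Euler's
#' number).  Returns 0 for an all-frozen spectrum.
#'
#' @inheritParams quantum_qh_entropy
#' @return Entropy in kJ/mol/K.
#' @export
schlitter_entropy <- function(spectrum, temperature = 300) {
  ev <- if (inherits(spectrum, "covariance_spectrum"))
    spectrum$eigenvalues else spectrum
  pc <- phys_constants()
  if (length(ev) == 0L) return(0)
  kT <- pc$kB * temperature
  0.5 * pc$kB * sum(log1p(kT * exp(2) / pc$hbar^2 * ev))
}

#' Time-windowed entropy profile of a pulled subensemble
#'
#' Slides [make_windows()] windows along a set of synchronized coordinate
#' ensembles (one per pulling realization), pools the frames of all
#' realizations inside each window, and evaluates the quasiharmonic entropy
#' of the pooled covariance, giving one entropy per window (10 realizations
#' x 400 frames per window in the reference protocol).
#'
#' @param trajectories A [coordinate_ensemble()] or list of them sharing the
#'   frame grid.
#' @param spec A [window_spec()]; its `n_frames` must match the data.
#' @param temperature Temperature (K).
#' @param formula `"quantum_qh"` or `"schlitter"`.
#' @param floor Eigenvalue floor passed to [covariance_spectrum()].
#' @return Data frame with columns `window`, `frame_start`, `frame_end`,
#'   `S_kJ_mol_K`, `n_retained`.
#' @export
windowed_entropy_profile <- function(trajectories, spec, temperature = 300,
                                     formula = c("quantum_qh", "schlitter"),
                                     floor = 1e-12) {
  formula <- match.arg(formula)
  if (inherits(trajectories, "coordinate_ensemble"))
    trajectories <- list(trajectories)
  nf <- vapply(trajectories, function(e) dim(e$frames)[1], 0L)
  if (length(unique(nf)) != 1L)
    stop("all realizations must share the frame grid")
  if (nf[1] != spec$n_frames)
    stop("window spec n_frames does not match the data")
  wins <- make_windows(spec)
  fun <- if (formula == "quantum_qh") quantum_qh_entropy else
    schlitter_entropy
  res <- lapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    sp <- covariance_spectrum(
      mass_weighted_covariance(trajectories, w), floor = floor,
      window_index = i)
    data.frame(window = i, frame_start = w[[1]], frame_end = w[[2]],
               S_kJ_mol_K = fun(sp, temperature),
               n_retained = sp$n_retained)
  })
  do.call(rbind, res)
}

#' Entropy profile relative to a designated bound-state reference
#'
#' Subtracts the entropy of an explicitly designated reference ensemble
#' (typically the bound state of the ligand) from a windowed entropy profile
#' and reports the result as T * dS in kcal/mol at the stated temperature.
#'
#' @param profile Result of [windowed_entropy_profile()].
#' @param bound_reference A [coordinate_ensemble()] (or list of them) whose
#'   pooled entropy defines the zero, or a single precomputed entropy in
#'   kJ/mol/K.  There is no default: the caller must designate the reference.
#' @param temperature Temperature (K).
#' @param formula Entropy formula, matching the profile.
#' @param lam_axis Optional control-parameter axis (e.g. from
#'   [window_lambda_axis()]) attached as a column.
#' @param floor Eigenvalue floor.
#' @return Object of class `entropy_profile`: data frame with `window`,
#'   optional `lambda_nm`, `TdS_kcal_mol`, `n_retained`, and attributes
#'   `formula`, `temperature`, `S_ref_kJ_mol_K`.
#' @export
relative_entropy_profile <- function(profile, bound_reference,
                                     temperature = 300,
                                     formula = c("quantum_qh", "schlitter"),
                                     lam_axis = NULL, floor = 1e-12) {
  formula <- match.arg(formula)
  if (missing(bound_reference) || is.null(bound_reference))
    stop("a bound-state reference must be designated explicitly")
  S_ref <- if (is.numeric(bound_reference) && length(bound_reference) == 1L) {
    bound_reference
  } else {
    fun <- if (formula == "quantum_qh") quantum_qh_entropy else
      schlitter_entropy
    sp <- covariance_spectrum(mass_weighted_covariance(bound_reference),
                              floor = floor)
    fun(sp, temperature)
  }
  TdS <- kj_to_kcal(temperature * (profile$S_kJ_mol_K - S_ref))
  out <- data.frame(window = profile$window)
  if (!is.null(lam_axis)) {
    stopifnot(length(lam_axis) == nrow(profile))
    out$lambda_nm <- lam_axis
  }
  out$TdS_kcal_mol <- TdS
  out$n_retained <- profile$n_retained
  structure(out, class = c("entropy_profile", "data.frame"),
            formula = formula, temperature = temperature,
            S_ref_kJ_mol_K = S_ref)
}
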