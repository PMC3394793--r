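#' Langevin dynamics parameters
#'
#' Parameters of the overdamped (Brownian) dynamics used as a surrogate for
#' solvated pulling simulations.  The default friction corresponds to a
#' diffusion coefficient D = kB T / friction of about 1e-3 nm^2/ps, typical of
#' a small molecule in water at 300 K.
#'
#' @param friction Friction coefficient gamma (amu/ps).
#' @param temperature Temperature (K).
#' @param dt Integration time step (ps).
#' @param seed Integer seed for reproducibility.
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(friction = 2500, temperature = 300, dt = 0.05,
                            seed = 1L) {
  stopifnot(friction > 0, temperature > 0, dt > 0)
  structure(list(friction = friction, temperature = temperature, dt = dt,
                 seed = as.integer(seed)),
            class = "langevin_params")
}

## internal: Euler-Maruyama stability precondition
check_stability <- function(potential, schedule, params) {
  stiff <- schedule$kappa + max_curvature(potential)
  if (params$dt * stiff / params$friction >= 0.1)
    stop(sprintf(
      "unstable configuration: dt*(kappa + max|G''|)/friction = %.3f >= 0.1",
      params$dt * stiff / params$friction))
  invisible(TRUE)
}

#' Simulate one constant-velocity pull by overdamped Langevin dynamics
#'
#' Integrates xi(t) under the force -G_true'(xi) + kappa (lambda(t) - xi) with
#' the Euler-Maruyama update
#' `xi <- xi + F/gamma dt + sqrt(2 kB T dt / gamma) N(0,1)`,
#' records frames at the schedule's sampling period and returns a fully
#' populated [pull_trajectory()] including accumulated net work.
#' Bit-reproducible for a fixed seed.
#'
#' @param potential An [analytic_potential()].
#' @param schedule A [pull_schedule()].
#' @param params A [langevin_params()].
#' @param x0 Initial collective coordinate (nm); defaults to the guide anchor
#'   `schedule$lambda0` (guide starting at rest).
#' @param subtract_initial Passed to [accumulate_work()].
#' @return A [pull_trajectory()].
#' @export
simulate_pulled_langevin <- function(potential, schedule, params,
                                     x0 = NULL, subtract_initial = TRUE) {
  stopifnot(inherits(potential, "analytic_potential"),
            inherits(schedule, "pull_schedule"),
            inherits(params, "langevin_params"))
  check_stability(potential, schedule, params)
  sample_every <- round(schedule$dt_sample / params$dt)
  if (abs(sample_every * params$dt - schedule$dt_sample) > 1e-9)
    stop("Langevin dt must divide dt_sample")
  if (is.null(x0)) x0 <- schedule$lambda0
  code <- potential_code(potential)
  kT <- phys_constants()$kB * params$temperature
  set.seed(params$seed)
  m <- .simulate_langevin_cpp(code$kind, code$params, x0, schedule$lambda0,
                              schedule$velocity, schedule$kappa,
                              schedule$duration, params$dt,
                              as.integer(sample_every), params$friction, kT)
  ## work accumulated at the integration step inside the integrator
  w <- m[, 3]
  if (subtract_initial)
    w <- w - spring_energy(x0, schedule$lambda0, schedule$kappa)
  pull_trajectory(schedule, time = m[, 1], xi = m[, 2],
                  temperature = params$temperature, work = w)
}

## internal: fixed-lambda Langevin relaxation; returns final xi
relax_at_lambda <- function(potential, lambda, kappa, equil_time, params,
                            x0, seed) {
  if (equil_time <= 0) return(x0)
  code <- potential_code(potential)
  kT <- phys_constants()$kB * params$temperature
  nst <- max(1L, round(equil_time / params$dt))
  set.seed(seed)
  m <- .simulate_langevin_cpp(code$kind, code$params, x0, lambda, 0, kappa,
                              nst * params$dt, params$dt, nst,
                              params$friction, kT)
  m[nrow(m), 2]
}

#' Prepare the initial state of a reverse (binding) pull
#'
#' Takes the end point of a forward pulling trajectory and relaxes it by
#' fixed-lambda Langevin dynamics at the unbound end state lambda_b, mimicking
#' the preparation of reverse pulls by a short equilibration of the forward
#' end-point structure.  `equil_time = 0` passes the end point through
#' unchanged.
#'
#' @param forward_traj A completed forward [pull_trajectory()].
#' @param equil_time Relaxation time (ps), default 50.
#' @param params A [langevin_params()]; its seed controls the relaxation noise.
#' @param potential The [analytic_potential()] the trajectory was run on.
#' @return List with `xi` (starting coordinate) and `lambda` (= lambda_b).
#' @export
make_reverse_start <- function(forward_traj, equil_time = 50, params,
                               potential) {
  stopifnot(inherits(forward_traj, "pull_trajectory"))
  sch <- forward_traj$schedule
  lam_b <- sch$lambda0 + sch$velocity * sch$duration
  xi_end <- forward_traj$xi[length(forward_traj$xi)]
  xi0 <- relax_at_lambda(potential, lam_b, sch$kappa, equil_time, params,
                         xi_end, params$seed)
  list(xi = xi0, lambda = lam_b)
}

#' Generate a bidirectional pulling ensemble with known ground truth
#'
#' Runs `n_F` forward (unbinding) and `n_R` reverse (binding) constant-velocity
#' pulls on an analytic potential.  Forward starts are drawn by a guide-on
#' equilibration at the bound end state lambda_a; each reverse pull is seeded
#' from its forward partner's end point after a guide-on relaxation at
#' lambda_b (when `n_F = 0`, reverse starts are instead equilibrated directly
#' at lambda_b).  One root seed spawns fixed per-realization substreams, so
#' the ensemble is reproducible regardless of execution order.
#'
#' @param potential An [analytic_potential()].
#' @param schedule The forward [pull_schedule()] (direction `"forward"`).
#' @param n_F,n_R Number of forward / reverse realizations (`n_F + n_R >= 1`).
#' @param params A [langevin_params()]; its `seed` is the root seed.
#' @param equil_time Guide-on equilibration time for the starts (ps).
#' @return A [trajectory_ensemble()].
#' @examples
#' \donttest{
#' ens <- generate_bidirectional_ensemble(gorge_potential(),
#'   pull_schedule(0, 5e-4, 1686.75, 5000, 1, "forward"),
#'   n_F = 2, n_R = 2, params = langevin_params(seed = 7))
#' }
#' @export
generate_bidirectional_ensemble <- function(potential, schedule,
                                            n_F = 10, n_R = 10,
                                            params = langevin_params(),
                                            equil_time = 50) {
  stopifnot(n_F >= 0, n_R >= 0)
  if (n_F + n_R < 1) stop("n_F + n_R must be >= 1")
  if (schedule$direction != "forward")
    stop("schedule must describe the forward (unbinding) protocol")
  check_stability(potential, schedule, params)
  set.seed(params$seed)
  nseed <- 2L * max(n_F, n_R) + n_F + n_R
  seeds <- sample.int(.Machine$integer.max - 1L, nseed)
  seed_eq_F <- seeds[seq_len(max(n_F, n_R))]
  seed_eq_R <- seeds[max(n_F, n_R) + seq_len(max(n_F, n_R))]
  seed_pull <- seeds[2L * max(n_F, n_R) + seq_len(n_F + n_R)]
  lam_a <- schedule$lambda0
  lam_b <- schedule$lambda0 + schedule$velocity * schedule$duration
  rev_schedule <- pull_schedule(lam_b, -schedule$velocity, schedule$kappa,
                                schedule$duration, schedule$dt_sample,
                                "reverse")
  with_seed <- function(s) {
    p <- params; p$seed <- s; p
  }
  forward <- vector("list", n_F)
  for (i in seq_len(n_F)) {
    x0 <- relax_at_lambda(potential, lam_a, schedule$kappa, equil_time,
                          params, lam_a, seed_eq_F[i])
    forward[[i]] <- simulate_pulled_langevin(potential, schedule,
                                             with_seed(seed_pull[i]),
                                             x0 = x0)
  }
  reverse <- vector("list", n_R)
  for (j in seq_len(n_R)) {
    if (n_F > 0) {
      partner <- forward[[(j - 1L) %% n_F + 1L]]
      xi_end <- partner$xi[length(partner$xi)]
    } else {
      xi_end <- lam_b
    }
    x0 <- relax_at_lambda(potential, lam_b, schedule$kappa, equil_time,
                          params, xi_end, seed_eq_R[j])
    reverse[[j]] <- simulate_pulled_langevin(potential, rev_schedule,
                                             with_seed(seed_pull[n_F + j]),
                                             x0 = x0)
  }
  trajectory_ensemble(forward, reverse, temperature = params$temperature)
}

#' Specification of a synthetic Gaussian coordinate ensemble
#'
#' Oracle input for the entropy machinery: frames drawn from a multivariate
#' normal with a prescribed covariance (plain Cartesian convention, nm^2) over
#' the 3N coordinates.
#'
#' @param n_atoms Number of atoms.
#' @param masses Atomic masses (amu), length `n_atoms`.
#' @param covariance 3N x 3N symmetric positive semidefinite matrix (nm^2), or
#'   a length-3N vector of per-coordinate variances (diagonal covariance).
#' @param n_frames Number of frames (>= 2).
#' @param seed Integer seed.
#' @param mean Optional 3N center; defaults to the origin.
#' @return Object of class `gaussian_ensemble_spec`.
#' @export
gaussian_ensemble_spec <- function(n_atoms, masses, covariance, n_frames,
                                   seed = 1L, mean = NULL) {
  stopifnot(n_atoms >= 1, length(masses) == n_atoms, all(masses > 0),
            n_frames >= 2)
  d <- 3L * n_atoms
  if (is.vector(covariance)) {
    if (length(covariance) != d) stop("variance vector must have length 3N")
    covariance <- diag(covariance, d)
  }
  if (!is.matrix(covariance) || any(dim(covariance) != d))
    stop("covariance must be 3N x 3N (atom-major coordinate order)")
  if (!isTRUE(all.equal(covariance, t(covariance), tolerance = 1e-8)))
    stop("covariance must be symmetric")
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("covariance must be positive semidefinite")
  structure(list(n_atoms = n_atoms, masses = masses, covariance = covariance,
                 n_frames = as.integer(n_frames), seed = as.integer(seed),
                 mean = mean %||% rep(0, d)),
            class = "gaussian_ensemble_spec")
}

#' Sample a Gaussian coordinate ensemble
#'
#' Draws `n_frames` frames from the multivariate normal defined by the spec.
#' Sampling goes through the eigendecomposition of the covariance, so exactly
#' semidefinite targets (including the zero matrix) are handled.
#'
#' @param spec A [gaussian_ensemble_spec()].
#' @param frame_period Time between frames (ps), metadata only.
#' @return A [coordinate_ensemble()].
#' @export
sample_gaussian_ensemble <- function(spec, frame_period = 1) {
  stopifnot(inherits(spec, "gaussian_ensemble_spec"))
  d <- 3L * spec$n_atoms
  eg <- eigen(spec$covariance, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), d)
  set.seed(spec$seed)
  Z <- matrix(rnorm(spec$n_frames * d), spec$n_frames, d)
  X <- sweep(Z %*% t(L), 2, spec$mean, `+`)
  frames <- array(NA_real_, c(spec$n_frames, spec$n_atoms, 3L))
  for (a in seq_len(spec$n_atoms))
    frames[, a, ] <- X[, (3L * (a - 1L) + 1L):(3L * a)]
  coordinate_ensemble(frames, spec$masses, frame_period = frame_period)
}

#' Default geometric criteria for hydrogen bonds
#'
#' Donor--acceptor distance below `max_da_distance` and donor-H...acceptor
#' deviation from linearity below `max_dha_deviation`, both strict.
#'
#' @param max_da_distance D--A cutoff (nm), default 0.35.
#' @param max_dha_deviation Deviation from linearity cutoff (degrees),
#'   default 30.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_da_distance = 0.35, max_dha_deviation = 30) {
  stopifnot(max_da_distance > 0, max_dha_deviation > 0)
  structure(list(max_da_distance = max_da_distance,
                 max_dha_deviation = max_dha_deviation),
            class = "hbond_criteria")
}

## internal: random 3x3 rotation matrix from the current RNG stream
random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    n <- sqrt(sum(q^2))
    if (n > 1e-8) break
  }
  q <- q / n
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Build a molecular scene with planted interactions and decoys
#'
#' Constructs atom positions whose ground-truth interaction counts are exact
#' by construction: `n_hbonds` protein-donor/drug-acceptor hydrogen bonds
#' (D--A 0.29 nm, linear), `n_bridges` single waters donating one hydrogen
#' bond each to a protein acceptor and a drug acceptor, and `n_hydrophobic`
#' apolar carbon pairs at 0.40 nm.  Near-miss decoys are always included:
#' a D--A pair 0.01 nm beyond the distance cutoff, a hydrogen bond bent 5
#' degrees beyond the angle cutoff, a water bonded to the protein only, and an
#' apolar pair 0.01 nm beyond the hydrophobic cutoff.  Motifs are placed on a
#' widely spaced grid with independent random orientations so they cannot
#' interact with one another.
#'
#' @param n_hbonds,n_bridges,n_hydrophobic Planted counts (each >= 0).
#' @param seed Integer seed for motif orientations.
#' @param criteria A [hbond_criteria()] defining the cutoffs the decoys sit
#'   just beyond.
#' @param hydrophobic_cutoff Apolar pair cutoff (nm), default 0.45.
#' @return Object of class `planted_scene`: list with `atoms` (data frame:
#'   id, x, y, z, element, role, molecule, h_parent), `expected` counts,
#'   `criteria` and `hydrophobic_cutoff`.
#' @export
build_planted_scene <- function(n_hbonds, n_bridges, n_hydrophobic,
                                seed = 1L, criteria = hbond_criteria(),
                                hydrophobic_cutoff = 0.45) {
  stopifnot(n_hbonds >= 0, n_bridges >= 0, n_hydrophobic >= 0)
  set.seed(seed)
  atoms <- list()
  add_atom <- function(pos, element, role, molecule, h_parent = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      x = pos[1], y = pos[2], z = pos[3], element = element, role = role,
      molecule = molecule, h_parent = h_parent, stringsAsFactors = FALSE)
    length(atoms)
  }
  cell <- 0L
  next_origin <- function() {
    cell <<- cell + 1L
    3 * c(cell %% 13L, (cell %/% 13L) %% 13L, cell %/% 169L)
  }
  place <- function(local) {           # rows = positions in local frame
    R <- random_rotation()
    sweep(local %*% t(R), 2, next_origin(), `+`)
  }
  dha <- function(dev_deg, da_target = NULL, d_dh = 0.10, d_ha = 0.19) {
    ## local geometry: H at origin, donor along +x, acceptor bent by dev
    th <- (180 - dev_deg) * pi / 180
    D <- c(d_dh, 0, 0)
    A <- d_ha * c(cos(th), sin(th), 0)
    if (!is.null(da_target)) {         # rescale H->A to hit a D--A distance
      Ahat <- A / sqrt(sum(A^2))
      g <- function(s) sqrt(sum((D - s * Ahat)^2)) - da_target
      s <- stats::uniroot(g, c(0.01, 2))$root
      A <- s * Ahat
    }
    rbind(H = c(0, 0, 0), D = D, A = A)
  }
  ## planted hydrogen bonds: linear, D--A = 0.29 nm
  for (i in seq_len(n_hbonds)) {
    g <- place(dha(0, da_target = 0.29))
    d_id <- add_atom(g["D", ], "N", "donor", "protein")
    add_atom(g["H", ], "H", "donor_H", "protein", h_parent = d_id)
    add_atom(g["A", ], "O", "acceptor", "drug")
  }
  ## planted water bridges: water O donates to protein and drug acceptors
  for (i in seq_len(n_bridges)) {
    ang <- 104.5 * pi / 180
    u1 <- c(1, 0, 0)
    u2 <- c(cos(ang), sin(ang), 0)
    local <- rbind(Ow = c(0, 0, 0),
                   H1 = 0.096 * u1, A1 = 0.28 * u1,
                   H2 = 0.096 * u2, A2 = 0.28 * u2)
    g <- place(local)
    o_id <- add_atom(g["Ow", ], "O", "water_O", "water")
    add_atom(g["H1", ], "H", "water_H", "water", h_parent = o_id)
    add_atom(g["H2", ], "H", "water_H", "water", h_parent = o_id)
    add_atom(g["A1", ], "O", "acceptor", "protein")
    add_atom(g["A2", ], "O", "acceptor", "drug")
  }
  ## planted hydrophobic contacts at 0.40 nm
  for (i in seq_len(n_hydrophobic)) {
    g <- place(rbind(c(0, 0, 0), c(0.40, 0, 0)))
    add_atom(g[1, ], "C", "apolar_C", "protein")
    add_atom(g[2, ], "C", "apolar_C", "drug")
  }
  ## decoys: each sits just beyond one cutoff
  g <- place(dha(0, da_target = criteria$max_da_distance + 0.01))
  d_id <- add_atom(g["D", ], "N", "donor", "protein")
  add_atom(g["H", ], "H", "donor_H", "protein", h_parent = d_id)
  add_atom(g["A", ], "O", "acceptor", "drug")
  g <- place(dha(criteria$max_dha_deviation + 5))
  d_id <- add_atom(g["D", ], "N", "donor", "protein")
  add_atom(g["H", ], "H", "donor_H", "protein", h_parent = d_id)
  add_atom(g["A", ], "O", "acceptor", "drug")
  ## water bonded to the protein side only (drug acceptor out of range)
  ang <- 104.5 * pi / 180
  local <- rbind(Ow = c(0, 0, 0),
                 H1 = 0.096 * c(1, 0, 0), A1 = 0.28 * c(1, 0, 0),
                 H2 = 0.096 * c(cos(ang), sin(ang), 0),
                 A2 = (criteria$max_da_distance + 0.01) *
                   c(cos(ang), sin(ang), 0))
  g <- place(local)
  o_id <- add_atom(g["Ow", ], "O", "water_O", "water")
  add_atom(g["H1", ], "H", "water_H", "water", h_parent = o_id)
  add_atom(g["H2", ], "H", "water_H", "water", h_parent = o_id)
  add_atom(g["A1", ], "O", "acceptor", "protein")
  add_atom(g["A2", ], "O", "acceptor", "drug")
  g <- place(rbind(c(0, 0, 0), c(hydrophobic_cutoff + 0.01, 0, 0)))
  add_atom(g[1, ], "C", "apolar_C", "protein")
  add_atom(g[2, ], "C", "apolar_C", "drug")

  df <- do.call(rbind, atoms)
  df$id <- seq_len(nrow(df))
  df <- df[, c("id", "x", "y", "z", "element", "role", "molecule",
               "h_parent")]
  structure(list(atoms = df,
                 expected = list(hbonds = n_hbonds, bridges = n_bridges,
                                 hydrophobic = n_hydrophobic),
                 criteria = criteria,
                 hydrophobic_cutoff = hydrophobic_cutoff),
            class = "planted_scene")
}
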