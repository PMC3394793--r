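#' Constant-velocity pulling schedule
#'
#' Defines the motion of the control parameter lambda (the anchor of the
#' harmonic guide) for one pulling protocol: lambda(t) = lambda0 + velocity * t.
#' The forward direction is the unbinding transition (lambda increasing); a
#' reverse (binding) schedule has negative velocity.
#'
#' @param lambda0 Control-parameter start position (nm).
#' @param velocity Pulling velocity (nm/ps); signed, negative for reverse.
#' @param kappa Spring constant of the harmonic guide (kJ/mol/nm^2).
#' @param duration Pull duration tau (ps).
#' @param dt_sample Sampling period (ps); must divide `duration`.
#' @param direction `"forward"` (unbinding, velocity >= 0) or `"reverse"`
#'   (binding, velocity <= 0).
#' @return An object of class `pull_schedule`.
#' @examples
#' sch <- pull_schedule(0, 5e-4, 1686.75, 5000, 1, "forward")
#' control_position(sch, 5000)   # 2.5 nm traversed
#' @seealso [control_position()], [spring_energy()], [pull_trajectory()]
#' @export
pull_schedule <- function(lambda0, velocity, kappa, duration, dt_sample,
                          direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(lambda0), is.numeric(velocity), is.numeric(kappa),
            is.numeric(duration), is.numeric(dt_sample))
  if (kappa <= 0) stop("kappa must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (dt_sample <= 0) stop("dt_sample must be > 0")
  nsteps <- duration / dt_sample
  if (abs(nsteps - round(nsteps)) > 1e-8)
    stop("dt_sample must divide duration")
  if (direction == "forward" && velocity < 0)
    stop("forward schedule requires velocity >= 0")
  if (direction == "reverse" && velocity > 0)
    stop("reverse schedule requires velocity <= 0")
  structure(list(lambda0 = lambda0, velocity = velocity, kappa = kappa,
                 duration = duration, dt_sample = dt_sample,
                 direction = direction),
            class = "pull_schedule")
}

#' @export
print.pull_schedule <- function(x, ...) {
  cat(sprintf("pull_schedule: %s, lambda0 = %g nm, v = %g nm/ps,\n",
              x$direction, x$lambda0, x$velocity))
  cat(sprintf("  kappa = %g kJ/mol/nm^2, duration = %g ps, dt = %g ps\n",
              x$kappa, x$duration, x$dt_sample))
  invisible(x)
}

#' Sampling times of a schedule
#' @param schedule A [pull_schedule()].
#' @return Numeric vector `seq(0, duration, by = dt_sample)`.
#' @export
schedule_times <- function(schedule) {
  seq(0, schedule$duration, by = schedule$dt_sample)
}

#' Position of the control parameter at time t
#'
#' @param schedule A [pull_schedule()].
#' @param t Time(s) in ps, each within `[0, duration]`.
#' @return lambda(t) = lambda0 + velocity * t (nm).
#' @export
control_position <- function(schedule, t) {
  stopifnot(inherits(schedule, "pull_schedule"))
  tol <- 1e-9 * max(1, schedule$duration)
  if (any(t < -tol | t > schedule$duration + tol))
    stop("t outside [0, duration]")
  schedule$lambda0 + schedule$velocity * t
}

#' Harmonic guiding potential
#'
#' u(xi, lambda) = (kappa/2) (xi - lambda)^2.  The corresponding spring force
#' on the pulled object is -du/dxi = kappa (lambda - xi).
#'
#' @param xi Collective coordinate (nm).
#' @param lam Control parameter (nm).
#' @param kappa Spring constant (kJ/mol/nm^2).
#' @return Energy in kJ/mol.
#' @export
spring_energy <- function(xi, lam, kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0")
  0.5 * kappa * (xi - lam)^2
}

#' Spring force on the pulled object
#' @inheritParams spring_energy
#' @return Force kappa (lambda - xi) in kJ/mol/nm.
#' @export
spring_force <- function(xi, lam, kappa) {
  if (any(kappa <= 0)) stop("kappa must be > 0")
  kappa * (lam - xi)
}

#' One pulling realization
#'
#' Container for a single constant-velocity pulling trajectory: sampled time,
#' control parameter lambda(t), collective coordinate xi(t), instantaneous
#' spring force and accumulated net work.  If `force` or `work` are omitted
#' they are computed from the schedule ([spring_force()], [accumulate_work()]).
#'
#' @param schedule A [pull_schedule()].
#' @param time Sample times (ps), starting at 0.
#' @param xi Collective coordinate at each sample (nm).
#' @param temperature Temperature (K).
#' @param force Optional spring force (kJ/mol/nm); validated against
#'   kappa (lambda - xi).
#' @param work Optional accumulated work (kJ/mol).
#' @param subtract_initial Passed to [accumulate_work()] when work is computed.
#' @return An object of class `pull_trajectory`.
#' @export
pull_trajectory <- function(schedule, time, xi, temperature = 300,
                            force = NULL, work = NULL,
                            subtract_initial = TRUE) {
  stopifnot(inherits(schedule, "pull_schedule"))
  n <- length(time)
  if (length(xi) != n) stop("time and xi must have equal length")
  if (n < 2L) stop("need at least two samples")
  if (abs(time[1]) > 1e-9) stop("time must start at 0")
  lam <- control_position(schedule, time)
  if (is.null(force)) {
    force <- spring_force(xi, lam, schedule$kappa)
  } else {
    if (length(force) != n) stop("force length mismatch")
    if (max(abs(force - spring_force(xi, lam, schedule$kappa))) >
        1e-6 * (1 + max(abs(force))))
      stop("force inconsistent with kappa*(lambda - xi)")
  }
  traj <- structure(list(schedule = schedule, time = time, lam = lam,
                         xi = xi, force = force, work = NULL,
                         temperature = temperature),
                    class = "pull_trajectory")
  if (is.null(work)) {
    traj$work <- accumulate_work(traj, subtract_initial = subtract_initial)
  } else {
    if (length(work) != n) stop("work length mismatch")
    traj$work <- work
  }
  traj
}

#' @export
print.pull_trajectory <- function(x, ...) {
  cat(sprintf("pull_trajectory (%s): %d frames over %g ps, T = %g K\n",
              x$schedule$direction, length(x$time), max(x$time),
              x$temperature))
  cat(sprintf("  lambda: %.4f -> %.4f nm;  W(tau) = %.3f kJ/mol\n",
              x$lam[1], x$lam[length(x$lam)], x$work[length(x$work)]))
  invisible(x)
}

#' Accumulated net work along a pulling trajectory
#'
#' Evaluates the force-extension contour integral W(t) = int f dlambda by the
#' trapezoidal (midpoint-in-lambda) Riemann rule, then subtracts the initial
#' energy stored in the spring, u(xi(0), lambda(0)), so that the result is the
#' net work imparted on the system.  For a guide that starts at rest on the
#' pulled coordinate the subtracted term is zero and W(0) = 0.
#'
#' @param traj A [pull_trajectory()] (its `force` and `lam` fields are used).
#' @param subtract_initial Subtract the frame-0 spring energy (default TRUE).
#' @return Numeric vector of accumulated work (kJ/mol), same length as the
#'   trajectory.
#' @export
accumulate_work <- function(traj, subtract_initial = TRUE) {
  stopifnot(inherits(traj, "pull_trajectory"))
  f <- traj$force
  lam <- traj$lam
  if (length(f) != length(lam)) stop("mismatched array lengths")
  dlam <- diff(lam)
  fbar <- (f[-1] + f[-length(f)]) / 2
  w <- c(0, cumsum(fbar * dlam))
  if (subtract_initial)
    w <- w - spring_energy(traj$xi[1], lam[1], traj$schedule$kappa)
  w
}

#' Ensemble of forward and reverse pulling realizations
#'
#' @param forward List of forward [pull_trajectory()] objects (may be empty).
#' @param reverse List of reverse [pull_trajectory()] objects (may be empty).
#' @param temperature Temperature (K); all members must agree.
#' @return An object of class `trajectory_ensemble` with fields `forward`,
#'   `reverse`, `beta`, `temperature`.
#' @export
trajectory_ensemble <- function(forward = list(), reverse = list(),
                                temperature = 300) {
  if (length(forward) + length(reverse) < 1L)
    stop("ensemble needs at least one trajectory")
  all_traj <- c(forward, reverse)
  stopifnot(all(vapply(all_traj, inherits, TRUE, "pull_trajectory")))
  kap <- vapply(all_traj, function(x) x$schedule$kappa, 0)
  spd <- vapply(all_traj, function(x) abs(x$schedule$velocity), 0)
  dts <- vapply(all_traj, function(x) x$schedule$dt_sample, 0)
  dur <- vapply(all_traj, function(x) x$schedule$duration, 0)
  if (diff(range(kap)) > 1e-9 || diff(range(spd)) > 1e-12 ||
      diff(range(dts)) > 1e-9 || diff(range(dur)) > 1e-6)
    stop("all ensemble members must share kappa, |velocity| and sampling grid")
  for (tr in forward)
    if (tr$schedule$direction != "forward") stop("misplaced reverse trajectory")
  for (tr in reverse)
    if (tr$schedule$direction != "reverse") stop("misplaced forward trajectory")
  structure(list(forward = forward, reverse = reverse,
                 beta = beta_of(temperature), temperature = temperature),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("trajectory_ensemble: %d forward + %d reverse pulls, T = %g K\n",
              length(x$forward), length(x$reverse), x$temperature))
  invisible(x)
}

#' Align forward and reverse works and positions on a common lambda grid
#'
#' Estimators need the works of both directions expressed at the same physical
#' control-parameter values.  Grid point g holds, for every forward
#' realization, the work (and xi) when its control first reaches lambda_g, and
#' for every reverse realization the work accumulated from its own start (the
#' lambda_b end) until its control reaches lambda_g.  The reverse time axis is
#' flipped here and only here; stored trajectories keep simulation order.
#'
#' Each realization's work is re-zeroed at its own start grid point, i.e. the
#' gridded works are the raw force-extension contour integrals from the
#' moment the pull begins.  This undoes the stored net-work offset (the
#' subtracted initial spring energy) at the estimator boundary: for starts
#' equilibrated under the guide at the end states, the raw switching work is
#' the quantity the fluctuation theorems apply to exactly, and it makes the
#' bidirectional curve reproduce the Bennett end-state solution identically.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param n_grid Number of lambda grid points (default: the shared sample
#'   count, i.e. one slice per sampling period).
#' @return A list of class `lambda_grid_works` with elements `lambda` (grid,
#'   increasing from lambda_a to lambda_b), `W_F`, `Xi_F` (n_F x G matrices),
#'   `W_R`, `Xi_R` (n_R x G), `beta`, `kappa`, `n_F`, `n_R`.
#' @export
resample_on_lambda_grid <- function(ensemble, n_grid = NULL) {
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  fw <- ensemble$forward; rv <- ensemble$reverse
  ref <- c(fw, rv)[[1]]
  sch <- ref$schedule
  if (abs(sch$velocity) <= 0)
    stop("lambda grid undefined for a static (v = 0) schedule")
  ## end states lambda_a (bound) < lambda_b (unbound)
  lam_ends <- range(sch$lambda0,
                    sch$lambda0 + sch$velocity * sch$duration)
  ## check all schedules traverse the same lambda interval
  for (tr in c(fw, rv)) {
    s <- tr$schedule
    e <- range(s$lambda0, s$lambda0 + s$velocity * s$duration)
    if (max(abs(e - lam_ends)) > 1e-6)
      stop("inconsistent schedules: lambda ranges differ across ensemble")
  }
  if (is.null(n_grid)) n_grid <- length(ref$time)
  grid <- seq(lam_ends[1], lam_ends[2], length.out = n_grid)
  interp_dir <- function(trajs) {
    W <- matrix(NA_real_, length(trajs), n_grid)
    X <- matrix(NA_real_, length(trajs), n_grid)
    for (i in seq_along(trajs)) {
      tr <- trajs[[i]]
      ## times at which this trajectory's control visits each grid value
      tg <- (grid - tr$schedule$lambda0) / tr$schedule$velocity
      W[i, ] <- stats::approx(tr$time, tr$work, xout = tg, rule = 2)$y
      W[i, ] <- W[i, ] - tr$work[1]      # re-zero at the realization start
      X[i, ] <- stats::approx(tr$time, tr$xi,   xout = tg, rule = 2)$y
    }
    list(W = W, X = X)
  }
  f <- interp_dir(fw); r <- interp_dir(rv)
  structure(list(lambda = grid, W_F = f$W, Xi_F = f$X,
                 W_R = r$W, Xi_R = r$X,
                 beta = ensemble$beta, kappa = sch$kappa,
                 n_F = length(fw), n_R = length(rv)),
            class = "lambda_grid_works")
}
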