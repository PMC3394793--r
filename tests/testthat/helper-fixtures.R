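## Shared fixture builders and independent oracles.

kT300 <- 1 / beta_of(300)

## Independent oracle: free energy of the guide-extended system,
## F(lambda) = -kT log int exp(-beta (G_true(x) + kappa/2 (x - lambda)^2)) dx,
## by direct quadrature on a fine grid.
biased_free_energy <- function(potential, lambda, kappa, beta,
                               xlim = c(-1, 3.5), dx = 5e-4) {
  xs <- seq(xlim[1], xlim[2], by = dx)
  gt <- potential_energy(potential, xs)
  vapply(lambda, function(l) {
    -1 / beta * (log(sum(exp(-beta * (gt + 0.5 * kappa * (xs - l)^2)))) +
                   log(dx))
  }, 0)
}

## Stable log-mean-exp, written independently of the package internals
logmeanexp_test <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

## RMS difference after removing the (unidentifiable) additive constant
rms_after_shift <- function(a, b) {
  d <- a - b
  sqrt(mean((d - mean(d))^2))
}

## Reference pulling protocol
protocol_schedule <- function(lambda0 = 0, velocity = 5e-4,
                              kappa = 1686.75, duration = 5000,
                              dt_sample = 1) {
  pull_schedule(lambda0, velocity, kappa, duration, dt_sample, "forward")
}

## Hand-built grid-works object for exact estimator algebra tests
toy_grid_works <- function(lambda, W_F, W_R, Xi_F = NULL, Xi_R = NULL,
                           beta = beta_of(300), kappa = 100) {
  structure(list(lambda = lambda, W_F = W_F,
                 Xi_F = Xi_F %||% W_F * 0,
                 W_R = W_R, Xi_R = Xi_R %||% W_R * 0,
                 beta = beta, kappa = kappa,
                 n_F = nrow(W_F), n_R = nrow(W_R)),
            class = "lambda_grid_works")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic smooth trajectory (no thermal noise) for quadrature tests
smooth_trajectory <- function(schedule, lag = 0.02, dt_sample = NULL) {
  if (!is.null(dt_sample)) {
    schedule <- pull_schedule(schedule$lambda0, schedule$velocity,
                              schedule$kappa, schedule$duration, dt_sample,
                              schedule$direction)
  }
  tt <- schedule_times(schedule)
  lam <- control_position(schedule, tt)
  xi <- lam - lag * (1 - exp(-tt / 50))
  pull_trajectory(schedule, tt, xi, temperature = 300)
}
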