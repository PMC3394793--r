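test_that("Jarzynski curve: degenerate and Gaussian closed forms", {
  beta <- beta_of(300)
  lam <- seq(0, 1, length.out = 6)
  ## single realization: the curve is the work itself
  W1 <- matrix(c(0, 1, 3, 2, 5, 4), 1)
  gw1 <- toy_grid_works(lam, W1, matrix(0, 1, 6), beta = beta)
  expect_equal(jarzynski_curve(gw1, "forward")$delta_F, W1[1, ])
  ## all works equal w: the curve is w
  Wm <- matrix(rep(c(0, 1, 3, 2, 5, 4), each = 4), 4)
  gwm <- toy_grid_works(lam, Wm, matrix(0, 1, 6), beta = beta)
  expect_equal(jarzynski_curve(gwm, "forward")$delta_F, Wm[1, ])
  ## i.i.d. Gaussian works: dF -> mu - beta sigma^2 / 2 within 3 SE
  set.seed(101)
  mu <- 8; sig <- 1.5; n <- 1e4
  W <- cbind(0, matrix(rnorm(n, mu, sig), n))
  gww <- toy_grid_works(c(0, 1), W, matrix(0, 1, 2), beta = beta)
  est <- jarzynski_curve(gww, "forward")$delta_F[2]
  ex <- exp(-beta * W[, 2])
  se <- sd(ex) / (mean(ex) * sqrt(n)) / beta
  expect_lt(abs(est - (mu - beta * sig^2 / 2)), 3 * se)
})

test_that("exponential averages are computed safely in log space", {
  beta <- beta_of(300)
  big <- 700 / beta
  W <- cbind(c(0, 0), c(-big, big))
  gw <- toy_grid_works(c(0, 1), W, matrix(0, 1, 2), beta = beta)
  dF <- jarzynski_curve(gw, "forward")$delta_F
  expect_true(all(is.finite(dF)))
  expect_equal(dF[2], -big + log(2) / beta)   # dominated by the -big sample
})

test_that("BAR solves the Bennett equation self-consistently", {
  beta <- beta_of(300)
  ## symmetric single samples: dF = w by hand
  b <- bar_delta_f(5, -5, beta)
  expect_equal(b$delta_F, 5, tolerance = 1e-7)
  expect_true(b$converged)
  expect_equal(bar_delta_f(0, 0, beta)$delta_F, 0, tolerance = 1e-10)
  expect_error(bar_delta_f(numeric(0), 1, beta), "jarzynski")
  ## Crooks-consistent Gaussian samples recover the planted dF
  set.seed(202)
  dF_true <- 5; d <- 2; n <- 1000
  sig <- sqrt(2 * d / beta)
  WF <- rnorm(n, dF_true + d, sig)
  WR <- rnorm(n, -dF_true + d, sig)
  est <- bar_delta_f(WF, WR, beta)$delta_F
  boot <- vapply(1:200, function(i) {
    bar_delta_f(sample(WF, n, TRUE), sample(WR, n, TRUE), beta,
                tol = 1e-6)$delta_F
  }, 0)
  expect_lt(abs(est - dF_true), 3 * sd(boot))
})

test_that("BAR has no larger variance than either Jarzynski estimate", {
  beta <- beta_of(300)
  set.seed(203)
  dF_true <- 4; d <- 3; n <- 120
  sig <- sqrt(2 * d / beta)
  WF <- rnorm(n, dF_true + d, sig)
  WR <- rnorm(n, -dF_true + d, sig)
  jarz <- function(w) -logmeanexp_test(-beta * w) / beta
  boots <- t(vapply(1:200, function(i) {
    wf <- sample(WF, n, TRUE); wr <- sample(WR, n, TRUE)
    c(bar = bar_delta_f(wf, wr, beta, tol = 1e-6)$delta_F,
      jf = jarz(wf), jr = -jarz(wr))
  }, c(bar = 0, jf = 0, jr = 0)))
  v <- apply(boots, 2, var)
  expect_lte(v["bar"], min(v["jf"], v["jr"]))
})

test_that("MA curve reduces to BAR at the end states", {
  pot <- harmonic_potential(a = 300)
  sch <- protocol_schedule(duration = 1000)
  ens <- generate_bidirectional_ensemble(pot, sch, 6, 6,
                                         langevin_params(seed = 71))
  gw <- resample_on_lambda_grid(ens)
  bar <- bar_delta_f(gw$W_F[, ncol(gw$W_F)], gw$W_R[, 1], gw$beta)
  mac <- ma_curve(gw, bar)
  expect_lt(abs(mac$delta_F[length(mac$delta_F)] - bar$delta_F), 1e-10)
  expect_identical(mac$delta_F[1], 0)
})

test_that("degenerate all-equal works give the same flat curves for MA and CP", {
  beta <- beta_of(300)
  lam <- seq(0, 1, length.out = 11)
  w <- seq(0, 7, length.out = 11)
  W_F <- matrix(rep(w, each = 3), 3)
  W_R <- matrix(rep(w - w[11], each = 3), 3)   # consistent reverse records
  gw <- toy_grid_works(lam, W_F, W_R, beta = beta)
  mac <- ma_curve(gw); cpc <- cp_curve(gw)
  expect_equal(mac$delta_F, w, tolerance = 1e-12)
  expect_equal(cpc$delta_F, mac$delta_F, tolerance = 1e-12)
})

test_that("bidirectional lambda-curve beats either unidirectional estimate", {
  a <- 300; kap <- 1686.75
  pot <- harmonic_potential(a = a, x0 = 0)
  sch <- protocol_schedule(duration = 2000)   # 1 nm pull
  ens <- generate_bidirectional_ensemble(pot, sch, 10, 10,
                                         langevin_params(seed = 72))
  gw <- resample_on_lambda_grid(ens)
  dF_true <- biased_free_energy(pot, gw$lambda, kap, gw$beta)
  dF_true <- dF_true - dF_true[1]
  rms <- function(curve) sqrt(mean((curve$delta_F - dF_true)^2))
  r_ma <- rms(ma_curve(gw))
  expect_lt(r_ma, rms(jarzynski_curve(gw, "forward")))
  expect_lt(r_ma, rms(jarzynski_curve(gw, "reverse")))
})

test_that("CP estimator interpolates between its limiting regimes", {
  pot <- gorge_potential()
  ## quasi-reversible (50x slower): CP reduces to the Jarzynski equality
  sch_s <- pull_schedule(0, 1e-5, 1686.75, 250000, 50, "forward")
  ens_s <- generate_bidirectional_ensemble(pot, sch_s, 10, 10,
                                           langevin_params(seed = 5))
  gws <- resample_on_lambda_grid(ens_s)
  expect_lt(max(abs(cp_curve(gws)$delta_F -
                      jarzynski_curve(gws, "forward")$delta_F)),
            0.2 * kT300)
  ## strongly dissipative (10x faster): CP behaves as the MA estimator
  sch_f <- pull_schedule(0, 5e-3, 1686.75, 500, 0.1, "forward")
  ens_f <- generate_bidirectional_ensemble(pot, sch_f, 10, 10,
                                           langevin_params(seed = 6))
  gwf <- resample_on_lambda_grid(ens_f)
  expect_lt(max(abs(cp_curve(gwf)$delta_F - ma_curve(gwf)$delta_F)),
            0.5 * kT300)
})

test_that("Hummer-Szabo unbiasing recovers G(xi)", {
  a <- 100; kap <- 1686.75
  pot <- harmonic_potential(a = a, x0 = 0.3, domain = c(-0.5, 1.5))
  sch <- pull_schedule(-0.2, 5e-4, kap, 2000, 1, "forward")
  ens <- generate_bidirectional_ensemble(pot, sch, 20, 0,
                                         langevin_params(seed = 73))
  prof <- hs_pmf(ens, "forward")
  ok <- is.finite(prof$G)
  gt <- potential_energy(pot, prof$xi_bins[ok])
  expect_lt(rms_after_shift(prof$G[ok], gt), 0.5 * kT300)
  ## stiff spring: G(xi) coincides with dF(lambda) evaluated at lambda = xi
  jf <- jarzynski_curve(ens, "forward")
  dF_at_xi <- approx(jf$lam_grid, jf$delta_F, xout = prof$xi_bins[ok])$y
  inner <- !is.na(dF_at_xi)
  expect_lt(rms_after_shift(prof$G[ok][inner], dF_at_xi[inner]), 0.3 * kT300)
})

test_that("bins never visited are masked, not zero", {
  pot <- harmonic_potential(a = 100)
  ens <- generate_bidirectional_ensemble(pot, protocol_schedule(duration = 200),
                                         2, 0, langevin_params(seed = 74))
  gw <- resample_on_lambda_grid(ens)
  bins <- make_xi_bins(range(gw$Xi_F) + c(0, 0.5), width = 0.025)
  expect_warning(prof <- hs_pmf(gw, "forward", bins = bins), NA)
  expect_true(anyNA(prof$G))
  expect_equal(prof$n_samples[is.na(prof$G)],
               rep(0L, sum(is.na(prof$G))))
})

test_that("PMF profiles are invariant to relabeling the pulling direction", {
  pot <- harmonic_potential(a = 300)
  sch <- protocol_schedule(duration = 1000)
  ens <- generate_bidirectional_ensemble(pot, sch, 5, 5,
                                         langevin_params(seed = 75))
  mirror_traj <- function(tr, direction) {
    s <- tr$schedule
    sch2 <- pull_schedule(-s$lambda0, -s$velocity, s$kappa, s$duration,
                          s$dt_sample, direction)
    pull_trajectory(sch2, tr$time, -tr$xi, temperature = tr$temperature,
                    force = -tr$force, work = tr$work)
  }
  ens_m <- trajectory_ensemble(
    forward = lapply(ens$reverse, mirror_traj, direction = "forward"),
    reverse = lapply(ens$forward, mirror_traj, direction = "reverse"))
  p1 <- bidirectional_pmf(ens, "ma", bin_width = 0.025)
  p2 <- bidirectional_pmf(ens_m, "ma", bin_width = 0.025)
  g2 <- approx(-p2$xi_bins, p2$G, xout = p1$xi_bins)$y
  ok <- is.finite(p1$G) & is.finite(g2)
  expect_gt(sum(ok), 10)
  expect_lt(rms_after_shift(p1$G[ok], g2[ok]), 0.1 * kT300)
})

test_that("profiles converge by 8 realizations per direction", {
  pot <- gorge_potential()
  ens <- generate_bidirectional_ensemble(pot, protocol_schedule(), 10, 10,
                                         langevin_params(seed = 11))
  p10 <- bidirectional_pmf(ens, "ma")
  sub <- trajectory_ensemble(ens$forward[1:8], ens$reverse[1:8])
  p8 <- bidirectional_pmf(sub, "ma")
  ok <- is.finite(p10$G) & is.finite(p8$G)
  expect_lt(rms_after_shift(p10$G[ok], p8$G[ok]), 0.5 * kT300)
})

test_that("Jensen bound: Jarzynski estimate never exceeds the mean work", {
  pot <- gorge_potential()
  ens <- generate_bidirectional_ensemble(pot, protocol_schedule(duration = 1000),
                                         8, 0, langevin_params(seed = 76))
  gw <- resample_on_lambda_grid(ens)
  jf <- jarzynski_curve(gw, "forward")
  mw <- colMeans(gw$W_F)
  expect_true(all(jf$delta_F <= (mw - mw[1]) + 1e-9))
})

test_that("global work offsets only move the anchor", {
  beta <- beta_of(300)
  lam <- seq(0, 1, length.out = 8)
  set.seed(303)
  W_F <- cbind(0, matrix(cumsum(runif(7)), 4, 7, byrow = TRUE) +
                 matrix(rnorm(28, 0, 0.3), 4))
  W_R <- -W_F[, 8] + W_F       # roughly consistent reverse works
  W_R <- W_R - W_R[, 8]
  gw <- toy_grid_works(lam, W_F, W_R, beta = beta)
  gw_off <- toy_grid_works(lam, W_F + 3, W_R, beta = beta)
  m1 <- ma_curve(gw)$delta_F
  ## the offset changes end-state balance, but anchoring keeps dF[1] = 0
  expect_identical(ma_curve(gw_off)$delta_F[1], 0)
  expect_identical(m1[1], 0)
})

test_that("basin and barrier detection with prominence filtering", {
  beta <- beta_of(300)
  ## V-shaped profile: one basin, no barrier
  xi <- seq(0, 1, by = 0.025)
  v <- abs(xi - 0.5) * 40
  pv <- pmf_profile(xi, v, "ma_bidirectional", beta, 0.025)
  rep_v <- locate_basins_barriers(pv, min_prominence = 1)
  expect_equal(rep_v$extrema$kind, "basin")
  expect_equal(rep_v$extrema$xi, 0.5)
  expect_equal(nrow(rep_v$barrier_heights), 0L)
  ## symmetric double well: both directional heights equal the barrier
  b <- 12
  w <- b * (((xi - 0.5) / 0.3)^2 - 1)^2
  pw <- pmf_profile(xi, w, "ma_bidirectional", beta, 0.025)
  rep_w <- locate_basins_barriers(pw, min_prominence = 1)
  expect_equal(rep_w$extrema$kind, c("basin", "barrier", "basin"))
  hts <- rep_w$barrier_heights$dG_kcal_mol
  expect_equal(length(hts), 2L)
  expect_equal(hts[1], hts[2], tolerance = 1e-6)
  expect_equal(hts[1], kj_to_kcal(b), tolerance = 0.05)
  ## monotone profile: no internal extrema
  pm <- pmf_profile(xi, 30 * xi, "ma_bidirectional", beta, 0.025)
  expect_equal(nrow(locate_basins_barriers(pm, 1)$extrema), 0L)
  ## plateaus collapse to their midpoint bin
  gplat <- c(5, 3, 1, 1, 1, 3, 5)
  pp <- pmf_profile(seq_len(7) / 10, gplat, "ma_bidirectional", beta, 0.1)
  rp <- locate_basins_barriers(pp, min_prominence = 1)
  expect_equal(rp$extrema$xi, 0.4)
  ## shallow ripples below the prominence threshold are pruned
  gr <- 30 * xi + 0.2 * sin(40 * xi)
  pr <- pmf_profile(xi, gr, "ma_bidirectional", beta, 0.025)
  expect_equal(nrow(locate_basins_barriers(pr, min_prominence = 1)$extrema),
               0L)
  expect_error(locate_basins_barriers(
    pmf_profile(xi, rep(NA_real_, length(xi)), "ma_bidirectional", beta,
                0.025), 1), "unmasked")
})
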