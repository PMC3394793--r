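test_that("window arithmetic matches the reference protocol", {
  expect_length(make_windows(window_spec(5000, 400, 20)), 230)
  expect_length(make_windows(window_spec(400, 400, 20)), 1)
  expect_length(make_windows(window_spec(10, 4, 2)), 3)
  expect_error(window_spec(100, 400, 20), "window_len")
  ## coverage: (n_windows * stride + window_len) frames at v = 5e-4 nm/ps,
  ## 1 ps per frame, spans the full 2.5 nm pulling range
  expect_equal((230 * 20 + 400) * 1 * 5e-4, 2.5)
})

test_that("window axis maps strides and spans to control displacement", {
  sch <- protocol_schedule()
  spec <- window_spec(5000, 400, 20)
  lam <- window_lambda_axis(spec, sch, frame_period = 1)
  expect_length(lam, 230)
  expect_equal(unique(round(diff(lam), 12)), 0.01)   # per-stride shift
  expect_equal(400 * 1 * 5e-4, 0.2)                  # per-window span
})

test_that("mass-weighted covariance definition", {
  ## identical frames: zero matrix
  fr <- array(rep(c(0.1, 0.2, 0.3), each = 4), c(4, 1, 3))
  ce <- coordinate_ensemble(fr, masses = 12)
  expect_equal(max(abs(mass_weighted_covariance(ce))), 0)
  ## one atom fluctuating along x with unit mass: eigenvalue = sample variance
  set.seed(11)
  x <- rnorm(100, 0, 0.05)
  fr2 <- array(0, c(100, 1, 3)); fr2[, 1, 1] <- x
  ce2 <- coordinate_ensemble(fr2, masses = 1)
  sp <- covariance_spectrum(mass_weighted_covariance(ce2))
  expect_equal(sp$eigenvalues[1], var(x))
  expect_equal(sp$n_retained, 1L)
  ## mass weighting scales the spectrum linearly
  ce3 <- coordinate_ensemble(fr2, masses = 16)
  sp3 <- covariance_spectrum(mass_weighted_covariance(ce3))
  expect_equal(sp3$eigenvalues[1], 16 * var(x))
  expect_error(mass_weighted_covariance(ce2, c(1, 1)), "at least 2")
})

test_that("sampled covariance matches the generator oracle", {
  set.seed(21)
  A <- matrix(rnorm(36, 0, 0.1), 6)
  Sigma <- crossprod(A)
  masses <- c(12, 16)
  sp <- gaussian_ensemble_spec(2, masses, Sigma, 4000, seed = 5)
  ce <- sample_gaussian_ensemble(sp)
  got <- mass_weighted_covariance(ce)
  w <- sqrt(rep(masses, each = 3))
  want <- Sigma * tcrossprod(w)
  expect_lt(norm(got - want, "F") / norm(want, "F"), 0.15)
})

test_that("quantum quasiharmonic entropy matches the analytic oscillator", {
  pc <- phys_constants(); kT <- pc$kB * 300
  m <- 12; k <- 1000
  sp <- gaussian_ensemble_spec(1, m, c(kT / k, 0, 0), 5000, seed = 2)
  ce <- sample_gaussian_ensemble(sp)
  spec <- covariance_spectrum(mass_weighted_covariance(ce))
  expect_equal(spec$n_retained, 1L)   # the two frozen axes are floored away
  omega <- sqrt(kT / spec$eigenvalues[1])
  expect_lt(abs(omega / sqrt(k / m) - 1), 0.05)
  a <- pc$hbar * sqrt(k / m) / kT
  S_true <- pc$kB * (a / expm1(a) - log1p(-exp(-a)))
  expect_lt(abs(quantum_qh_entropy(spec, 300) / S_true - 1), 0.05)
})

test_that("quantum entropy: frozen modes vanish, softening increases S", {
  S1 <- quantum_qh_entropy(c(1e-3, 1e-2), 300)
  ## an (almost) frozen extra mode adds nothing
  expect_equal(quantum_qh_entropy(c(1e-3, 1e-2, 1e-13), 300), S1)
  expect_gt(quantum_qh_entropy(c(2e-3, 2e-2), 300), S1)
  ## a vanishing eigenvalue contributes nothing
  expect_lt(quantum_qh_entropy(1e-10, 300), 1e-12)
  expect_error(quantum_qh_entropy(numeric(0), 300), "empty")
})

test_that("Schlitter bound dominates the quantum entropy on any spectrum", {
  expect_equal(schlitter_entropy(numeric(0), 300), 0)
  set.seed(31)
  for (i in 1:100) {
    ev <- 10^runif(sample(1:12, 1), -9, 1)
    expect_gte(schlitter_entropy(ev, 300), quantum_qh_entropy(ev, 300))
  }
  ## logarithmic growth for a single dominant eigenvalue
  pc <- phys_constants()
  gap <- schlitter_entropy(10, 300) - schlitter_entropy(1, 300)
  expect_equal(gap, 0.5 * pc$kB * log(10), tolerance = 1e-3)
})

test_that("windowed profiles track the time dependence of the fluctuations", {
  masses <- c(12, 16, 14)
  n_fr <- 600
  make_traj <- function(seed, ramp = FALSE) {
    set.seed(seed)
    sd_t <- if (ramp) 0.02 * (1 + 3 * seq_len(n_fr) / n_fr) else
      rep(0.04, n_fr)
    fr <- array(rnorm(n_fr * 9, 0, sd_t), c(n_fr, 3, 3))
    coordinate_ensemble(fr, masses)
  }
  spec <- window_spec(n_fr, 100, 25)
  ## stationary process: flat profile within sampling noise
  flat <- windowed_entropy_profile(lapply(1:5, make_traj), spec, 300)
  expect_lt(diff(range(flat$S_kJ_mol_K)) / mean(flat$S_kJ_mol_K), 0.05)
  ## variance ramping in time: monotone increasing trend
  ramp <- windowed_entropy_profile(lapply(1:5, make_traj, ramp = TRUE),
                                  spec, 300)
  expect_gt(cor(ramp$window, ramp$S_kJ_mol_K), 0.95)
  ## a single window spanning everything equals the whole-ensemble entropy
  one <- windowed_entropy_profile(make_traj(99), window_spec(n_fr, n_fr, 1),
                                 300)
  expect_equal(nrow(one), 1L)
  whole <- quantum_qh_entropy(
    covariance_spectrum(mass_weighted_covariance(make_traj(99))), 300)
  expect_equal(one$S_kJ_mol_K, whole)
})

test_that("relative profiles are zero against themselves and need a reference", {
  set.seed(41)
  fr <- array(rnorm(200 * 6, 0, 0.05), c(200, 2, 3))
  ce <- coordinate_ensemble(fr, c(12, 12))
  spec <- window_spec(200, 200, 1)
  prof <- windowed_entropy_profile(ce, spec, 300)
  rel <- relative_entropy_profile(prof, ce, 300)
  expect_equal(rel$TdS_kcal_mol, 0)
  expect_error(relative_entropy_profile(prof, NULL), "reference")
})

test_that("escaping a tight well raises T dS along the pull", {
  masses <- rep(12, 2)
  n_fr <- 500
  set.seed(42)
  sd_t <- 0.01 * (1 + 9 * seq_len(n_fr) / n_fr)    # tight well -> wide region
  fr <- array(rnorm(n_fr * 6, 0, sd_t), c(n_fr, 2, 3))
  ce <- coordinate_ensemble(fr, masses)
  spec <- window_spec(n_fr, 100, 40)
  prof <- windowed_entropy_profile(ce, spec, 300)
  ref <- coordinate_ensemble(fr[1:100, , , drop = FALSE], masses)
  rel <- relative_entropy_profile(prof, ref, 300)
  expect_gt(rel$TdS_kcal_mol[nrow(rel)], rel$TdS_kcal_mol[1])
  expect_gt(rel$TdS_kcal_mol[nrow(rel)], 0)
})

test_that("entropy is invariant under translation and atom reordering", {
  set.seed(51)
  fr <- array(rnorm(300 * 9, 0, 0.05), c(300, 3, 3))
  masses <- c(12, 16, 1)
  S0 <- quantum_qh_entropy(
    covariance_spectrum(mass_weighted_covariance(
      coordinate_ensemble(fr, masses))), 300)
  fr_shift <- fr
  fr_shift[, , 1] <- fr_shift[, , 1] + 5
  fr_shift[, , 3] <- fr_shift[, , 3] - 2
  S_shift <- quantum_qh_entropy(
    covariance_spectrum(mass_weighted_covariance(
      coordinate_ensemble(fr_shift, masses))), 300)
  expect_equal(S_shift, S0, tolerance = 1e-10)
  perm <- c(3, 1, 2)
  S_perm <- quantum_qh_entropy(
    covariance_spectrum(mass_weighted_covariance(
      coordinate_ensemble(fr[, perm, , drop = FALSE], masses[perm]))), 300)
  expect_equal(S_perm, S0, tolerance = 1e-10)
})

test_that("entropy bias shrinks as the ensemble grows", {
  pc <- phys_constants(); kT <- pc$kB * 300
  m <- 12; k <- 1000
  a <- pc$hbar * sqrt(k / m) / kT
  S_true <- pc$kB * (a / expm1(a) - log1p(-exp(-a)))
  err_at <- function(n, seed) {
    sp <- gaussian_ensemble_spec(1, m, c(kT / k, 0, 0), n, seed = seed)
    ce <- sample_gaussian_ensemble(sp)
    abs(quantum_qh_entropy(
      covariance_spectrum(mass_weighted_covariance(ce)), 300) - S_true)
  }
  errs <- vapply(c(500, 2000, 8000), function(n)
    mean(vapply(1:6, function(s) err_at(n, 60 + s), 0)), 0)
  expect_true(all(diff(errs) < 0))
})
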