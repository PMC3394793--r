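## ---- containers ------------------------------------------------------------

#' Free-energy curve along the control parameter
#'
#' @param lam_grid Control-parameter grid (nm), increasing from lambda_a.
#' @param delta_F Free-energy differences (kJ/mol), anchored so
#'   `delta_F[1] = 0` at lambda_a.
#' @param estimator One of `"jarzynski_F"`, `"jarzynski_R"`, `"minh_adib"`,
#'   `"chelli_procacci"`.
#' @param beta Inverse temperature (mol/kJ).
#' @param n_F,n_R Realization counts that produced the curve.
#' @return Object of class `free_energy_curve`.
#' @export
free_energy_curve <- function(lam_grid, delta_F, estimator, beta,
                              n_F = NA_integer_, n_R = NA_integer_) {
  stopifnot(length(lam_grid) == length(delta_F))
  if (is.finite(delta_F[1]) && abs(delta_F[1]) > 1e-8)
    stop("delta_F must be anchored to 0 at lambda_a")
  structure(list(lam_grid = lam_grid, delta_F = delta_F,
                 estimator = estimator, beta = beta, n_F = n_F, n_R = n_R),
            class = "free_energy_curve")
}

#' @export
print.free_energy_curve <- function(x, ...) {
  cat(sprintf(
    "free_energy_curve [%s]: %d points, lambda %.3f..%.3f nm, dF(end) = %.3f kJ/mol\n",
    x$estimator, length(x$lam_grid), min(x$lam_grid), max(x$lam_grid),
    x$delta_F[length(x$delta_F)]))
  invisible(x)
}

#' Binned potential of mean force G(xi)
#'
#' @param xi_bins Bin centers (nm); bins are half-open `[lo, hi)`.
#' @param G Free energy per bin (kJ/mol); `NA` marks bins with no samples.
#' @param estimator `"hs_forward"`, `"hs_reverse"`, `"ma_bidirectional"` or
#'   `"cp_bidirectional"`.
#' @param beta Inverse temperature (mol/kJ).
#' @param bin_width Bin width (nm).
#' @param n_F,n_R Realization counts.
#' @param n_samples Integer samples per bin (optional).
#' @return Object of class `pmf_profile`.
#' @export
pmf_profile <- function(xi_bins, G, estimator, beta, bin_width,
                        n_F = NA_integer_, n_R = NA_integer_,
                        n_samples = NULL) {
  stopifnot(length(xi_bins) == length(G))
  structure(list(xi_bins = xi_bins, G = G, estimator = estimator,
                 beta = beta, bin_width = bin_width, n_F = n_F, n_R = n_R,
                 n_samples = n_samples %||% rep(NA_integer_, length(G))),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  occ <- sum(is.finite(x$G))
  cat(sprintf(
    "pmf_profile [%s]: %d bins (%d occupied), width %.4g nm, range G = [%.2f, %.2f] kJ/mol\n",
    x$estimator, length(x$G), occ, x$bin_width,
    min(x$G, na.rm = TRUE), max(x$G, na.rm = TRUE)))
  invisible(x)
}

## internal: accept an ensemble or an already-resampled grid
as_grid_works <- function(x, n_grid = NULL) {
  if (inherits(x, "lambda_grid_works")) return(x)
  if (inherits(x, "trajectory_ensemble"))
    return(resample_on_lambda_grid(x, n_grid))
  stop("expected a trajectory_ensemble or lambda_grid_works object")
}

## ---- unidirectional estimators --------------------------------------------

## internal: raw (unanchored) Jarzynski log average per grid column
## returns -beta * dF_raw(g) = log <exp(-beta W(g))>
jarz_lograw <- function(W, beta) {
  apply(W, 2, function(w) logmeanexp(-beta * w))
}

#' Jarzynski free-energy curve from one pulling direction
#'
#' Computes the exponential-average free-energy estimate
#' `dF(lambda) = -(1/beta) log < exp(-beta W(lambda)) >` over the realizations
#' of one direction, with log-sum-exp stabilization, anchored to 0 at
#' lambda_a.  For the reverse direction the works accumulated from the
#' lambda_b end are used and the resulting curve is re-anchored at lambda_a,
#' so curves from both directions live on the same reference.
#'
#' @param x A [trajectory_ensemble()] or [resample_on_lambda_grid()] result.
#' @param direction `"forward"` or `"reverse"`.
#' @param n_grid Optional grid size when `x` is an ensemble.
#' @return A [free_energy_curve()].
#' @export
jarzynski_curve <- function(x, direction = c("forward", "reverse"),
                            n_grid = NULL) {
  direction <- match.arg(direction)
  gw <- as_grid_works(x, n_grid)
  W <- if (direction == "forward") gw$W_F else gw$W_R
  if (nrow(W) < 1L) stop("no realizations in the requested direction")
  lr <- jarz_lograw(W, gw$beta)
  dF <- -lr / gw$beta
  free_energy_curve(gw$lambda, dF - dF[1],
                    if (direction == "forward") "jarzynski_F" else
                      "jarzynski_R",
                    gw$beta, gw$n_F, gw$n_R)
}

## ---- BAR -------------------------------------------------------------------

## internal: log of the two sides of the Bennett equation
## LHS(dF) = sum_i [1 + (nF/nR) exp(beta (WF_i - dF))]^-1   (increasing in dF)
## RHS(dF) = sum_j [1 + (nR/nF) exp(beta (WR_j + dF))]^-1   (decreasing in dF)
bar_logsides <- function(dF, W_F, W_R, beta) {
  nF <- length(W_F); nR <- length(W_R)
  M <- log(nF / nR)
  lhs <- logsumexp(stats::plogis(-(M + beta * (W_F - dF)), log.p = TRUE))
  rhs <- logsumexp(stats::plogis(-(-M + beta * (W_R + dF)), log.p = TRUE))
  c(lhs = lhs, rhs = rhs)
}

#' Bennett acceptance ratio estimate of the end-state free-energy difference
#'
#' Solves the Bennett equation
#' `sum_i [1 + (nF/nR) e^{beta(W_F,i - dF)}]^-1 =
#'  sum_j [1 + (nR/nF) e^{beta(W_R,j + dF)}]^-1`
#' self-consistently for dF, starting from 0, by a damped fixed-point
#' iteration with bisection fallback on the monotone residual.  `W_R` is the
#' work performed on the system during the b -> a realizations, as simulated.
#'
#' @param W_F_end Total forward works W_F(tau) (kJ/mol), length n_F >= 1.
#' @param W_R_end Total reverse works W_R(tau) (kJ/mol), length n_R >= 1.
#' @param beta Inverse temperature (mol/kJ).
#' @param tol Convergence tolerance on dF (kJ/mol), default 1e-8.
#' @param max_iter Maximum iterations, default 1000.
#' @return Object of class `bar_solution`: list with `delta_F` (kJ/mol),
#'   `iterations`, `residual` (log LHS - log RHS at the solution), and
#'   `converged`.
#' @examples
#' b <- beta_of(300)
#' bar_delta_f(5, -5, b)$delta_F   # symmetric single samples: dF = 5
#' @export
bar_delta_f <- function(W_F_end, W_R_end, beta, tol = 1e-8,
                        max_iter = 1000L) {
  if (length(W_F_end) < 1L || length(W_R_end) < 1L)
    stop("BAR needs at least one realization in each direction; ",
         "use jarzynski_curve() for unidirectional data")
  resid <- function(dF) {
    s <- bar_logsides(dF, W_F_end, W_R_end, beta)
    s[["lhs"]] - s[["rhs"]]
  }
  ## bracket the root of the increasing residual
  lo <- min(-W_R_end, W_F_end) - 50 / beta
  hi <- max(-W_R_end, W_F_end) + 50 / beta
  dF <- 0
  dF <- min(max(dF, lo), hi)
  iter <- 0L
  converged <- FALSE
  step_scale <- 1
  r <- resid(dF)
  while (iter < max_iter) {
    iter <- iter + 1L
    if (abs(r) < 1e-12) {
      converged <- TRUE
      break
    }
    if (r > 0) hi <- min(hi, dF) else lo <- max(lo, dF)
    step <- -r / beta * step_scale       # fixed-point move, damped
    cand <- dF + step
    if (!is.finite(cand) || cand <= lo || cand >= hi)
      cand <- (lo + hi) / 2              # bisection fallback
    r_new <- resid(cand)
    if (abs(r_new) > abs(r)) {
      step_scale <- step_scale / 2
      cand <- (lo + hi) / 2
      r_new <- resid(cand)
    }
    delta <- abs(cand - dF)
    dF <- cand
    r <- r_new
    if (delta < tol && abs(r) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  structure(list(delta_F = dF, iterations = iter, residual = unname(r),
                 converged = converged),
            class = "bar_solution")
}

#' @export
print.bar_solution <- function(x, ...) {
  cat(sprintf("bar_solution: dF = %.6f kJ/mol (%s, %d iterations, residual %.2e)\n",
              x$delta_F, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  invisible(x)
}

## ---- bidirectional lambda-curves ------------------------------------------

## internal: log Bennett trajectory weights for the bidirectional estimator
## forward i: -log(nF + nR exp(beta (dF - WF_i(tau))))
## reverse j: -log(nF + nR exp(beta (dF + WR_j(tau))))
## and the forward-image partial works of the reverse pulls,
## hatW[j, g] = WR[j, g] - WR[j, 1].
ma_ingredients <- function(gw, bar) {
  G <- length(gw$lambda)
  WFtau <- gw$W_F[, G]
  WRtau <- gw$W_R[, 1]
  dF <- bar$delta_F
  lw_F <- -vapply(WFtau, function(w)
    logsumexp(c(log(gw$n_F), log(gw$n_R) + gw$beta * (dF - w))), 0)
  lw_R <- -vapply(WRtau, function(w)
    logsumexp(c(log(gw$n_F), log(gw$n_R) + gw$beta * (dF + w))), 0)
  hatW <- gw$W_R - gw$W_R[, 1]
  list(lw_F = lw_F, lw_R = lw_R, hatW = hatW)
}

#' Bidirectional free-energy curve (Minh-Adib estimator)
#'
#' Combines the partial works of forward pulls with the time-reversed images
#' of reverse pulls under Bennett weights fixed by the end-state BAR solution:
#' `exp(-beta dF(lambda)) = sum_i exp(-beta W_F,i(lambda)) /
#' (nF + nR exp(beta(dF - W_F,i(tau)))) + sum_j exp(-beta hatW_j(lambda)) /
#' (nF + nR exp(beta(dF + W_R,j(tau))))`, where `hatW_j` is the forward-image
#' work of reverse pull j.  At the end states the curve reproduces the BAR
#' free-energy difference exactly.
#'
#' @inheritParams jarzynski_curve
#' @param bar Optional [bar_delta_f()] solution on the same end-state works;
#'   solved internally when omitted.
#' @return A [free_energy_curve()] (estimator `"minh_adib"`) with the BAR
#'   solution attached as attribute `"bar"`.
#' @export
ma_curve <- function(x, bar = NULL, n_grid = NULL) {
  gw <- as_grid_works(x, n_grid)
  if (gw$n_F < 1L || gw$n_R < 1L)
    stop("bidirectional estimator needs both directions")
  G <- length(gw$lambda)
  if (is.null(bar))
    bar <- bar_delta_f(gw$W_F[, G], gw$W_R[, 1], gw$beta)
  ing <- ma_ingredients(gw, bar)
  logZ <- vapply(seq_len(G), function(g) {
    logsumexp(c(-gw$beta * gw$W_F[, g] + ing$lw_F,
                -gw$beta * ing$hatW[, g] + ing$lw_R))
  }, 0)
  dF <- -logZ / gw$beta
  out <- free_energy_curve(gw$lambda, dF - dF[1], "minh_adib", gw$beta,
                           gw$n_F, gw$n_R)
  attr(out, "bar") <- bar
  out
}

#' Bidirectional free-energy curve (Chelli-Procacci style estimator)
#'
#' Evaluates the two unidirectional Jarzynski estimates (forward works from
#' lambda_a, reverse works from lambda_b re-referenced through the end-state
#' BAR solution) and combines them with sample-size weights in the
#' exponential domain:
#' `exp(-beta dF(lambda)) = [nF <e^{-beta W_F(lambda)}>_F +
#'  nR e^{-beta dF_BAR} <e^{-beta W_R(lambda)}>_R] / (nF + nR)`.
#' In the quasi-reversible regime the two channels coincide and the curve
#' reduces to the Jarzynski equality; in strongly dissipative pulls the
#' exponential weighting hands every lambda to the direction that reaches it
#' with less dissipation, and after anchoring the curve tracks the Minh-Adib
#' estimator, reproducing the BAR difference at the end states.
#'
#' @inheritParams ma_curve
#' @return A [free_energy_curve()] (estimator `"chelli_procacci"`).
#' @export
cp_curve <- function(x, bar = NULL, n_grid = NULL) {
  gw <- as_grid_works(x, n_grid)
  if (gw$n_F < 1L || gw$n_R < 1L)
    stop("bidirectional estimator needs both directions")
  G <- length(gw$lambda)
  if (is.null(bar))
    bar <- bar_delta_f(gw$W_F[, G], gw$W_R[, 1], gw$beta)
  lrF <- jarz_lograw(gw$W_F, gw$beta)    # log <e^{-beta W_F(g)}>
  lrR <- jarz_lograw(gw$W_R, gw$beta)    # log <e^{-beta W_R(g)}>
  logZ <- vapply(seq_len(G), function(g) {
    logsumexp(c(log(gw$n_F) + lrF[g],
                log(gw$n_R) - gw$beta * bar$delta_F + lrR[g]))
  }, 0) - log(gw$n_F + gw$n_R)
  dF <- -logZ / gw$beta
  free_energy_curve(gw$lambda, dF - dF[1], "chelli_procacci", gw$beta,
                    gw$n_F, gw$n_R)
}

## ---- PMF reconstruction ----------------------------------------------------

#' Uniform half-open bins over the sampled coordinate range
#'
#' @param xi_range Length-2 numeric range (nm).
#' @param width Bin width (nm), default 0.025.
#' @return List with `breaks`, `centers`, `width`.
#' @export
make_xi_bins <- function(xi_range, width = 0.025) {
  stopifnot(length(xi_range) == 2L, width > 0)
  ## small epsilon guards against representation error at the edges
  lo <- floor(xi_range[1] / width + 1e-9) * width
  nb <- max(1L, floor((xi_range[2] - lo) / width + 1e-9) + 1L)
  breaks <- lo + width * (0:nb)
  list(breaks = breaks, centers = breaks[-1] - width / 2, width = width)
}

## internal: bin index with half-open [lo, hi) convention; NA outside
bin_index <- function(x, bins) {
  i <- floor((x - bins$breaks[1]) / bins$width + 1e-9) + 1L
  i[i < 1L | i > length(bins$centers)] <- NA_integer_
  as.integer(i)
}

## internal: shared WHAM-type unbiasing step.
## Given per-point log weights lw (matrix n x G, already including the
## per-slice normalization e^{+beta dF(lambda_g)}), positions Xi (n x G),
## plus per-slice log normalizers lnorm(g) = beta dF(lambda_g), returns log
## numerator per bin and log denominator per bin.
hs_bin_sums <- function(Xi, lw, lnorm, lambda, kappa, beta, bins) {
  bi <- bin_index(as.numeric(Xi), bins)
  lwv <- as.numeric(lw)
  keep <- !is.na(bi) & is.finite(lwv)
  nb <- length(bins$centers)
  lognum <- rep(-Inf, nb)
  cnt <- integer(nb)
  if (any(keep)) {
    sp <- split(lwv[keep], bi[keep])
    idx <- as.integer(names(sp))
    lognum[idx] <- vapply(sp, logsumexp, 0)
    tb <- table(bi[keep])
    cnt[as.integer(names(tb))] <- as.integer(tb)
  }
  ## denominator: sum over slices of exp(-beta u(xi_b, lambda_g) + lnorm_g)
  logden <- vapply(bins$centers, function(xb) {
    logsumexp(-beta * spring_energy(xb, lambda, kappa) + lnorm)
  }, 0)
  list(lognum = lognum, logden = logden, count = cnt)
}

## internal: anchor a PMF at its first occupied bin (G = 0 there)
anchor_pmf <- function(G) {
  occ <- which(is.finite(G))
  if (length(occ) == 0L) stop("all bins are empty")
  G - G[occ[1]]
}

#' Hummer-Szabo potential of mean force from one pulling direction
#'
#' Unbiases the spring-biased, time-sliced samples into the unperturbed
#' G(xi) by the weighted-histogram prescription:
#' `exp(-beta G(xi)) = [sum_t <delta(xi - xi_t) e^{-beta W_t}> /
#' <e^{-beta W_t}>] / [sum_t e^{-beta u(xi, lambda_t)} / <e^{-beta W_t}>]`,
#' with `u` the harmonic guide and `<e^{-beta W_t}>` the Jarzynski estimate
#' at each slice.  Bins never visited are reported as `NA`, not zero; the
#' profile is anchored to 0 at the lowest-xi occupied bin.
#'
#' @param x A [trajectory_ensemble()] or [resample_on_lambda_grid()] result.
#' @param direction `"forward"` or `"reverse"`.
#' @param bins Optional [make_xi_bins()] result; default 0.025 nm bins over
#'   the sampled xi range of the chosen direction.
#' @param bin_width Bin width used when `bins` is NULL.
#' @param n_grid Optional grid size when `x` is an ensemble.
#' @return A [pmf_profile()].
#' @export
hs_pmf <- function(x, direction = c("forward", "reverse"), bins = NULL,
                   bin_width = 0.025, n_grid = NULL) {
  direction <- match.arg(direction)
  gw <- as_grid_works(x, n_grid)
  W <- if (direction == "forward") gw$W_F else gw$W_R
  Xi <- if (direction == "forward") gw$Xi_F else gw$Xi_R
  if (nrow(W) < 1L) stop("no realizations in the requested direction")
  if (is.null(bins)) bins <- make_xi_bins(range(Xi), bin_width)
  if (min(Xi) < bins$breaks[1] ||
      max(Xi) >= bins$breaks[length(bins$breaks)])
    warning("bin range does not cover all sampled xi; outside samples masked")
  lnorm <- -jarz_lograw(W, gw$beta)      # +beta dF_raw(lambda_g)
  n <- nrow(W)
  lw <- -gw$beta * W - log(n) + matrix(lnorm, n, length(lnorm), byrow = TRUE)
  hb <- hs_bin_sums(Xi, lw, lnorm, gw$lambda, gw$kappa, gw$beta, bins)
  G <- -(hb$lognum - hb$logden) / gw$beta
  G[!is.finite(G)] <- NA_real_
  pmf_profile(bins$centers, anchor_pmf(G),
              if (direction == "forward") "hs_forward" else "hs_reverse",
              gw$beta, bins$width, gw$n_F, gw$n_R, hb$count)
}

#' Bidirectional potential of mean force
#'
#' `method = "ma"` extends the Hummer-Szabo unbiasing with the Minh-Adib
#' bidirectional path-ensemble average: samples from both directions enter
#' each time slice with Bennett weights fixed by the end-state BAR solution,
#' and the per-slice normalization comes from the bidirectional
#' free-energy curve ([ma_curve()]).  `method = "cp"` combines the two
#' unidirectional Hummer-Szabo profiles by the same sample-size weighted
#' exponential average as [cp_curve()], aligning the reverse profile with the
#' end-state free-energy difference.
#'
#' @inheritParams hs_pmf
#' @param method `"ma"` or `"cp"`.
#' @return A [pmf_profile()] (estimator `"ma_bidirectional"` or
#'   `"cp_bidirectional"`).
#' @export
bidirectional_pmf <- function(x, method = c("ma", "cp"), bins = NULL,
                              bin_width = 0.025, n_grid = NULL) {
  method <- match.arg(method)
  gw <- as_grid_works(x, n_grid)
  if (gw$n_F < 1L || gw$n_R < 1L)
    stop("bidirectional estimator needs both directions")
  if (is.null(bins))
    bins <- make_xi_bins(range(c(gw$Xi_F, gw$Xi_R)), bin_width)
  G <- length(gw$lambda)
  if (method == "ma") {
    mac <- ma_curve(gw)
    bar <- attr(mac, "bar")
    ing <- ma_ingredients(gw, bar)
    lnorm <- gw$beta * mac$delta_F       # +beta dF_MA(lambda_g)
    lw_F <- -gw$beta * gw$W_F + ing$lw_F +
      matrix(lnorm, gw$n_F, G, byrow = TRUE)
    lw_R <- -gw$beta * ing$hatW + ing$lw_R +
      matrix(lnorm, gw$n_R, G, byrow = TRUE)
    hb <- hs_bin_sums(rbind(gw$Xi_F, gw$Xi_R), rbind(lw_F, lw_R), lnorm,
                      gw$lambda, gw$kappa, gw$beta, bins)
    Gp <- -(hb$lognum - hb$logden) / gw$beta
    Gp[!is.finite(Gp)] <- NA_real_
    out <- pmf_profile(bins$centers, anchor_pmf(Gp), "ma_bidirectional",
                       gw$beta, bins$width, gw$n_F, gw$n_R, hb$count)
    attr(out, "bar") <- bar
    return(out)
  }
  ## method "cp": combine unanchored unidirectional HS profiles
  hs_raw <- function(direction) {
    W <- if (direction == "forward") gw$W_F else gw$W_R
    Xi <- if (direction == "forward") gw$Xi_F else gw$Xi_R
    lnorm <- -jarz_lograw(W, gw$beta)
    n <- nrow(W)
    lw <- -gw$beta * W - log(n) +
      matrix(lnorm, n, length(lnorm), byrow = TRUE)
    hs_bin_sums(Xi, lw, lnorm, gw$lambda, gw$kappa, gw$beta, bins)
  }
  hf <- hs_raw("forward"); hr <- hs_raw("reverse")
  logGF <- hf$lognum - hf$logden         # = -beta G_F(xi), lambda_a reference
  logGR <- hr$lognum - hr$logden         # lambda_b reference
  dF_end <- cp_curve(gw)$delta_F[G]      # aligns the reverse reference
  comb <- vapply(seq_along(logGF), function(b) {
    logsumexp(c(log(gw$n_F) + logGF[b],
                log(gw$n_R) + logGR[b] - gw$beta * dF_end)) -
      log(gw$n_F + gw$n_R)
  }, 0)
  Gp <- -comb / gw$beta
  Gp[!is.finite(Gp)] <- NA_real_
  pmf_profile(bins$centers, anchor_pmf(Gp), "cp_bidirectional", gw$beta,
              bins$width, gw$n_F, gw$n_R, hf$count + hr$count)
}

## ---- basin / barrier analysis ---------------------------------------------

#' Locate basins and barriers in a PMF profile
#'
#' Finds alternating interior minima (basins) and maxima (barriers) of the
#' profile, collapsing plateaus to their midpoint bin, then prunes
#' basin/barrier pairs whose amplitude is below `min_prominence`.  Barrier
#' heights are reported in kcal/mol as basin-to-adjacent-barrier differences:
#' the unbinding direction reads left-to-right (climb from the lower-xi
#' basin), the binding direction right-to-left.
#'
#' @param profile A [pmf_profile()] with at least 3 unmasked bins.
#' @param min_prominence Minimum basin-barrier amplitude to keep (kJ/mol).
#' @return Object of class `basin_barrier_report`: `extrema` (data frame with
#'   xi, G_kJ_mol, kind, label) and `barrier_heights` (data frame with
#'   from_basin, over_barrier, direction, dG_kcal_mol).
#' @export
locate_basins_barriers <- function(profile, min_prominence = 1.0) {
  stopifnot(inherits(profile, "pmf_profile"))
  ok <- is.finite(profile$G)
  if (sum(ok) < 3L) stop("profile needs at least 3 unmasked bins")
  xi <- profile$xi_bins[ok]
  g <- profile$G[ok]
  ## collapse exact plateaus to their midpoint bin
  r <- rle(g)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mid <- floor((starts + ends) / 2)
  gv <- r$values
  n <- length(gv)
  ext_idx <- integer(0)
  ext_kind <- character(0)
  if (n >= 3L) {
    for (k in 2:(n - 1)) {
      if (gv[k] < gv[k - 1] && gv[k] < gv[k + 1]) {
        ext_idx <- c(ext_idx, k); ext_kind <- c(ext_kind, "basin")
      } else if (gv[k] > gv[k - 1] && gv[k] > gv[k + 1]) {
        ext_idx <- c(ext_idx, k); ext_kind <- c(ext_kind, "barrier")
      }
    }
  }
  ## prune low-prominence basin/barrier pairs, smallest amplitude first
  repeat {
    if (length(ext_idx) < 2L) break
    amp <- abs(diff(gv[ext_idx]))
    k <- which.min(amp)
    if (amp[k] >= min_prominence) break
    ext_idx <- ext_idx[-c(k, k + 1L)]
    ext_kind <- ext_kind[-c(k, k + 1L)]
  }
  if (length(ext_idx) == 1L && abs(gv[ext_idx]) < Inf) {
    ## single extremum always kept (prominence vs boundary values)
    bnd <- min(abs(gv[ext_idx] - gv[1]), abs(gv[ext_idx] - gv[n]))
    if (bnd < min_prominence) {
      ext_idx <- integer(0); ext_kind <- character(0)
    }
  }
  extrema <- data.frame(
    xi = xi[mid[ext_idx]], G_kJ_mol = gv[ext_idx], kind = ext_kind,
    label = seq_along(ext_idx), stringsAsFactors = FALSE)
  heights <- data.frame(from_basin = integer(0), over_barrier = integer(0),
                        direction = character(0), dG_kcal_mol = numeric(0),
                        stringsAsFactors = FALSE)
  if (nrow(extrema) >= 2L) {
    for (k in which(extrema$kind == "barrier")) {
      if (k > 1L && extrema$kind[k - 1] == "basin")
        heights <- rbind(heights, data.frame(
          from_basin = extrema$label[k - 1], over_barrier = extrema$label[k],
          direction = "unbinding",
          dG_kcal_mol = kj_to_kcal(extrema$G_kJ_mol[k] -
                                     extrema$G_kJ_mol[k - 1])))
      if (k < nrow(extrema) && extrema$kind[k + 1] == "basin")
        heights <- rbind(heights, data.frame(
          from_basin = extrema$label[k + 1], over_barrier = extrema$label[k],
          direction = "binding",
          dG_kcal_mol = kj_to_kcal(extrema$G_kJ_mol[k] -
                                     extrema$G_kJ_mol[k + 1])))
    }
  }
  structure(list(extrema = extrema, barrier_heights = heights),
            class = "basin_barrier_report")
}

#' @export
print.basin_barrier_report <- function(x, ...) {
  cat("basin_barrier_report:\n")
  if (nrow(x$extrema) == 0) {
    cat("  no interior extrema\n")
  } else {
    print(x$extrema, row.names = FALSE)
    if (nrow(x$barrier_heights)) {
      cat("barrier heights (kcal/mol):\n")
      print(x$barrier_heights, row.names = FALSE)
    }
  }
  invisible(x)
}
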