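#' Analytic 1-D free-energy profiles for the synthetic simulator
#'
#' Three families of unperturbed profiles G_true(xi) with evaluable value and
#' gradient everywhere on their domain:
#' \describe{
#'   \item{harmonic}{`a/2 (xi - x0)^2`; params `a` (kJ/mol/nm^2), `x0` (nm).}
#'   \item{double_well}{`h (((xi - x0)/c)^2 - 1)^2`; minima at `x0 +/- c`,
#'     barrier `h` at `x0`.}
#'   \item{gorge_profile}{`slope * xi + sum_k A_k exp(-(xi-mu_k)^2/(2 s_k^2))`;
#'     a rugged translocation profile with multiple basins and barriers
#'     (bound basin, intermediate bump, main bottleneck barrier, exterior
#'     capture basin).}
#' }
#'
#' @param kind One of `"harmonic"`, `"double_well"`, `"gorge_profile"`.
#' @param params Named list of coefficients (see Details).
#' @param domain Length-2 numeric, the xi interval of interest (nm).
#' @return Object of class `analytic_potential`.
#' @examples
#' pot <- gorge_potential()
#' curve(potential_energy(pot, x), 0, 2.5, xlab = "xi (nm)",
#'       ylab = "G_true (kJ/mol)")
#' @export
analytic_potential <- function(kind = c("harmonic", "double_well",
                                        "gorge_profile"),
                               params, domain) {
  kind <- match.arg(kind)
  stopifnot(is.list(params), length(domain) == 2L, domain[1] < domain[2])
  need <- switch(kind,
                 harmonic = c("a", "x0"),
                 double_well = c("h", "c", "x0"),
                 gorge_profile = c("slope", "gaussians"))
  if (!all(need %in% names(params)))
    stop("params must contain: ", paste(need, collapse = ", "))
  if (kind == "harmonic" && params$a < 0) stop("a must be >= 0")
  if (kind == "gorge_profile") {
    g <- params$gaussians
    if (!is.matrix(g) || ncol(g) != 3L)
      stop("gaussians must be a matrix with columns (A, mu, sigma)")
    if (any(g[, 3] <= 0)) stop("gaussian widths must be > 0")
  }
  structure(list(kind = kind, params = params, domain = as.numeric(domain)),
            class = "analytic_potential")
}

#' Convenience constructors for the built-in potentials
#'
#' `gorge_potential()` is the default rugged translocation profile used by the
#' package's validation studies: a linear ramp plus four Gaussians giving a
#' deep bound basin near 0.25 nm, an intermediate bump near 1 nm, the main
#' bottleneck barrier near 2 nm and a shallow exterior capture basin near
#' 2.3 nm, over the 0--2.5 nm pulling range.
#'
#' @param a,x0 Harmonic stiffness (kJ/mol/nm^2) and minimum (nm).
#' @param h,c Double-well barrier height (kJ/mol) and half-separation (nm).
#' @param slope Linear ramp (kJ/mol/nm).
#' @param gaussians Matrix with columns (A, mu, sigma): amplitude (kJ/mol),
#'   center (nm), width (nm).
#' @param domain xi interval (nm).
#' @return An [analytic_potential()].
#' @export
harmonic_potential <- function(a = 400, x0 = 0, domain = c(x0 - 1, x0 + 3)) {
  analytic_potential("harmonic", list(a = a, x0 = x0), domain)
}

#' @rdname harmonic_potential
#' @export
double_well_potential <- function(h = 12, c = 0.5, x0 = 0,
                                  domain = c(x0 - 2 * c, x0 + 2 * c)) {
  analytic_potential("double_well", list(h = h, c = c, x0 = x0), domain)
}

#' @rdname harmonic_potential
#' @export
gorge_potential <- function(slope = 8,
                            gaussians = rbind(c(-25, 0.25, 0.25),
                                              c(  6, 1.00, 0.15),
                                              c( 15, 2.00, 0.15),
                                              c(-10, 2.30, 0.12)),
                            domain = c(0, 2.5)) {
  analytic_potential("gorge_profile",
                     list(slope = slope, gaussians = gaussians), domain)
}

#' Evaluate an analytic potential or its gradient
#'
#' @param potential An [analytic_potential()].
#' @param x Positions (nm).
#' @return `potential_energy`: G_true(x) in kJ/mol.
#'   `potential_grad`: dG_true/dx in kJ/mol/nm.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "analytic_potential"))
  p <- potential$params
  switch(potential$kind,
         harmonic = 0.5 * p$a * (x - p$x0)^2,
         double_well = p$h * (((x - p$x0) / p$c)^2 - 1)^2,
         gorge_profile = {
           v <- p$slope * x
           for (k in seq_len(nrow(p$gaussians))) {
             g <- p$gaussians[k, ]
             v <- v + g[1] * exp(-0.5 * ((x - g[2]) / g[3])^2)
           }
           v
         })
}

#' @rdname potential_energy
#' @export
potential_grad <- function(potential, x) {
  stopifnot(inherits(potential, "analytic_potential"))
  p <- potential$params
  switch(potential$kind,
         harmonic = p$a * (x - p$x0),
         double_well = {
           u <- (x - p$x0) / p$c
           4 * p$h * u * (u^2 - 1) / p$c
         },
         gorge_profile = {
           v <- rep(p$slope, length(x))
           for (k in seq_len(nrow(p$gaussians))) {
             g <- p$gaussians[k, ]
             z <- (x - g[2]) / g[3]
             v <- v - g[1] * z / g[3] * exp(-0.5 * z^2)
           }
           v
         })
}

## internal: encode potential for the C++ integrator
potential_code <- function(potential) {
  p <- potential$params
  switch(potential$kind,
         harmonic = list(kind = 0L, params = c(p$a, p$x0)),
         double_well = list(kind = 1L, params = c(p$h, p$c, p$x0)),
         gorge_profile = list(kind = 2L,
                              params = c(p$slope, as.numeric(t(p$gaussians)))))
}

## internal: crude bound on max |G''| over the domain (stability check)
max_curvature <- function(potential) {
  xs <- seq(potential$domain[1], potential$domain[2], length.out = 2001)
  g <- potential_grad(potential, xs)
  max(abs(diff(g) / diff(xs)))
}
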