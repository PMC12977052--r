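#' Gas constant in kJ/(mol K)
#' @export
GAS_CONSTANT_KJ <- 8.31446e-3

#' Softmax weights from Rosetta-style scores
#'
#' Converts per-model scores (lower = better) into normalised model weights
#' \eqn{w_m \propto \exp(-(s_m - \min s)/\tau)}. The softening scale
#' \eqn{\tau} controls how sharply good scores dominate: \code{tau = Inf}
#' gives uniform weights (unweighted KDE); the default is the sample
#' standard deviation of the scores, which is scale-free after the min
#' shift and degrades gracefully to uniform when all scores coincide.
#'
#' @param scores numeric vector of per-model scores.
#' @param tau positive softening scale, or \code{Inf} for uniform weights;
#'   default \code{sd(scores)}.
#' @return weights summing to 1, one per score.
#' @export
score_weights <- function(scores, tau = NULL) {
  if (length(scores) < 1) stop("need at least one score")
  if (!all(is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (is.null(tau)) tau <- stats::sd(scores)
  if (is.null(tau) || is.na(tau) || tau == 0) tau <- Inf
  if (tau < 0) stop("tau must be positive (or Inf)")
  if (!is.finite(tau)) return(rep(1 / n, n))
  w <- exp(-(scores - min(scores)) / tau)
  w / sum(w)
}

#' Ensemble-size-adaptive kernel bandwidth
#'
#' Scales a base bandwidth by the Silverman rate \eqn{(n_{ref}/n)^{1/5}} so
#' that small ensembles (e.g. 100 models instead of 10,000) get a
#' proportionally wider kernel, then clamps to \code{[h_min, h_max]}.
#'
#' @param n number of models in the ensemble.
#' @param base_bandwidth kernel width (degrees) at the reference size.
#' @param n_ref reference ensemble size (default 10000).
#' @param h_min,h_max clamp bounds in degrees.
#' @return bandwidth in degrees.
#' @export
kde_bandwidth <- function(n, base_bandwidth = 5, n_ref = 10000,
                          h_min = 2, h_max = 30) {
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be >= 1")
  if (base_bandwidth <= 0) stop("base_bandwidth must be positive")
  h <- base_bandwidth * (n_ref / n)^(1 / 5)
  min(max(h, h_min), h_max)
}

# internal: wrapped Gaussian kernel (density per degree) and its derivative,
# summed over +/- n_images periodic images. x in degrees, h in degrees.
.wrapped_gauss <- function(x, h, n_images = 2) {
  out <- 0
  for (k in -n_images:n_images) {
    xi <- x + 360 * k
    out <- out + exp(-0.5 * (xi / h)^2)
  }
  out / (h * sqrt(2 * pi))
}

.wrapped_gauss_deriv <- function(x, h, n_images = 2) {
  out <- 0
  for (k in -n_images:n_images) {
    xi <- x + 360 * k
    out <- out - (xi / h^2) * exp(-0.5 * (xi / h)^2)
  }
  out / (h * sqrt(2 * pi))
}

#' Score-weighted circular kernel density of a torsion sample
#'
#' Estimates the periodic probability density of one torsion angle from its
#' per-model observations and weights, using a wrapped Gaussian kernel. The
#' raw KDE is mixed with a small uniform floor (fraction \code{floor_mix} of
#' the mass) so the subsequent Boltzmann inversion stays finite in regions
#' the ensemble never visits, then renormalised on the grid.
#'
#' @param sample a \code{\link{torsion_sample}} (angles in degrees, weights
#'   normalised).
#' @param bandwidth kernel width in degrees (> 0).
#' @param grid_step grid spacing in degrees; the grid runs -180..+180
#'   inclusive (duplicated periodic endpoint, table-file convention).
#' @param floor_mix uniform mixing fraction epsilon (default 1e-6).
#' @return object of class \code{weighted_density} with fields \code{grid}
#'   (degrees), \code{density} (per degree), \code{bandwidth},
#'   \code{n_effective} (inverse sum of squared weights), plus the kernel
#'   ingredients needed for analytic derivatives.
#' @export
weighted_circular_density <- function(sample, bandwidth,
                                      grid_step = 1, floor_mix = 1e-6) {
  stopifnot(inherits(sample, "torsion_sample"))
  if (length(sample$angles) == 0) stop("empty torsion sample")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (grid_step <= 0 || 360 %% grid_step != 0)
    stop("grid_step must be positive and divide 360")
  grid <- seq(-180, 180, by = grid_step)
  diffs <- outer(grid, sample$angles, "-")
  raw <- as.numeric(.wrapped_gauss(diffs, bandwidth) %*% sample$weights)
  mixed <- (1 - floor_mix) * raw + floor_mix / 360
  # Riemann normalisation over one period (drop the duplicated endpoint)
  z <- sum(mixed[-length(mixed)]) * grid_step
  structure(list(grid = grid, density = mixed / z, bandwidth = bandwidth,
                 grid_step = grid_step, floor_mix = floor_mix, norm = z,
                 angles = sample$angles, weights = sample$weights,
                 n_effective = 1 / sum(sample$weights^2),
                 torsion_id = c(residue_index = sample$residue_index,
                                kind = sample$kind)),
            class = "weighted_density")
}

# internal: analytic d(density)/d(alpha) (per degree^2) on the stored grid
.density_deriv <- function(wd) {
  diffs <- outer(wd$grid, wd$angles, "-")
  raw_d <- as.numeric(.wrapped_gauss_deriv(diffs, wd$bandwidth) %*% wd$weights)
  (1 - wd$floor_mix) * raw_d / wd$norm
}

#' Boltzmann inversion of a torsion density into a potential
#'
#' Applies \eqn{PEF(\alpha) = -RT \ln P(\alpha)} with the gas constant
#' R = 8.31446e-3 kJ/(mol K). The potential is gauge-shifted so its minimum
#' is 0 (the shift, \code{pef_offset}, is retained; it does not affect
#' forces). The potential's argmin coincides with the density's argmax.
#'
#' @param density a \code{\link{weighted_circular_density}} result (strictly
#'   positive everywhere; the uniform floor guarantees this).
#' @param temperature absolute temperature in kelvin (default 310).
#' @return object of class \code{potential_table} with fields \code{grid},
#'   \code{pef} (kJ/mol, min 0), \code{force} (filled by
#'   \code{\link{potential_force}}), \code{pef_offset}, \code{temperature},
#'   \code{torsion_id}, and the source \code{density}.
#' @export
boltzmann_invert <- function(density, temperature = 310) {
  stopifnot(inherits(density, "weighted_density"))
  if (temperature <= 0) stop("temperature must be positive")
  if (any(density$density <= 0))
    stop("density must be strictly positive; regularize before inverting")
  rt <- GAS_CONSTANT_KJ * temperature
  pef_raw <- -rt * log(density$density)
  off <- min(pef_raw)
  structure(list(grid = density$grid, pef = pef_raw - off, force = NULL,
                 pef_offset = off, temperature = temperature, rt = rt,
                 torsion_id = density$torsion_id, density = density,
                 grid_step = density$grid_step),
            class = "potential_table")
}

#' Restraining force column of a potential table
#'
#' Fills \code{force = -dPEF/d\alpha} in kJ/mol/degree. When the potential
#' came from a kernel density the derivative is analytic (kernel derivatives
#' through the chain rule: \eqn{-dPEF/d\alpha = RT\, P'/P}); otherwise
#' periodic central differences on the uniform grid are used. Both routes
#' agree to second order in the grid step.
#'
#' @param table a \code{\link{potential_table}}.
#' @param method \code{"auto"} (analytic when possible), \code{"analytic"}
#'   or \code{"numeric"}.
#' @return the table with its \code{force} column filled.
#' @export
potential_force <- function(table, method = c("auto", "analytic", "numeric")) {
  stopifnot(inherits(table, "potential_table"))
  method <- match.arg(method)
  g <- table$grid
  step <- unique(round(diff(g), 12))
  if (length(step) != 1) stop("non-uniform grid")
  analytic_ok <- !is.null(table$density) &&
    inherits(table$density, "weighted_density")
  if (method == "analytic" && !analytic_ok)
    stop("no kernel density attached; analytic derivative unavailable")
  if (method != "numeric" && analytic_ok) {
    d <- table$density
    table$force <- table$rt * .density_deriv(d) / d$density
  } else {
    pef <- table$pef
    n <- length(pef)
    # points 1..n-1 are unique; point n duplicates point 1 (periodic endpoint)
    u <- pef[-n]
    m <- length(u)
    fwd <- u[c(2:m, 1)]
    bwd <- u[c(m, 1:(m - 1))]
    f <- -(fwd - bwd) / (2 * step)
    table$force <- c(f, f[1])
  }
  table
}

#' Quadratic curvature of a potential at its minimum
#'
#' Fits a quadratic to the PEF over a window centred on the grid minimum and
#' returns twice the quadratic coefficient, i.e. d2PEF/dalpha2 at the
#' minimum in kJ/mol/rad^2. For a torsion whose angles follow a von Mises
#' distribution with concentration kappa, this equals RT*kappa up to kernel
#' broadening.
#'
#' @param table a \code{potential_table}.
#' @param window_deg half-width of the fit window in degrees (default 20).
#' @return curvature in kJ/mol/rad^2.
#' @export
pef_curvature <- function(table, window_deg = 20) {
  stopifnot(inherits(table, "potential_table"))
  imin <- which.min(table$pef)
  d <- abs(wrap_angle(table$grid - table$grid[imin]))
  sel <- d <= window_deg
  th <- wrap_angle(table$grid[sel] - table$grid[imin]) * pi / 180
  fit <- stats::lm(table$pef[sel] ~ th + I(th^2))
  2 * unname(stats::coef(fit)[3])
}

#' @export
print.potential_table <- function(x, ...) {
  cat(sprintf("potential_table (%s %s): %d grid points, T = %g K, barrier %.3f kJ/mol\n",
              x$torsion_id["kind"], x$torsion_id["residue_index"],
              length(x$grid), x$temperature, max(x$pef)))
  invisible(x)
}
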