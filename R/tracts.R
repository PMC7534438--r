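#' Along-genome ancestry switch rate at distance r from the selected site
#'
#' Moving along the chromosome away from the selected locus, the local
#' ancestry forms an (approximately Markov) two-state process. The rate
#' at which donor ancestry (type 1) switches to recipient ancestry
#' (type 0) at distance `r` is obtained from the six-state solution with
#' `r1 = r` and an infinitesimal probe distance `r2`: it is the
#' probability of the state in which the beta-lineage carries the
#' selected allele while the gamma-lineage does not, divided by the
#' marginal probability of donor ancestry at `r` (the first three
#' states) and by the probe width.
#'
#' @param r distance from the selected locus in Morgans (`> 0`); may be a
#'   vector.
#' @param scenario a [scenario()] (or anything [as_scenario()] accepts).
#' @param trajectory optionally a pre-built `allele_trajectory`.
#' @param probe probe width `r2` in Morgans; defaults to the scenario's
#'   `r2_probe` control (1e-6). Must be small relative to the scale on
#'   which the hazard varies.
#' @return Switch rate(s) per Morgan (non-negative).
#' @export
tau10 <- function(r, scenario, trajectory = NULL, probe = NULL) {
  scenario <- as_scenario(scenario)
  if (any(r <= 0)) stop("'r' must be positive", call. = FALSE)
  if (is.null(trajectory)) trajectory <- build_trajectory(scenario)
  if (is.null(probe)) probe <- scenario$r2_probe
  vapply(r, function(ri) {
    p <- solve_ancestry(trajectory, r1 = ri, r2 = probe,
                        lambda = scenario$lambda,
                        rtol = scenario$rtol, atol = scenario$atol)
    denom <- p[1L] + p[2L] + p[3L]
    if (denom < 1e-12) {
      stop("no surviving donor-ancestry probability at r = ", ri,
           " (degenerate scenario)", call. = FALSE)
    }
    max(p[3L] / (denom * probe), 0)
  }, numeric(1))
}

#' Hazard of tract termination on a distance grid
#'
#' Evaluates [tau10()] on a geometric grid of distances from the selected
#' locus. The grid runs from 1e-6 Morgans to `r_max`, which defaults to
#' ten times the neutral expected one-sided tract length and is doubled
#' (up to three times) until the survival of the tract beyond `r_max`
#' falls below `tail_tol`.
#'
#' @inheritParams tau10
#' @param n_points number of grid points (default from the scenario,
#'   normally 1000).
#' @param r_max initial grid maximum in Morgans (automatic when `NULL`).
#' @param tail_tol target survival beyond `r_max` (default 1e-6).
#' @return An object of class `hazard_curve`: list with the grid `r`, the
#'   rates `tau`, and metadata.
#' @export
hazard_curve <- function(scenario, trajectory = NULL, n_points = NULL,
                         r_max = NULL, probe = NULL, tail_tol = 1e-6) {
  scenario <- as_scenario(scenario)
  if (is.null(trajectory)) trajectory <- build_trajectory(scenario)
  if (is.null(n_points)) n_points <- scenario$n_points
  if (is.null(probe)) probe <- scenario$r2_probe
  if (is.null(r_max)) r_max <- scenario$r_max
  omega1 <- if (!is.null(scenario$omega1)) scenario$omega1 else
    trajectory$omega1
  if (is.null(r_max)) {
    one_sided_neutral <- neutral_expected_tract_length(
      omega1, scenario$T, scenario$two_ne) / 2
    r_max <- 10 * one_sided_neutral
  }
  r_min <- 1e-6
  for (attempt in 0:3) {
    r <- exp(seq(log(r_min), log(r_max), length.out = n_points))
    tau <- tau10(r, scenario, trajectory, probe)
    surv_end <- exp(-cumhaz(r, tau)[n_points])
    if (surv_end < tail_tol || attempt == 3L) break
    r_max <- 2 * r_max
  }
  structure(list(r = r, tau = tau, probe = probe, r_max = r_max,
                 tail_survival = surv_end, scenario = scenario,
                 trajectory_mode = trajectory$mode),
            class = "hazard_curve")
}

# cumulative hazard by trapezoidal rule, with the stretch below the first
# grid point treated as constant hazard tau[1]
cumhaz <- function(r, tau) {
  n <- length(r)
  inc <- c(tau[1L] * r[1L],
           diff(r) * (tau[-n] + tau[-1L]) / 2)
  cumsum(inc)
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf(
    "Ancestry switch-rate curve: %d points on [%.3g, %.3g] Morgans\n",
    length(x$r), x$r[1L], x$r[length(x$r)]))
  cat(sprintf("  tau10 range %.4g .. %.4g per Morgan; tail survival %.2g\n",
              min(x$tau), max(x$tau), x$tail_survival))
  invisible(x)
}

#' Tract-length distribution from a hazard curve
#'
#' The distance from the selected locus to one end of the introgressed
#' tract has survival `S1(r) = exp(-int_0^r tau10)` and density
#' `f(r) = tau10(r) S1(r)`. The full tract is the sum of the two
#' independent, identically distributed one-sided distances, so the full
#' tract mean is twice the one-sided mean and the full variance twice the
#' one-sided variance. Moments are computed by trapezoidal quadrature of
#' the survival-function identities, with the mass beyond the end of the
#' grid assigned a closed-form exponential tail with rate
#' `tau10(r_max)`.
#'
#' @param hazard a [hazard_curve()].
#' @param tail_mass_max error threshold on the residual survival beyond
#'   the grid (default 1e-3).
#' @return An object of class `tract_distribution` with the grid,
#'   survival, density, one-sided and full-tract moments and the tail
#'   mass.
#' @export
tract_length_distribution <- function(hazard, tail_mass_max = 1e-3) {
  stopifnot(inherits(hazard, "hazard_curve"))
  r <- hazard$r; tau <- hazard$tau
  n <- length(r)
  H <- cumhaz(r, tau)
  S <- exp(-H)
  f <- tau * S
  tail_mass <- S[n]
  if (tail_mass > tail_mass_max) {
    stop("tail mass beyond r_max is ", signif(tail_mass, 3),
         "; increase r_max", call. = FALSE)
  }
  c_end <- tau[n]
  # E[X] = int S dr, E[X^2] = 2 int r S dr, both with (0, S=1) prepended
  # and the exponential tail appended analytically
  rr <- c(0, r); SS <- c(1, S)
  m1 <- trapz(rr, SS) + tail_mass / c_end
  ex2 <- 2 * trapz(rr, rr * SS) +
    2 * tail_mass * (r[n] / c_end + 1 / c_end^2)
  v1 <- ex2 - m1^2
  structure(list(r = r, survival = S, density = f, tau = tau,
                 one_sided_mean = m1, one_sided_var = v1,
                 mean = 2 * m1, var = 2 * v1, sd = sqrt(2 * v1),
                 tail_mass = tail_mass, hazard = hazard),
            class = "tract_distribution")
}

trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-n] + y[-1L]) / 2)
}

#' @export
print.tract_distribution <- function(x, ...) {
  cat("Introgressed tract-length distribution\n")
  cat(sprintf("  expected full-tract length: %.6g Morgans (sd %.6g)\n",
              x$mean, x$sd))
  cat(sprintf("  one-sided mean %.6g; tail mass beyond grid %.2g\n",
              x$one_sided_mean, x$tail_mass))
  invisible(x)
}

#' Expected length of the tract containing the selected allele
#'
#' Orchestrates trajectory construction, hazard evaluation and moment
#' integration, and returns the expected full-tract length (twice the
#' one-sided mean). Accepts a [scenario()], a parameter list, or a fitted
#' [tract_model()] (whose cached distribution is then reused).
#'
#' @param scenario scenario, parameter list or `tract_model`.
#' @param trajectory optional pre-built trajectory.
#' @param ... passed to [hazard_curve()].
#' @return Expected tract length in Morgans.
#' @export
expected_tract_length <- function(scenario, trajectory = NULL, ...) {
  if (inherits(scenario, "tract_model")) return(scenario$dist$mean)
  hz <- hazard_curve(as_scenario(scenario), trajectory, ...)
  tract_length_distribution(hz)$mean
}

#' Standard deviation of the tract length
#'
#' Square root of twice the one-sided variance of the hazard-derived
#' distribution; approximates the across-population standard deviation of
#' tract lengths (tracts in different replicate populations).
#'
#' @inheritParams expected_tract_length
#' @return Standard deviation in Morgans.
#' @export
tract_length_sd <- function(scenario, trajectory = NULL, ...) {
  if (inherits(scenario, "tract_model")) return(scenario$dist$sd)
  hz <- hazard_curve(as_scenario(scenario), trajectory, ...)
  tract_length_distribution(hz)$sd
}

#' Neutral expected tract length (sequentially Markov closed form)
#'
#' Expected length of the tract containing a neutral introgressed allele
#' under the SMC' approximation,
#' `2 / (2Ne (1 - omega1) (1 - exp(-T / 2Ne)))`; the factor of two in the
#' numerator reflects conditioning on observing the introgressed allele
#' on the sampled haplotype.
#'
#' @param omega1 admixture fraction in `(0, 1)`.
#' @param T generations since admixture.
#' @param two_ne haploid population size.
#' @return Expected tract length in Morgans.
#' @export
neutral_expected_tract_length <- function(omega1, T, two_ne) {
  stopifnot(omega1 > 0, omega1 < 1, T > 0, two_ne > 0)
  2 / (two_ne * (1 - omega1) * (-expm1(-T / two_ne)))
}
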