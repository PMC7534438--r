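#' Parameterize one adaptive-introgression scenario
#'
#' Bundles the parameters of a single admixture-pulse model with one
#' positively selected introgressed allele, together with the numeric
#' controls used downstream. Exactly one of `omega1` (admixture fraction)
#' and `omega0` (observed frequency at sampling) is the primary
#' parameter; under the logistic trajectory the other is implied through
#' the trajectory and must round-trip if both are supplied.
#'
#' @param omega1 admixture fraction in `(0, 1)` (frequency of the selected
#'   allele right after the pulse).
#' @param s selection coefficient (diploid fitnesses 1, 1+s/2, 1+s);
#'   `s = 0` only in `constant` or `tabulated` mode.
#' @param T generations since admixture (`> 0`).
#' @param two_ne haploid effective population size in chromosomes
#'   (`>= 2`); the pairwise coalescence intensity is `lambda = 1/two_ne`.
#' @param omega0 optional observed frequency at sampling time; give it
#'   *instead of* `omega1` to condition on the present-day frequency.
#' @param mode trajectory mode: `"logistic"` (default), `"constant"`
#'   (neutral) or `"tabulated"` (conditioned mean trajectory).
#' @param n_points number of distances at which the ancestry switch rate
#'   is evaluated (default 1000).
#' @param r2_probe probe width in Morgans used to take the finite-
#'   difference limit defining the switch rate (default 1e-6).
#' @param r_max optional initial maximal distance of the hazard grid in
#'   Morgans; chosen automatically (and extended as needed) when `NULL`.
#' @param rtol,atol relative/absolute tolerances of the ODE solver.
#' @param n_reps replicate count for tabulated-mode trajectory estimation.
#' @param seed optional integer seed for stochastic components.
#' @return An object of class `scenario`.
#' @export
scenario <- function(omega1 = NULL, s = 0, T, two_ne, omega0 = NULL,
                     mode = c("logistic", "constant", "tabulated"),
                     n_points = 1000L, r2_probe = 1e-6, r_max = NULL,
                     rtol = 1e-8, atol = 1e-10, n_reps = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(omega1) && is.null(omega0)) {
    stop("one of 'omega1' or 'omega0' must be given", call. = FALSE)
  }
  omega0_primary <- is.null(omega1)
  for (om in list(omega1, omega0)) {
    if (!is.null(om) && (!is.numeric(om) || om <= 0 || om >= 1)) {
      stop("allele frequencies must lie strictly inside (0, 1)",
           call. = FALSE)
    }
  }
  if (!is.numeric(T) || T <= 0) stop("'T' must be positive", call. = FALSE)
  if (!is.numeric(two_ne) || two_ne < 2) {
    stop("'two_ne' must be at least 2 chromosomes", call. = FALSE)
  }
  if (mode == "logistic") {
    check_selection(s)
  } else if (s < 0) {
    stop("'s' must be non-negative", call. = FALSE)
  }
  if (mode == "tabulated" && omega0_primary) {
    stop("tabulated mode requires 'omega1' (the trajectory is simulated ",
         "forward from the admixture fraction)", call. = FALSE)
  }
  if (r2_probe <= 0 || n_points < 2) {
    stop("'r2_probe' must be positive and 'n_points' at least 2",
         call. = FALSE)
  }
  structure(list(omega1 = omega1, s = s, T = T, two_ne = two_ne,
                 lambda = 1 / two_ne, omega0 = omega0,
                 omega0_primary = omega0_primary, mode = mode,
                 n_points = as.integer(n_points), r2_probe = r2_probe,
                 r_max = r_max, rtol = rtol, atol = atol,
                 n_reps = n_reps, seed = seed),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  prim <- if (x$omega0_primary) {
    sprintf("omega0 = %g (observed frequency, primary)", x$omega0)
  } else {
    sprintf("omega1 = %g (admixture fraction)", x$omega1)
  }
  cat("Adaptive-introgression scenario\n")
  cat(sprintf("  %s, s = %g, T = %g generations, 2Ne = %g (%s trajectory)\n",
              prim, x$s, x$T, x$two_ne, x$mode))
  invisible(x)
}

as_scenario <- function(x, ...) {
  if (inherits(x, "scenario")) return(x)
  if (inherits(x, "tract_model")) return(x$scenario)
  if (is.list(x)) return(do.call(scenario, x))
  stop("cannot interpret object of class '", class(x)[1L],
       "' as a scenario", call. = FALSE)
}
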