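#' Deterministic tract-length model for adaptive introgression
#'
#' Fits the deterministic approximation for the distribution of the
#' introgressed ancestry tract containing a positively selected allele:
#' builds the allele-frequency trajectory, integrates the six-state
#' ancestral process to obtain the along-genome ancestry switch rate at a
#' grid of distances, and converts that hazard into the one-sided and
#' full tract-length distribution with its mean and standard deviation.
#'
#' @inheritParams scenario
#' @param trajectory optional pre-built `allele_trajectory` (mainly for
#'   tabulated mode, e.g. from [conditional_mean_trajectory()]).
#' @param ... further numeric controls passed to [scenario()]
#'   (`n_points`, `r2_probe`, `r_max`, `rtol`, `atol`, `n_reps`, `seed`).
#' @return An object of class `tract_model` with components `scenario`,
#'   `trajectory`, `hazard`, `dist` and the scalar summaries `mean`,
#'   `sd`, `tail_mass` and `neutral_mean` (the neutral closed form at the
#'   same admixture fraction, time and population size).
#' @examples
#' \donttest{
#' m <- tract_model(omega1 = 0.025, s = 0.01, T = 1000, two_ne = 10000)
#' m
#' coef(m)
#' mean(m)
#' }
#' @export
tract_model <- function(omega1 = NULL, s = 0, T, two_ne, omega0 = NULL,
                        mode = c("logistic", "constant", "tabulated"),
                        trajectory = NULL, ...) {
  sc <- scenario(omega1 = omega1, s = s, T = T, two_ne = two_ne,
                 omega0 = omega0, mode = mode, ...)
  fit_tract_model(sc, trajectory)
}

#' @rdname tract_model
#' @param scenario_obj a ready-made [scenario()] to fit instead of the
#'   individual parameters.
#' @export
fit_tract_model <- function(scenario_obj, trajectory = NULL) {
  sc <- as_scenario(scenario_obj)
  t_start <- proc.time()[["elapsed"]]
  if (is.null(trajectory)) trajectory <- build_trajectory(sc)
  hz <- hazard_curve(sc, trajectory)
  dist <- tract_length_distribution(hz)
  om1 <- if (!is.null(sc$omega1)) sc$omega1 else trajectory$omega1
  structure(list(scenario = sc, trajectory = trajectory, hazard = hz,
                 dist = dist, mean = dist$mean, sd = dist$sd,
                 tail_mass = dist$tail_mass,
                 neutral_mean = neutral_expected_tract_length(
                   om1, sc$T, sc$two_ne),
                 elapsed = proc.time()[["elapsed"]] - t_start),
            class = "tract_model")
}

#' @export
print.tract_model <- function(x, digits = 6, ...) {
  sc <- x$scenario
  cat("Tract-length model under adaptive introgression\n")
  print(sc)
  cat(sprintf("  expected tract length: %.*g Morgans\n", digits, x$mean))
  cat(sprintf("  sd of tract length:    %.*g Morgans\n", digits, x$sd))
  cat(sprintf("  neutral expectation:   %.*g Morgans\n", digits,
              x$neutral_mean))
  invisible(x)
}

#' @export
summary.tract_model <- function(object, ...) {
  x <- object
  out <- list(
    coef = coef(x), mean = x$mean, sd = x$sd,
    one_sided_mean = x$dist$one_sided_mean,
    neutral_mean = x$neutral_mean,
    selection_vs_neutral = x$mean / x$neutral_mean - 1,
    tail_mass = x$tail_mass, n_points = length(x$hazard$r),
    r_max = x$hazard$r_max, trajectory_mode = x$trajectory$mode,
    omega0 = x$trajectory$omega0, elapsed = x$elapsed)
  class(out) <- "summary.tract_model"
  out
}

#' @export
print.summary.tract_model <- function(x, ...) {
  cat("Tract-length model summary\n")
  cat("  parameters:\n")
  print(signif(x$coef, 6))
  cat(sprintf("  trajectory: %s; frequency at sampling %.4g\n",
              x$trajectory_mode, x$omega0))
  cat(sprintf("  expected tract length %.6g M (one-sided %.6g), sd %.6g M\n",
              x$mean, x$one_sided_mean, x$sd))
  cat(sprintf("  neutral closed form %.6g M (%+.1f%% under selection)\n",
              x$neutral_mean, 100 * x$selection_vs_neutral))
  cat(sprintf("  hazard grid: %d points up to %.4g M; tail mass %.2g\n",
              x$n_points, x$r_max, x$tail_mass))
  invisible(x)
}

#' @export
coef.tract_model <- function(object, ...) {
  sc <- object$scenario
  c(omega1 = if (is.null(sc$omega1)) object$trajectory$omega1 else sc$omega1,
    omega0 = object$trajectory$omega0,
    s = sc$s, T = sc$T, two_ne = sc$two_ne)
}

#' @export
mean.tract_model <- function(x, ...) x$mean

#' Evaluate fitted hazard, survival or density at new distances
#'
#' @param object a [tract_model()].
#' @param r distances in Morgans (defaults to the fitted grid).
#' @param type which one-sided function to return.
#' @param ... unused.
#' @return Numeric vector (log-linear interpolation on the fitted grid).
#' @export
predict.tract_model <- function(object, r = NULL,
                                type = c("hazard", "survival", "density"),
                                ...) {
  type <- match.arg(type)
  d <- object$dist
  y <- switch(type, hazard = d$tau, survival = d$survival,
              density = d$density)
  if (is.null(r)) return(y)
  approx(d$r, y, xout = r, rule = 2)$y
}

#' Plot a fitted tract-length model
#'
#' Three panels: the one-sided tract-end density with the matched-mean
#' exponential for comparison, the survival function, and the ancestry
#' switch rate against distance from the selected site.
#'
#' @param x a [tract_model()].
#' @param which subset of panels `1:3`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tract_model <- function(x, which = 1:3, ...) {
  d <- x$dist
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(d$r, d$density, type = "l", xlab = "distance (M)",
                   ylab = "one-sided density", ...)
    graphics::lines(d$r, stats::dexp(d$r, rate = 1 / d$one_sided_mean),
                    lty = 2)
    graphics::legend("topright", c("model", "exponential (same mean)"),
                     lty = 1:2, bty = "n")
  }
  if (2 %in% which) {
    graphics::plot(d$r, d$survival, type = "l", xlab = "distance (M)",
                   ylab = "survival", ...)
  }
  if (3 %in% which) {
    graphics::plot(d$r, d$tau, type = "l", log = "x",
                   xlab = "distance (M)", ylab = "switch rate (per M)", ...)
  }
  invisible(x)
}

#' Simulate tract data from the model's generating process
#'
#' Runs the forward Wright-Fisher admixture simulator at the model's
#' parameters (matched haploid size `2N = two_ne` unless `N` is given)
#' and returns the sampled ancestry tracts of each replicate.
#'
#' @param object a [tract_model()] in logistic or constant mode.
#' @param nsim number of replicate populations.
#' @param seed optional integer seed.
#' @param N diploid size for the simulation (default `two_ne / 2`).
#' @param sample_size chromosomes sampled per replicate.
#' @param L,position chromosome geometry in Morgans.
#' @param ... unused.
#' @return Data frame of tract records across replicates (columns
#'   `replicate`, `chromosome`, `start`, `end`, `ancestry`).
#' @export
simulate.tract_model <- function(object, nsim = 1, seed = NULL,
                                 N = NULL, sample_size = 100L, L = 1,
                                 position = 0.5, ...) {
  sc <- object$scenario
  if (is.null(sc$omega1)) {
    stop("simulation requires an admixture-fraction parameterization",
         call. = FALSE)
  }
  if (is.null(N)) N <- max(2L, as.integer(round(sc$two_ne / 2)))
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim_config(N = N, omega1 = sc$omega1,
                    s = if (sc$mode == "constant") 0 else sc$s,
                    T = sc$T, L = L, position = position,
                    sample_size = sample_size)
  out <- lapply(seq_len(nsim), function(i) {
    pop <- simulate_admixture(cfg, seed = NULL)
    sample_tracts(pop, replicate = i)
  })
  do.call(rbind, out)
}
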