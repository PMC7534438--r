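#' Logistic frequency of a selected allele in backward time
#'
#' Frequency of a positively selected allele along the deterministic
#' logistic trajectory, parameterized in backward time so that the
#' frequency *decreases* toward the past: `omega(t) = 1 / (1 + exp(s*t/2))`.
#' The origin `t = 0` is the symmetry point where the allele is at
#' frequency 1/2; negative times are closer to fixation, positive times
#' closer to loss. The factor `s/2` arises from the additive diploid
#' fitness scheme (1, 1+s/2, 1+s) reduced to genic selection.
#'
#' @param t backward time in generations (numeric vector).
#' @param s selection coefficient, `s > 0`.
#' @return Allele frequency in `[0, 1]`, same length as `t`.
#' @seealso [logistic_time()] for the inverse, [build_trajectory()].
#' @examples
#' logistic_frequency(0, 0.01)        # 0.5 at the symmetry point
#' logistic_frequency(439.44, 0.01)   # ~0.1
#' @export
logistic_frequency <- function(t, s) {
  check_selection(s)
  z <- s * t / 2
  ifelse(z > 700, 0, ifelse(z < -700, 1, 1 / (1 + exp(z))))
}

#' Backward time at which the logistic trajectory passes a frequency
#'
#' Inverse of [logistic_frequency()]: `t = (2/s) * log((1 - omega)/omega)`.
#' Used to anchor the time of introgression `t1` (where the trajectory
#' equals the admixture fraction) and the time of sampling `t0 = t1 - T`.
#'
#' @param omega allele frequency, strictly inside `(0, 1)`.
#' @param s selection coefficient, `s > 0`.
#' @return Backward time in generations.
#' @export
logistic_time <- function(omega, s) {
  check_selection(s)
  if (any(omega <= 0 | omega >= 1)) {
    stop("'omega' must lie strictly inside (0, 1)", call. = FALSE)
  }
  (2 / s) * log((1 - omega) / omega)
}

check_selection <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0) {
    stop("selection coefficient 's' must be a single positive number; ",
         "for a neutral allele use the constant trajectory mode",
         call. = FALSE)
  }
  invisible(s)
}

#' Build the selected-allele frequency trajectory for a scenario
#'
#' Constructs the backward-time frequency function `omega(t)` on the
#' interval from sampling (`t0`) to introgression (`t1 = t0 + T`):
#'
#' * `logistic`: closed form anchored so that `omega(t1)` equals the
#'   admixture fraction `omega1`; if the scenario is parameterized by the
#'   observed frequency `omega0` instead, `t0` solves
#'   `omega(t0) = omega0` and `omega1` is implied.
#' * `constant`: `omega(t) = omega1` for all `t` (neutral mode; the
#'   drift-free mean of a neutral allele frequency).
#' * `tabulated`: a per-generation table of conditioned mean frequencies,
#'   typically from [conditional_mean_trajectory()], re-anchored so that
#'   forward generation 0 (introgression) sits at `t1 = T` and the
#'   sampling time at `t0 = 0`; evaluation is piecewise linear.
#'
#' @param scenario a [scenario()] object.
#' @param table for tabulated mode, an `allele_trajectory` from
#'   [conditional_mean_trajectory()] (or a data frame with columns
#'   `generation` and `mean_frequency`). Generated on the fly from the
#'   scenario's `n_reps` and `seed` controls when omitted.
#' @return An object of class `allele_trajectory`.
#' @export
build_trajectory <- function(scenario, table = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  mode <- scenario$mode
  Tgen <- scenario$T
  if (mode == "logistic") {
    s <- scenario$s
    if (!is.null(scenario$omega0) && scenario$omega0_primary) {
      t0 <- logistic_time(scenario$omega0, s)
      t1 <- t0 + Tgen
      omega1 <- logistic_frequency(t1, s)
      omega0 <- scenario$omega0
    } else {
      t1 <- logistic_time(scenario$omega1, s)
      t0 <- t1 - Tgen
      omega0 <- logistic_frequency(t0, s)
      omega1 <- scenario$omega1
    }
    traj <- new_trajectory("logistic", s = s, t0 = t0, t1 = t1,
                           omega1 = omega1, omega0 = omega0)
  } else if (mode == "constant") {
    omega1 <- if (!is.null(scenario$omega1)) scenario$omega1 else scenario$omega0
    traj <- new_trajectory("constant", t0 = 0, t1 = Tgen,
                           omega1 = omega1, omega0 = omega1,
                           omega_const = omega1)
  } else { # tabulated
    if (is.null(table)) {
      table <- conditional_mean_trajectory(
        omega1 = scenario$omega1, s = scenario$s, two_ne = scenario$two_ne,
        horizon = ceiling(1.5 * Tgen) + 10L,
        n_reps = scenario$n_reps, seed = scenario$seed)
    }
    tab <- if (inherits(table, "allele_trajectory")) table$table else table
    stopifnot(all(c("generation", "mean_frequency") %in% names(tab)))
    if (max(tab$generation) < Tgen) {
      stop("tabulated trajectory horizon (", max(tab$generation),
           ") is shorter than T = ", Tgen, call. = FALSE)
    }
    traj <- new_trajectory("tabulated", t0 = 0, t1 = Tgen,
                           omega1 = tab$mean_frequency[1L],
                           omega0 = approx(tab$generation, tab$mean_frequency,
                                           xout = Tgen)$y,
                           table = tab)
  }
  if (!is.null(scenario$omega1) && !is.null(scenario$omega0) &&
      mode == "logistic") {
    # the primary parameter anchored the trajectory; the other must be
    # implied by it
    mismatch <- if (scenario$omega0_primary) {
      abs(traj$omega1 - scenario$omega1)
    } else {
      abs(traj$omega0 - scenario$omega0)
    }
    if (mismatch > 1e-6) {
      stop("omega1 and omega0 are mutually inconsistent under the ",
           "logistic trajectory (implied omega0 = ",
           signif(traj$omega0, 6), ", implied omega1 = ",
           signif(traj$omega1, 6), ")", call. = FALSE)
    }
  }
  traj
}

new_trajectory <- function(mode, s = NA_real_, t0, t1, omega1, omega0,
                           omega_const = NA_real_, table = NULL,
                           meta = list()) {
  structure(list(mode = mode, s = s, t0 = t0, t1 = t1, omega1 = omega1,
                 omega0 = omega0, omega_const = omega_const, table = table,
                 meta = meta),
            class = "allele_trajectory")
}

#' Evaluate a trajectory at backward times
#'
#' @param trajectory an `allele_trajectory`.
#' @param t backward times (generations); for tabulated trajectories these
#'   must fall inside the tabulated span.
#' @return Allele frequencies in `[0, 1]`.
#' @export
trajectory_frequency <- function(trajectory, t) {
  stopifnot(inherits(trajectory, "allele_trajectory"))
  switch(trajectory$mode,
    logistic = logistic_frequency(t, trajectory$s),
    constant = rep_len(trajectory$omega_const, length(t)),
    tabulated = {
      g <- trajectory$t1 - t # forward generations since introgression
      tab <- trajectory$table
      approx(tab$generation, tab$mean_frequency, xout = g, rule = 2)$y
    })
}

#' @export
print.allele_trajectory <- function(x, ...) {
  cat("Selected-allele trajectory (", x$mode, " mode)\n", sep = "")
  cat(sprintf("  span (backward time): t0 = %.6g .. t1 = %.6g generations\n",
              x$t0, x$t1))
  cat(sprintf("  omega(t1) = %.6g (introgression), omega(t0) = %.6g (sampling)\n",
              x$omega1, x$omega0))
  if (x$mode == "logistic") cat(sprintf("  s = %g\n", x$s))
  if (x$mode == "tabulated") {
    cat(sprintf("  tabulated over %d generations, %d replicates surviving at the end\n",
                max(x$table$generation),
                utils::tail(x$table$n_surviving, 1L)))
  }
  invisible(x)
}

#' Conditioned mean allele-frequency trajectory by Wright-Fisher simulation
#'
#' For small admixture fractions genetic drift makes the logistic
#' approximation poor. The expected trajectory is then estimated by
#' forward-in-time haploid Wright-Fisher simulation under genic selection:
#' at each generation the allele count is drawn as
#' `Binomial(2Ne, p)` with `p = x (1 + s/2) / (1 + x s/2)` where `x` is
#' the current frequency, and the per-generation mean is taken over
#' replicates in which the allele is still present at that generation
#' (the conditioning event; loss is absorbing, fixed replicates remain in
#' the average).
#'
#' @param omega1 initial admixture fraction; the initial copy number is
#'   `round(omega1 * two_ne)`, at least 1.
#' @param s selection coefficient (`>= 0`; the haploid allele fitness is
#'   `1 + s/2`).
#' @param two_ne haploid population size (chromosomes).
#' @param horizon number of generations to simulate.
#' @param n_reps number of replicate trajectories (at least 1000; the
#'   default `1e5` is needed for admixture fractions as small as 6e-4).
#' @param seed optional integer seed.
#' @param condition conditioning event for the per-generation average:
#'   `"sampling"` (default) averages, at every generation, over the
#'   replicates in which the allele is still present at the *end* of the
#'   simulated horizon (the time of sampling) — since loss is absorbing
#'   these replicates are present at every earlier generation too;
#'   `"generation"` averages over the replicates with the allele present
#'   at that generation (a weaker conditioning that also includes
#'   replicates that later lose the allele, hence rises more slowly).
#' @param batch_size replicates simulated per internal batch (memory
#'   control; does not affect the result for a given seed).
#' @return A tabulated `allele_trajectory` whose `table` has columns
#'   `generation`, `mean_frequency` and `n_surviving` (replicates with
#'   the allele present at that generation), anchored at `t0 = 0`,
#'   `t1 = horizon` (re-anchor through [build_trajectory()]).
#' @export
conditional_mean_trajectory <- function(omega1, s, two_ne, horizon,
                                        n_reps = 1e5, seed = NULL,
                                        condition = c("sampling",
                                                      "generation"),
                                        batch_size = 2e4) {
  condition <- match.arg(condition)
  stopifnot(omega1 > 0, omega1 < 1, s >= 0, two_ne >= 2, horizon >= 1)
  if (n_reps < 1000) {
    stop("'n_reps' must be at least 1000 for a usable conditioned mean",
         call. = FALSE)
  }
  k0 <- max(1L, as.integer(round(omega1 * two_ne)))
  if (!is.null(seed)) set.seed(seed)
  H <- as.integer(horizon)
  sum_cond <- numeric(H + 1L)   # sum of counts over the conditioning set
  n_cond <- numeric(H + 1L)     # size of the conditioning set
  n_alive <- numeric(H + 1L)    # replicates with the allele present
  left <- as.integer(n_reps)
  while (left > 0L) {
    nb <- min(left, as.integer(batch_size))
    left <- left - nb
    path <- matrix(0L, nrow = nb, ncol = H + 1L)
    k <- rep.int(k0, nb)
    idx <- seq_len(nb)
    path[, 1L] <- k0
    for (g in seq_len(H)) {
      x <- k / two_ne
      p <- x * (1 + s / 2) / (1 + x * s / 2)
      k <- rbinom(length(k), two_ne, p)
      alive <- k > 0L
      k <- k[alive]
      idx <- idx[alive]
      if (length(idx)) path[cbind(idx, g + 1L)] <- k
      n_alive[g + 1L] <- n_alive[g + 1L] + length(idx)
      if (length(idx) == 0L) break
    }
    if (condition == "sampling") {
      surv <- path[, H + 1L] > 0L
      if (any(surv)) {
        sum_cond <- sum_cond + colSums(path[surv, , drop = FALSE])
        n_cond <- n_cond + sum(surv)
      }
    } else {
      sum_cond <- sum_cond + colSums(path)
      n_cond <- n_cond + colSums(path > 0L)
    }
  }
  n_alive[1L] <- n_reps
  if (n_cond[H + 1L] == 0) {
    stop("all ", n_reps, " replicates lost the allele before the horizon ",
         "of ", H, " generations (initial copies: ", k0, ")",
         call. = FALSE)
  }
  tab <- data.frame(generation = 0:H,
                    mean_frequency = sum_cond / (n_cond * two_ne),
                    n_surviving = as.integer(n_alive))
  new_trajectory("tabulated", s = s, t0 = 0, t1 = H,
                 omega1 = tab$mean_frequency[1L],
                 omega0 = tab$mean_frequency[nrow(tab)],
                 table = tab,
                 meta = list(omega1 = omega1, s = s, two_ne = two_ne,
                             n_reps = n_reps, seed = seed,
                             condition = condition,
                             n_conditioned = n_cond[H + 1L]))
}

#' First generation at which a tabulated trajectory reaches a frequency
#'
#' Used by the dating workflow: the time since introgression is estimated
#' as the time needed for the conditioned mean trajectory to reach the
#' observed allele frequency.
#'
#' @param trajectory a tabulated `allele_trajectory` (forward-time table).
#' @param target frequency to reach.
#' @param interpolate if `TRUE`, return the linearly interpolated real
#'   crossing time; the default reports the first integer generation whose
#'   mean frequency is at or above `target`.
#' @return Generations since introgression.
#' @export
time_to_frequency <- function(trajectory, target, interpolate = FALSE) {
  stopifnot(inherits(trajectory, "allele_trajectory"),
            trajectory$mode == "tabulated")
  tab <- trajectory$table
  mf <- tab$mean_frequency
  if (mf[1L] >= target) return(0)
  hit <- which(mf >= target)
  if (length(hit) == 0L) {
    stop("trajectory never reaches frequency ", target,
         " within its horizon of ", max(tab$generation), " generations",
         call. = FALSE)
  }
  i <- hit[1L]
  if (!interpolate) return(tab$generation[i])
  g0 <- tab$generation[i - 1L]; g1 <- tab$generation[i]
  f0 <- mf[i - 1L]; f1 <- mf[i]
  g0 + (target - f0) / (f1 - f0) * (g1 - g0)
}
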