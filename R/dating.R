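#' Date an introgression event while accounting for selection
#'
#' For each candidate selection coefficient, estimates the conditioned
#' mean allele-frequency trajectory from the admixture fraction by
#' Wright-Fisher simulation, finds the time needed to reach the observed
#' present-day frequency, and computes the expected tract length of the
#' introgressed segment under that trajectory together with the neutral
#' closed-form expectation for the same admixture fraction and time.
#' Comparing the two columns shows by how much a neutral dating of the
#' tract length would misjudge the timing when the allele was in fact
#' selected.
#'
#' @param omega1 admixture fraction (e.g. 6e-4 for Denisovan-like pulses).
#' @param omega0 observed present-day frequency of the selected allele.
#' @param s vector of candidate selection coefficients (each `> 0`).
#' @param two_ne haploid population size used in the tract model
#'   (coalescence intensity) and the neutral closed form.
#' @param traj_two_ne haploid size used in the Wright-Fisher trajectory
#'   simulation (defaults to `two_ne`). The conditioning acceleration of
#'   the sweep depends on the initial copy number
#'   `round(omega1 * traj_two_ne)`, so the dating is sensitive to this
#'   size even when the coalescent side is not.
#' @param n_reps replicate trajectories per `s` (default 1e5).
#' @param seed optional integer seed; each `s` uses an offset sub-seed so
#'   rows are independent yet reproducible.
#' @param horizon simulation horizon in generations; defaults to 1.5
#'   times the deterministic logistic time from `omega1` to `omega0`.
#' @param ... further controls passed to [scenario()].
#' @return Data frame with one row per `s`: `s`, `T` (generations),
#'   `tract_length` (selection-aware, Morgans), `neutral_length`
#'   (closed form at the same `T`) and `rel_diff`
#'   (`tract_length/neutral_length - 1`).
#' @export
date_introgression <- function(omega1, omega0, s, two_ne,
                               traj_two_ne = two_ne, n_reps = 1e5,
                               seed = NULL, horizon = NULL, ...) {
  stopifnot(all(s > 0), omega0 > omega1)
  rows <- vector("list", length(s))
  for (i in seq_along(s)) {
    si <- s[i]
    hor <- horizon
    if (is.null(hor)) {
      hor <- ceiling(1.3 * (logistic_time(omega1, si) -
                              logistic_time(omega0, si)))
    }
    sub_seed <- if (is.null(seed)) NULL else (seed + 7919L * i) %% .Machine$integer.max
    traj <- conditional_mean_trajectory(omega1, si, traj_two_ne,
                                        horizon = hor,
                                        n_reps = n_reps, seed = sub_seed)
    Tg <- time_to_frequency(traj, omega0)
    sc <- scenario(omega1 = omega1, s = si, T = Tg, two_ne = two_ne,
                   mode = "tabulated", n_reps = n_reps, seed = sub_seed, ...)
    fit <- fit_tract_model(sc, trajectory = build_trajectory(sc, table = traj))
    neutral <- neutral_expected_tract_length(omega1, Tg, two_ne)
    rows[[i]] <- data.frame(s = si, T = Tg, tract_length = fit$mean,
                            neutral_length = neutral,
                            rel_diff = fit$mean / neutral - 1)
  }
  do.call(rbind, rows)
}
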