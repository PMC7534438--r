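#' Generator matrix of the six-state ancestral-configuration process
#'
#' The three loci are the selected site `alpha` and two linked neutral
#' sites `beta` and `gamma` at recombination distances `r1`
#' (`alpha`-`beta`) and `r2` (`beta`-`gamma`), both in Morgans. Tracking
#' the lineages ancestral to a sampled chromosome backward in time, the
#' joint configuration takes six states (A/a is the allele at the
#' selected site on the chromosome carrying the ancestral material;
#' `ba/bn`, `ga/gn` mark whether the material at beta/gamma is ancestral
#' to the sample):
#'
#' 1. `(A-ba-ga)`  4. `(a-ba-gn, A-bn-ga)`
#' 2. `(A-ba-gn, A-bn-ga)`  5. `(a-ba-gn, a-bn-ga)`
#' 3. `(A-ba-gn, a-bn-ga)`  6. `(a-ba-ga)`
#'
#' Transitions are recombination events (rates proportional to `r1`, `r2`
#' and the frequency `omega` of the selected allele, which determines the
#' allele on the incoming chromosome) and coalescence, possible only
#' between chromosomes carrying the same allele, at rate `lambda/omega`
#' within the A background and `lambda/(1 - omega)` within the a
#' background, where `lambda = 1/2Ne`.
#'
#' @param omega frequency of the selected allele, strictly in `(0, 1)`;
#'   values outside `[1e-12, 1 - 1e-12]` are clamped since the
#'   coalescence rates diverge at the boundary.
#' @param r1,r2 recombination distances in Morgans (`>= 0`).
#' @param lambda pairwise coalescence intensity `1/2Ne` per generation.
#' @return A 6x6 generator matrix (row = outflow state): off-diagonal
#'   entries are non-negative and every row sums to zero.
#' @export
rate_matrix <- function(omega, r1, r2, lambda) {
  if (length(omega) != 1L || is.na(omega) || omega <= 0 || omega >= 1) {
    stop("'omega' must be a single frequency strictly inside (0, 1); ",
         "clamp boundary frequencies to [1e-12, 1 - 1e-12]", call. = FALSE)
  }
  stopifnot(r1 >= 0, r2 >= 0, lambda > 0)
  w <- min(max(omega, 1e-12), 1 - 1e-12)
  wb <- 1 - w
  M <- matrix(0, 6, 6)
  M[1, 2] <- r2 * w;        M[1, 3] <- r2 * wb;       M[1, 6] <- r1 * wb
  M[2, 1] <- lambda / w;    M[2, 3] <- (r1 + r2) * wb; M[2, 4] <- r1 * wb
  M[3, 2] <- (r1 + r2) * w; M[3, 5] <- r1 * wb
  M[4, 2] <- r1 * w;        M[4, 5] <- (r1 + r2) * wb
  M[5, 3] <- r1 * w;        M[5, 4] <- (r1 + r2) * w;  M[5, 6] <- lambda / wb
  M[6, 1] <- r1 * w;        M[6, 4] <- r2 * w;         M[6, 5] <- r2 * wb
  diag(M) <- -rowSums(M)
  dimnames(M) <- list(state_labels(), state_labels())
  M
}

state_labels <- function() {
  c("(A-ba-ga)", "(A-ba-gn,A-bn-ga)", "(A-ba-gn,a-bn-ga)",
    "(a-ba-gn,A-bn-ga)", "(a-ba-gn,a-bn-ga)", "(a-ba-ga)")
}

#' Integrate the six-state ancestry process over a frequency trajectory
#'
#' Solves the linear non-autonomous system `P'(t) = P(t) M(t)` from the
#' sampling time `t0` to the introgression time `t1` (backward time
#' increases toward the past), where `M(t)` is [rate_matrix()] evaluated
#' along the allele-frequency trajectory. Integration uses `lsoda`
#' through \pkg{deSolve} with a compiled right-hand side.
#'
#' @param trajectory an `allele_trajectory` evaluable on `[t0, t1]`.
#' @param t0,t1 backward times with `t0 < t1`; defaults taken from the
#'   trajectory anchors.
#' @param r1,r2 recombination distances in Morgans.
#' @param lambda coalescence intensity `1/2Ne`.
#' @param init initial state probabilities at `t0`; the default
#'   `(1,0,0,0,0,0)` conditions on sampling a chromosome that carries the
#'   selected allele with both neutral loci on it.
#' @param times optional vector of backward times at which to report the
#'   solution (must start at `t0` and end at `t1`); by default only the
#'   endpoint is returned.
#' @param rtol,atol solver tolerances. Integration always uses the
#'   stiff-capable adaptive `lsoda`; for tabulated trajectories, which
#'   are piecewise linear with derivative kinks at every generation, the
#'   solver is restarted at each generation (output points on the
#'   generation grid) so that no step straddles a kink.
#' @return If `times` is `NULL`, the named probability vector at `t1`
#'   (clamped to `[0, 1]`); otherwise a matrix with one row per requested
#'   time and columns `t`, `p1`..`p6`.
#' @export
solve_ancestry <- function(trajectory, t0 = trajectory$t0,
                           t1 = trajectory$t1, r1, r2, lambda,
                           init = c(1, 0, 0, 0, 0, 0), times = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(trajectory, "allele_trajectory"), t0 < t1,
            r1 >= 0, r2 >= 0, lambda > 0, length(init) == 6L)
  if (abs(sum(init) - 1) > 1e-8) {
    stop("'init' must sum to 1", call. = FALSE)
  }
  mode_code <- match(trajectory$mode, c("logistic", "constant", "tabulated")) - 1
  parms <- c(r1, r2, lambda, mode_code,
             if (is.na(trajectory$s)) 0 else trajectory$s,
             if (is.na(trajectory$omega_const)) 0 else trajectory$omega_const)
  tt <- if (is.null(times)) c(t0, t1) else times
  args <- list(y = init, times = tt, func = "admixtract_derivs",
               parms = parms, dllname = "admixtract",
               initfunc = "admixtract_initmod", method = "lsoda",
               rtol = rtol, atol = atol)
  if (mode_code == 2) {
    tab <- trajectory$table
    tb <- trajectory$t1 - tab$generation # table generations -> backward time
    ord <- order(tb)
    # pad so the forcing covers solver look-ahead just outside [t0, t1]
    fmat <- cbind(c(min(tb) - 2, tb[ord], max(tb) + 2),
                  c(tab$mean_frequency[ord][1L], tab$mean_frequency[ord],
                    tab$mean_frequency[ord][length(ord)]))
    args$initforc <- "admixtract_initforc"
    args$forcings <- fmat
    steps <- unique(c(t0, seq(ceiling(t0), floor(t1), by = 1), t1))
    args$times <- if (is.null(times)) steps else sort(union(steps, times))
  }
  sol <- do.call(deSolve::ode, args)
  p_end <- sol[nrow(sol), 2:7]
  drift <- abs(sum(p_end) - 1)
  if (drift > 1e-4) {
    stop("probability mass drifted by ", signif(drift, 3),
         " during integration; tighten rtol/atol", call. = FALSE)
  }
  if (is.null(times)) {
    p <- pmin(pmax(as.numeric(p_end), 0), 1)
    names(p) <- state_labels()
    return(p)
  }
  sol <- sol[sol[, 1L] %in% times, , drop = FALSE]
  colnames(sol) <- c("t", paste0("p", 1:6))
  sol
}
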