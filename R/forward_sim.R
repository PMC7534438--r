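#' Configuration of the forward admixture simulator
#'
#' @param N diploid population size (constant; `>= 2`).
#' @param omega1 admixture fraction in `(0, 1)`: a fraction `omega1` of
#'   generation-0 individuals are donor-homozygous (chromosomes of pure
#'   donor ancestry carrying the selected allele), the rest recipient.
#' @param s selection coefficient; fitnesses 1, 1+s/2 and 1+s by the
#'   number of selected alleles at the selected site.
#' @param T generations to simulate.
#' @param L chromosome length in Morgans (default 1).
#' @param position position of the selected site in Morgans (default 0.5).
#' @param sample_size chromosomes to sample (default 100, i.e. 50
#'   diploids).
#' @param n_reps replicate populations (default 1).
#' @param seed optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(N, omega1, s = 0, T, L = 1, position = 0.5,
                       sample_size = 100L, n_reps = 1L, seed = NULL) {
  stopifnot(N >= 2, omega1 > 0, omega1 < 1, s >= 0, T >= 1,
            L > 0, position > 0, position < L, sample_size >= 1)
  structure(list(N = as.integer(N), omega1 = omega1, s = s,
                 T = as.integer(T), L = L, position = position,
                 sample_size = as.integer(sample_size),
                 n_reps = as.integer(n_reps), seed = seed),
            class = "sim_config")
}

#' Forward Wright-Fisher admixture simulation with junction tracking
#'
#' Simulates a constant-size population of hermaphroditic diploids with a
#' single continuous chromosome. Each generation, every offspring draws
#' two parents independently with probability proportional to fitness
#' (selfing permitted), and each transmitted gamete recombines with a
#' Poisson(`L`) number of crossovers at uniform positions (no
#' interference). Chromosomes are stored as ancestry-junction lists; the
#' allele at the selected site is determined by the local ancestry there
#' (donor ancestry = selected allele).
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (overrides the config's).
#' @return An object of class `admix_population`: junction lists
#'   (`anc0`, `breaks`) for the `2N` chromosomes, the per-chromosome
#'   selected allele, the allele-frequency path over generations
#'   `0..T`, and the config.
#' @export
simulate_admixture <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  res <- .Call(C_simulate_admixture, config$N, config$L, config$position,
               config$omega1, config$s, config$T)
  structure(c(res, list(config = config)), class = "admix_population")
}

#' @export
print.admix_population <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Admixed population: N = %d diploids, %g Morgans, generation %d\n",
    cfg$N, cfg$L, cfg$T))
  cat(sprintf("  selected allele frequency: %.4g (started at %.4g)\n",
              x$freq_path[length(x$freq_path)], x$freq_path[1L]))
  cat(sprintf("  mean junctions per chromosome: %.2f\n",
              mean(lengths(x$breaks))))
  invisible(x)
}

#' Sample chromosomes and report their ancestry tracts
#'
#' Draws chromosomes uniformly without replacement and expands their
#' junction lists into ancestry tracts. Tracts partition `[0, L)` under
#' the half-open convention and adjacent tracts carry different ancestry.
#'
#' @param population an `admix_population`.
#' @param n_chromosomes chromosomes to sample (default: the config's
#'   `sample_size`); at most `2N`.
#' @param focal_position if non-`NULL`, only the tract covering this
#'   position (in Morgans) is returned for each sampled chromosome.
#' @param seed optional seed for the sampling step.
#' @param replicate replicate id stored in the output (default 1).
#' @return A data frame with columns `replicate`, `chromosome`,
#'   `start`, `end` (Morgans) and `ancestry` (0 recipient / 1 donor).
#' @export
sample_tracts <- function(population, n_chromosomes = NULL,
                          focal_position = NULL, seed = NULL,
                          replicate = 1L) {
  stopifnot(inherits(population, "admix_population"))
  cfg <- population$config
  n_tot <- 2L * cfg$N
  if (is.null(n_chromosomes)) n_chromosomes <- cfg$sample_size
  if (n_chromosomes > n_tot) {
    stop("cannot sample ", n_chromosomes, " chromosomes from ", n_tot,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n_tot, n_chromosomes)
  out <- lapply(idx, function(i) {
    brk <- population$breaks[[i]]
    bounds <- c(0, brk, cfg$L)
    anc <- (population$anc0[i] + seq_len(length(brk) + 1L) - 1L) %% 2L
    d <- data.frame(replicate = replicate, chromosome = i,
                    start = bounds[-length(bounds)], end = bounds[-1L],
                    ancestry = anc)
    if (!is.null(focal_position)) {
      d <- d[d$start <= focal_position & focal_position < d$end, ,
             drop = FALSE]
    }
    d
  })
  do.call(rbind, out)
}

#' Summaries of sampled tract lengths
#'
#' Mean and standard deviation of tract lengths, conditioning on a given
#' ancestry (donor by default). The across-replicate ("across
#' population") sd pools all qualifying tracts; the within-replicate sd
#' is computed per replicate and averaged over replicates with at least
#' two qualifying tracts.
#'
#' @param tracts a tract data frame as from [sample_tracts()] (possibly
#'   several replicates bound together), or any data frame with columns
#'   `replicate`, `start`, `end`, `ancestry` — or `replicate` and
#'   `length`.
#' @param ancestry ancestry to condition on (default 1, donor).
#' @return A list with `mean`, `sd_across`, `sd_within`, `n_tracts` and
#'   `n_replicates`.
#' @export
empirical_summary <- function(tracts, ancestry = 1L) {
  if (!"length" %in% names(tracts)) {
    tracts$length <- tracts$end - tracts$start
  }
  if ("ancestry" %in% names(tracts)) {
    tracts <- tracts[tracts$ancestry == ancestry, , drop = FALSE]
  }
  if (nrow(tracts) < 2L) {
    stop("fewer than two qualifying tracts", call. = FALSE)
  }
  len <- tracts$length
  per_rep <- split(len, tracts$replicate)
  within <- vapply(per_rep, function(v) {
    if (length(v) >= 2L) stats::sd(v) else NA_real_
  }, numeric(1))
  list(mean = mean(len), sd_across = stats::sd(len),
       sd_within = mean(within, na.rm = TRUE),
       n_tracts = length(len), n_replicates = length(per_rep))
}

#' Validate the deterministic model against forward simulations
#'
#' For each `(omega1, s)` block of a parameter grid, runs replicate
#' forward simulations to the largest requested time, snapshotting the
#' tract covering the selected site on every donor-ancestry chromosome at
#' each requested time, and compares the empirical mean tract length with
#' the deterministic model at the matched haploid size `2N`.
#'
#' Tract lengths within one replicate are strongly correlated (they share
#' the replicate's allele-frequency path and descend from few founders),
#' so precision is governed by the number of replicates, not tracts.
#' Replicates therefore accumulate until, at every snapshot, at least
#' `min_tracts` tracts were collected *and* the cluster-robust
#' (replicate-level) standard error of the pooled mean falls below
#' `se_target` (relative), subject to `min_reps`/`max_reps` bounds.
#'
#' The scenarios of a grid row may carry their own simulation geometry:
#' optional grid columns `N`, `L`, `position` and `max_reps` override
#' the defaults. By default short horizons (`T <= 100`) run at
#' `N = 1000` on a 1-Morgan chromosome, while long horizons run at
#' `N = 2500` (drift and its conditioning effect shrink with the
#' initial copy number `omega1 * 2N`, and the deterministic model
#' assumes they are negligible) on a 0.15-Morgan chromosome — tracts
#' after hundreds of generations are 30+ times shorter than the
#' half-chromosome, and junction bookkeeping scales with chromosome
#' length. Rows sharing `(omega1, s, N, L, position)` are served by
#' common simulations with snapshots at each requested `T`. The default
#' replicate caps give every simulation group a similar wall-clock
#' share (a few minutes each): short horizons are cheap per replicate
#' and get a high cap, while among the long horizons the caps scale
#' inversely with per-replicate cost, which grows with the admixture
#' fraction (donor-segment bookkeeping) and with sweeps to high
#' frequency.
#'
#' @param grid data frame with columns `omega1`, `s`, `T` (use
#'   [table1_grid()] for the standard 16-scenario validation grid) and
#'   optionally `N`, `L`, `position`.
#' @param min_tracts minimum donor tracts per scenario.
#' @param se_target relative (cluster-robust) standard-error target for
#'   each scenario's empirical mean.
#' @param min_reps replicate floor per simulation group; `max_reps` caps
#'   come from the grid (see above).
#' @param chunk replicates per internal batch.
#' @param seed optional integer seed.
#' @param verbose print per-group progress.
#' @return Data frame with one row per scenario: empirical mean, its
#'   cluster-robust relative standard error, model mean, relative error
#'   (fraction), tract and replicate counts.
#' @export
validate_model <- function(grid = table1_grid(), min_tracts = 1e4,
                           se_target = 0.02, min_reps = 300L,
                           chunk = 100L, seed = NULL, verbose = FALSE) {
  stopifnot(all(c("omega1", "s", "T") %in% names(grid)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid$N)) {
    # keep the initial copy number omega1 * 2N at 50-250: the
    # deterministic model neglects the drift-conditioning acceleration
    # of the sweep, which scales inversely with the copy number
    grid$N <- ifelse(grid$omega1 <= 0.02,
                     ifelse(grid$T <= 100, 2500L, 5000L),
                     ifelse(grid$T <= 100, 1000L, 2500L))
  }
  if (is.null(grid$L)) grid$L <- ifelse(grid$T <= 100, 1, 0.15)
  if (is.null(grid$position)) grid$position <- grid$L / 2
  if (is.null(grid$max_reps)) {
    grid$max_reps <- ifelse(grid$T <= 100, 3000L,
                     ifelse(grid$omega1 <= 0.02 & grid$s <= 0.005, 800L,
                     ifelse(grid$omega1 <= 0.02, 300L,
                     ifelse(grid$s <= 0.005, 350L, 240L))))
  }
  key <- interaction(grid$omega1, grid$s, grid$N, grid$L, grid$position,
                     drop = TRUE)
  out <- NULL
  for (grp in levels(key)) {
    rows <- grid[key == grp, , drop = FALSE]
    om <- rows$omega1[1L]; sel <- rows$s[1L]; Nb <- as.integer(rows$N[1L])
    max_reps <- max(rows$max_reps)
    snaps <- sort(unique(as.integer(rows$T)))
    sums <- counts <- vector("list", length(snaps))
    reps_done <- 0L
    repeat {
      res <- .Call(C_focal_tracts, Nb, rows$L[1L], rows$position[1L],
                   om, sel, snaps, as.integer(chunk),
                   .Machine$integer.max)
      for (i in seq_along(snaps)) {
        sums[[i]] <- c(sums[[i]],
                       vapply(split(res[[i]]$length, res[[i]]$replicate),
                              sum, 0))
        counts[[i]] <- c(counts[[i]],
                         vapply(split(res[[i]]$length, res[[i]]$replicate),
                                length, 0L))
      }
      reps_done <- reps_done + chunk
      stats <- vapply(seq_along(snaps), function(i) {
        cl <- cluster_mean_se(sums[[i]], counts[[i]])
        c(n = sum(counts[[i]]), rse = cl[2] / cl[1])
      }, numeric(2))
      if (verbose) {
        message(sprintf("  %s: %d reps, rse %s", grp, reps_done,
                        paste(signif(stats["rse", ], 2), collapse = " ")))
      }
      done <- all(stats["n", ] >= min_tracts) &&
        all(stats["rse", ] <= se_target) && reps_done >= min_reps
      if (done || reps_done >= max_reps) break
    }
    for (i in seq_along(snaps)) {
      model <- expected_tract_length(scenario(
        omega1 = om, s = sel, T = snaps[i], two_ne = 2 * Nb,
        mode = "logistic"))
      cl <- cluster_mean_se(sums[[i]], counts[[i]])
      out <- rbind(out, data.frame(
        omega1 = om, s = sel, T = snaps[i], N = Nb,
        n_reps = reps_done, n_tracts = sum(counts[[i]]),
        sim_mean = cl[1], sim_rse = cl[2] / cl[1], model_mean = model,
        rel_err = abs(cl[1] - model) / cl[1]))
    }
  }
  out[order(out$omega1, out$s, out$T), ]
}

# pooled mean of clustered observations and its cluster-robust standard
# error (linearized ratio estimator over replicates)
cluster_mean_se <- function(sums, counts) {
  ntot <- sum(counts)
  mu <- sum(sums) / ntot
  se <- sqrt(sum((sums - mu * counts)^2)) / ntot
  c(mu, se)
}

#' The standard 16-scenario validation grid
#'
#' Admixture fractions 0.01 and 0.05, selection coefficients 0.001 and
#' 0.01, and 50, 100, 500 and 1000 generations since admixture.
#'
#' @return Data frame with columns `omega1`, `s`, `T`.
#' @export
table1_grid <- function() {
  expand.grid(T = c(50L, 100L, 500L, 1000L), s = c(0.001, 0.01),
              omega1 = c(0.01, 0.05))[, c("omega1", "s", "T")]
}
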