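#' Write / read a tabulated trajectory as TSV
#'
#' Tab-separated columns `generation`, `mean_frequency`, `n_surviving`,
#' preceded by a `#` header line carrying the generating parameters.
#'
#' @param trajectory a tabulated `allele_trajectory`.
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "allele_trajectory"),
            trajectory$mode == "tabulated")
  m <- trajectory$meta
  hdr <- sprintf("# omega1=%s s=%s two_ne=%s n_reps=%s seed=%s",
                 fmt_meta(m$omega1), fmt_meta(m$s), fmt_meta(m$two_ne),
                 fmt_meta(m$n_reps), fmt_meta(m$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(trajectory$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

fmt_meta <- function(x) if (is.null(x)) "NA" else format(x)

#' @rdname write_trajectory
#' @return `read_trajectory()` returns a tabulated `allele_trajectory`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  meta <- list()
  if (length(hdr)) {
    kv <- regmatches(hdr[1L], gregexpr("[a-z0-9_]+=[^ ]+", hdr[1L]))[[1L]]
    for (item in kv) {
      parts <- strsplit(item, "=", fixed = TRUE)[[1L]]
      val <- suppressWarnings(as.numeric(parts[2L]))
      meta[[parts[1L]]] <- if (is.na(val)) NULL else val
    }
  }
  new_trajectory("tabulated", s = meta$s %||% NA_real_, t0 = 0,
                 t1 = max(tab$generation),
                 omega1 = tab$mean_frequency[1L],
                 omega0 = tab$mean_frequency[nrow(tab)],
                 table = tab, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a scenario grid from a YAML or JSON config file
#'
#' The file either lists scenarios explicitly under `scenarios:` or gives
#' parameter vectors under `grid:` whose Cartesian product is expanded.
#' Optional `controls:` (e.g. `n_points`, `r2_probe`, `seed`) apply to
#' every scenario.
#'
#' @param path config file; format chosen by extension (`.json` parsed
#'   with \pkg{jsonlite}, anything else with \pkg{yaml}).
#' @return A list of [scenario()] objects, classed `scenario_grid`.
#' @export
read_scenario_grid <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_scenario_grid(cfg)
}

#' @rdname read_scenario_grid
#' @param cfg a list with elements `scenarios` or `grid`, plus optional
#'   `controls`.
#' @export
as_scenario_grid <- function(cfg) {
  controls <- cfg$controls %||% list()
  raw <- if (!is.null(cfg$scenarios)) {
    cfg$scenarios
  } else if (!is.null(cfg$grid)) {
    df <- expand.grid(cfg$grid, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  } else {
    stop("config must contain 'scenarios' or 'grid'", call. = FALSE)
  }
  scenarios <- lapply(raw, function(p) do.call(scenario, c(p, controls)))
  structure(scenarios, class = "scenario_grid", controls = controls)
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat("Scenario grid with", length(x), "scenarios\n")
  invisible(x)
}

#' Serialize a scenario grid back to a config list
#'
#' Inverse of [as_scenario_grid()] up to field order; round-trips through
#' [as_scenario_grid()].
#'
#' @param grid a `scenario_grid`.
#' @return A list with `scenarios` and `controls` entries.
#' @export
scenario_grid_config <- function(grid) {
  stopifnot(inherits(grid, "scenario_grid"))
  keep <- c("omega1", "s", "T", "two_ne", "omega0", "mode")
  list(scenarios = lapply(grid, function(sc) {
    p <- sc[keep]
    p[!vapply(p, is.null, TRUE)]
  }), controls = attr(grid, "controls"))
}

write_tsv_with_header <- function(df, path, meta_lines) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", meta_lines), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected tract length over a scenario grid
#'
#' One row per scenario, in grid order, with the expected tract length,
#' its standard deviation, the residual tail mass and timing. Failures
#' are caught per scenario and reported in an `error` column without
#' aborting the rest of the grid.
#'
#' @param grid a `scenario_grid` (or list of [scenario()] objects).
#' @param out optional TSV output path (`#`-prefixed metadata header).
#' @return The summary data frame, invisibly when `out` is given.
#' @export
run_expected_length <- function(grid, out = NULL) {
  rows <- lapply(grid, function(sc) {
    base <- data.frame(
      omega1 = sc$omega1 %||% NA, omega0 = sc$omega0 %||% NA,
      s = sc$s, T = sc$T, two_ne = sc$two_ne, mode = sc$mode,
      expected_length_morgan = NA_real_, sd_morgan = NA_real_,
      tail_mass = NA_real_, seconds = NA_real_, error = "")
    tryCatch({
      fit <- fit_tract_model(sc)
      base$expected_length_morgan <- fit$mean
      base$sd_morgan <- fit$sd
      base$tail_mass <- fit$tail_mass
      base$seconds <- fit$elapsed
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  })
  res <- if (length(rows) == 0L) {
    data.frame(omega1 = numeric(), omega0 = numeric(), s = numeric(),
               T = numeric(), two_ne = numeric(), mode = character(),
               expected_length_morgan = numeric(),
               sd_morgan = numeric(), tail_mass = numeric(),
               seconds = numeric(), error = character())
  } else {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  if (!is.null(out)) {
    write_tsv_with_header(res, out, sprintf(
      "expected tract lengths for %d scenarios", length(rows)))
    return(invisible(res))
  }
  res
}

#' Export the fitted tract-end distribution as TSV
#'
#' Columns `r_morgan`, `tau10`, `survival`, `density` and
#' `exp_density` (the exponential density with the model's one-sided
#' mean, for goodness-of-fit comparison).
#'
#' @param model a [tract_model()] (or a [scenario()] to fit first).
#' @param out optional TSV output path.
#' @return The distribution data frame, invisibly when `out` is given.
#' @export
run_distribution <- function(model, out = NULL) {
  if (!inherits(model, "tract_model")) model <- fit_tract_model(model)
  d <- model$dist
  df <- data.frame(r_morgan = d$r, tau10 = d$tau, survival = d$survival,
                   density = d$density,
                   exp_density = stats::dexp(d$r, 1 / d$one_sided_mean))
  if (!is.null(out)) {
    sc <- model$scenario
    write_tsv_with_header(df, out, sprintf(
      "one-sided tract-end distribution: omega1=%s s=%g T=%g two_ne=%g mode=%s mean=%.6g",
      fmt_meta(sc$omega1), sc$s, sc$T, sc$two_ne, sc$mode, model$mean))
    return(invisible(df))
  }
  df
}

#' Run the dating workflow and write its table
#'
#' Thin wrapper around [date_introgression()] that writes the per-`s`
#' dating table as TSV.
#'
#' @inheritParams date_introgression
#' @param out optional TSV output path.
#' @return The dating data frame, invisibly when `out` is given.
#' @export
run_dating <- function(omega1, omega0, s, two_ne, n_reps = 1e5,
                       seed = NULL, out = NULL, ...) {
  res <- date_introgression(omega1, omega0, s, two_ne, n_reps = n_reps,
                            seed = seed, ...)
  if (!is.null(out)) {
    write_tsv_with_header(res, out, sprintf(
      "introgression dating: omega1=%g omega0=%g two_ne=%g n_reps=%g seed=%s",
      omega1, omega0, two_ne, n_reps, fmt_meta(seed)))
    return(invisible(res))
  }
  res
}
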