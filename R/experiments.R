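#' First passage below the consensus threshold
#'
#' Scans a disagreement series for the first entry strictly below the
#' threshold ("below" is read strictly). Entry `j` of the series is the
#' disagreement after step `j - 1`, so the initial state is step 0.
#'
#' @param sigma_series numeric vector of disagreement values (step 0, 1, ...).
#' @param sigma_cons consensus threshold; must be positive.
#' @return The first step with `sigma < sigma_cons`, or `NA_integer_` if the
#'   series never crosses.
#' @export
detect_consensus <- function(sigma_series, sigma_cons = 0.01) {
  if (!is.numeric(sigma_cons) || length(sigma_cons) != 1 || sigma_cons <= 0) {
    stop("`sigma_cons` must be a single positive number", call. = FALSE)
  }
  hit <- which(sigma_series < sigma_cons)
  if (length(hit) == 0) NA_integer_ else as.integer(hit[1] - 1L)
}

#' Run a seeded Monte Carlo ensemble
#'
#' Executes `reps` independent simulations of the same configuration with
#' derived seeds `base_seed + 0, base_seed + 1, ...` (a counter scheme, so
#' an ensemble can be extended without re-running existing members) and
#' summarizes how often consensus is reached. The result is identical for a
#' given `base_seed` and `reps` regardless of execution order.
#'
#' By default each run stops at first passage below `sigma_cons`: under
#' purely assimilative influence consensus is empirically absorbing, and the
#' consensus frequency is defined through first passage, so early stopping
#' changes no summary.
#'
#' @param config a [sim_config()]; its own `seed` is ignored in favour of
#'   the derived per-run seeds.
#' @param reps number of runs (>= 1).
#' @param base_seed first seed of the counter scheme (default `config$seed`).
#' @param stop_at_consensus stop runs at first passage (default `TRUE`).
#' @return An object of class `ensemble_summary`: `reps`, `consensus_times`
#'   (per-run first-passage step, `NA` when no consensus), `consensus_count`,
#'   `C_t` (consensus frequency at the run horizon), `t` (the horizon),
#'   `seeds` and the `config`.
#' @export
#' @examples
#' ens <- run_ensemble(sim_config(scenario = "U3", p = 1, t_max = 300), reps = 5)
#' ens$C_t
run_ensemble <- function(config, reps, base_seed = config$seed,
                         stop_at_consensus = TRUE) {
  stopifnot(inherits(config, "sim_config"), reps >= 1)
  seeds <- as.integer(base_seed) + seq_len(reps) - 1L
  times <- integer(reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seeds[r]
    res <- run_simulation(cfg, record = "sigma",
                          stop_at_consensus = stop_at_consensus)
    times[r] <- if (is.na(res$consensus_step)) NA_integer_
                else res$consensus_step
  }
  structure(
    list(
      reps = as.integer(reps),
      consensus_times = times,
      consensus_count = sum(!is.na(times)),
      C_t = mean(!is.na(times)),
      t = config$t_max,
      seeds = seeds,
      config = config
    ),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "<ensemble_summary> %d runs, C_%d = %.3f (%d consensus)\n",
    x$reps, x$t, x$C_t, x$consensus_count
  ))
  invisible(x)
}

#' Consensus frequency at an earlier horizon
#'
#' The fraction of ensemble runs whose first passage below the threshold
#' occurred at or before step `t`; non-decreasing in `t` by construction.
#'
#' @param ensemble an `ensemble_summary`.
#' @param t horizon in steps (default: the ensemble's run horizon).
#' @return A frequency in \[0, 1\].
#' @export
consensus_frequency <- function(ensemble, t = ensemble$t) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  mean(!is.na(ensemble$consensus_times) & ensemble$consensus_times <= t)
}

#' Consensus-frequency parameter sweep
#'
#' Runs one ensemble per row of a parameter grid and returns a tidy results
#' table. Any column of `grid` matching a [sim_config()] field overrides the
#' base configuration for that point; a `scenario` column sets the
#' perception parameters. Covers both layouts of interest: rewiring-by-
#' perception grids (`p` x `alpha_in` x `alpha_out`) and single-parameter
#' sensitivity lines.
#'
#' @param grid data frame of parameter points.
#' @param reps runs per point.
#' @param base_seed first seed for every point's ensemble (each point uses
#'   the same derived seed sequence, so points differ only by parameters).
#' @param base_config configuration supplying all unswept parameters.
#' @return `grid` with columns `reps`, `consensus_count` and `C_t` appended,
#'   plus attribute `ensembles` (the per-point `ensemble_summary` list).
#' @export
sweep_consensus <- function(grid, reps, base_seed = 1L,
                            base_config = sim_config()) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1)
  bad <- setdiff(names(grid), config_fields())
  if (length(bad) > 0) {
    stop(sprintf("unknown parameter column(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  ensembles <- vector("list", nrow(grid))
  out <- grid
  out$reps <- as.integer(reps)
  out$consensus_count <- NA_integer_
  out$C_t <- NA_real_
  for (i in seq_len(nrow(grid))) {
    vals <- unclass(base_config)
    vals$scenario <- NULL
    if ("scenario" %in% names(grid)) {
      # a swept scenario defines the perception parameters unless the grid
      # also sweeps them explicitly
      vals$alpha_in <- NULL
      vals$alpha_out <- NULL
    }
    for (f in names(grid)) vals[[f]] <- grid[[f]][i]
    cfg <- do.call(sim_config, vals)
    ens <- run_ensemble(cfg, reps = reps, base_seed = base_seed)
    ensembles[[i]] <- ens
    out$consensus_count[i] <- ens$consensus_count
    out$C_t[i] <- ens$C_t
  }
  attr(out, "ensembles") <- ensembles
  out
}
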