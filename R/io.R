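format_float <- function(x) formatC(x, digits = 17, format = "g")

#' Write a simulation run to an output directory
#'
#' Produces the standard plain-text artifact set for one run: a per-step
#' summary CSV (`step, sigma, consensus_flag`), a trajectory CSV
#' (`step, agent_id, mean_opinion`; only when the run recorded means), the
#' network edge/node lists, the configuration echo (`config.json`) and a
#' manifest (`manifest.json`) from which the run can be reproduced
#' bit-identically on the same platform. Floats in trajectories carry 17
#' significant digits so reproduction checks can compare files byte-wise.
#'
#' @param result a `sim_result` from [run_simulation()].
#' @param dir output directory (created if needed); should be empty or new —
#'   one directory per invocation, with exactly one manifest.
#' @return Invisibly, the manifest as a list.
#' @export
write_run <- function(result, dir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config

  files <- c("config.json", "summary.csv", "edges.csv", "nodes.csv")
  save_config(cfg, file.path(dir, "config.json"))

  steps <- seq_along(result$sigma) - 1L
  summary_df <- data.frame(
    step = steps,
    sigma = format_float(result$sigma),
    consensus_flag = as.integer(result$sigma < cfg$sigma_cons)
  )
  utils::write.csv(summary_df, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)

  write_edge_list(result$final$network,
                  file.path(dir, "edges.csv"), file.path(dir, "nodes.csv"))

  if (!is.null(result$mean_trajectory)) {
    traj <- result$mean_trajectory
    rec_steps <- (seq_len(ncol(traj)) - 1L) * result$thin
    df <- data.frame(
      step = rep(rec_steps, each = nrow(traj)),
      agent_id = rep(seq_len(nrow(traj)), times = ncol(traj)),
      mean_opinion = format_float(as.vector(traj))
    )
    utils::write.csv(df, file.path(dir, "trajectory.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, "trajectory.csv")
  }

  manifest <- list(
    package = "opinionet",
    version = as.character(utils::packageVersion("opinionet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = {
      v <- unclass(cfg)
      if (is.na(v$scenario)) v$scenario <- NULL
      v
    },
    consensus_step = if (is.na(result$consensus_step)) NULL
                     else result$consensus_step,
    steps_run = result$steps_run,
    files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Reproduce a run from its manifest
#'
#' Reads the configuration echoed in a run manifest and re-executes the
#' simulation. On one platform the rerun is bit-identical, so writing it to
#' a fresh directory reproduces every output file byte for byte (timestamps
#' in the manifest aside).
#'
#' @param manifest_path path to a `manifest.json` written by [write_run()].
#' @param record,thin passed to [run_simulation()]; defaults reproduce the
#'   summary outputs.
#' @return The recomputed `sim_result`.
#' @export
reproduce_run <- function(manifest_path, record = "sigma", thin = 1L) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg <- do.call(sim_config, man$config)
  run_simulation(cfg, record = record, thin = thin)
}

#' Write an ensemble summary to an output directory
#'
#' One results CSV row per ensemble (the sweep-table schema) plus a JSON
#' file with the per-run consensus times and seeds, and a manifest.
#'
#' @param ensemble an `ensemble_summary` from [run_ensemble()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "ensemble_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- ensemble$config
  row <- data.frame(
    p = cfg$p, alpha_in = cfg$alpha_in, alpha_out = cfg$alpha_out,
    k_in = cfg$k_in, k_out = cfg$k_out, delta = cfg$delta, n = cfg$n,
    q = cfg$q, kappa = cfg$kappa, sigma0 = cfg$sigma0, t = ensemble$t,
    reps = ensemble$reps, consensus_count = ensemble$consensus_count,
    C_t = ensemble$C_t
  )
  utils::write.csv(row, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      seeds = ensemble$seeds,
      consensus_times = ensemble$consensus_times,
      C_t = ensemble$C_t
    ),
    file.path(dir, "ensemble.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE
  )
  manifest <- list(
    package = "opinionet",
    version = as.character(utils::packageVersion("opinionet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = ensemble$seeds[1],
    reps = ensemble$reps,
    config = {
      v <- unclass(cfg)
      if (is.na(v$scenario)) v$scenario <- NULL
      v
    },
    files = c("results.csv", "ensemble.json")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write a sweep results table
#'
#' @param sweep_table result of [sweep_consensus()].
#' @param path destination CSV.
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(sweep_table, path) {
  tab <- sweep_table
  attr(tab, "ensembles") <- NULL
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
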