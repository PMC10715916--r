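#' Named perception scenarios
#'
#' Four reference societies distinguished by the perception-filter
#' transparencies: unbiased skeptical `U1` (`alpha_in = alpha_out = 0.25`),
#' unbiased neutral `U2` (0.5, 0.5), unbiased credulous `U3` (0.75, 0.75) and
#' biased `B` — credulous towards the in-group, skeptical towards the
#' out-group (0.75, 0.25).
#'
#' @param name one of `"U1"`, `"U2"`, `"U3"`, `"B"`.
#' @return Named list with `alpha_in` and `alpha_out`.
#' @export
scenario_params <- function(name) {
  tab <- list(
    U1 = c(0.25, 0.25), U2 = c(0.5, 0.5),
    U3 = c(0.75, 0.75), B = c(0.75, 0.25)
  )
  if (!is.character(name) || length(name) != 1 || !name %in% names(tab)) {
    stop("`name` must be one of \"U1\", \"U2\", \"U3\", \"B\"", call. = FALSE)
  }
  list(alpha_in = tab[[name]][1], alpha_out = tab[[name]][2])
}

config_fields <- function() {
  c("n", "k_in", "k_out", "p", "q", "kappa", "sigma0", "delta",
    "alpha_in", "alpha_out", "t_max", "sigma_cons", "seed", "scenario")
}

#' Simulation configuration
#'
#' The single source of truth for one run. Defaults are the standard study
#' conditions: a society of `n = 100` agents on a moderately homophilic
#' network (`k_in = 8`, `k_out = 2`), interaction probability `q = 0.2`,
#' opinion decay speed `kappa = 2e-4`, initial opinion spread `sigma0 = 0.2`,
#' no identity predisposition (`delta = 0`), 5000 steps and a consensus
#' threshold of `sigma_cons = 0.01` on the population SD of mean opinions.
#'
#' @param n number of agents (even).
#' @param k_in,k_out average in-/out-group degree.
#' @param p link rewiring probability in \[0, 1\].
#' @param q per-agent interaction probability per step.
#' @param kappa opinion decay speed during non-interaction.
#' @param sigma0 spread of the initial Gaussian opinions.
#' @param delta identity predisposition of initial means, in \[0, 1\]: a red
#'   agent draws a negative initial mean with probability `0.5 + delta/2`
#'   (blue symmetric).
#' @param alpha_in,alpha_out perception-filter transparencies in \[0, 0.99\].
#' @param t_max number of simulation steps.
#' @param sigma_cons consensus threshold on the disagreement sigma.
#' @param seed RNG seed driving network topology, initial opinions and
#'   update order.
#' @param scenario optional scenario name (see [scenario_params()]); sets
#'   `alpha_in`/`alpha_out` unless those are given explicitly.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' sim_config(scenario = "B", p = 1, seed = 7)
sim_config <- function(n = 100, k_in = 8, k_out = 2, p = 1, q = 0.2,
                       kappa = 2e-4, sigma0 = 0.2, delta = 0,
                       alpha_in = NULL, alpha_out = NULL, t_max = 5000,
                       sigma_cons = 0.01, seed = 1, scenario = NULL) {
  if (!is.null(scenario)) {
    sc <- scenario_params(scenario)
    if (is.null(alpha_in)) alpha_in <- sc$alpha_in
    if (is.null(alpha_out)) alpha_out <- sc$alpha_out
  }
  if (is.null(alpha_in)) alpha_in <- 0.5
  if (is.null(alpha_out)) alpha_out <- 0.5

  cfg <- list(
    n = as.integer(n), k_in = as.integer(k_in), k_out = as.integer(k_out),
    p = as.numeric(p), q = as.numeric(q), kappa = as.numeric(kappa),
    sigma0 = as.numeric(sigma0), delta = as.numeric(delta),
    alpha_in = as.numeric(alpha_in), alpha_out = as.numeric(alpha_out),
    t_max = as.integer(t_max), sigma_cons = as.numeric(sigma_cons),
    seed = as.integer(seed),
    scenario = if (is.null(scenario)) NA_character_ else scenario
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
  }
  prob <- function(x) is.finite(x) && x >= 0 && x <= 1
  chk(cfg$n >= 1, "n", "need at least one agent")
  if (cfg$n > 1) chk(cfg$n %% 2 == 0, "n", "must be even (two equal groups)")
  chk(prob(cfg$p), "p", "must be in [0, 1]")
  chk(prob(cfg$q), "q", "must be in [0, 1]")
  chk(prob(cfg$delta), "delta", "must be in [0, 1]")
  chk(is.finite(cfg$kappa) && cfg$kappa >= 0, "kappa", "must be >= 0")
  chk(is.finite(cfg$sigma0) && cfg$sigma0 > 0, "sigma0", "must be > 0")
  chk(prob(cfg$alpha_in) && cfg$alpha_in <= 0.99, "alpha_in",
      "must be in [0, 0.99]")
  chk(prob(cfg$alpha_out) && cfg$alpha_out <= 0.99, "alpha_out",
      "must be in [0, 0.99]")
  chk(cfg$t_max >= 0, "t_max", "must be >= 0")
  chk(is.finite(cfg$sigma_cons) && cfg$sigma_cons > 0, "sigma_cons",
      "must be > 0")
  chk(!is.na(cfg$seed), "seed", "must be an integer")
  if (cfg$n > 1) {
    chk(cfg$k_in < cfg$n / 2, "k_in", "must be < n/2")
    chk(cfg$k_out <= cfg$n / 2, "k_out", "must be <= n/2")
    chk(cfg$k_in >= 0, "k_in", "must be >= 0")
    chk(cfg$k_out >= 0, "k_out", "must be >= 0")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> n=%d k_in=%d k_out=%d p=%g | alpha_in=%g alpha_out=%g",
      " | q=%g kappa=%g sigma0=%g delta=%g | t_max=%d sigma_cons=%g seed=%d\n"
    ),
    x$n, x$k_in, x$k_out, x$p, x$alpha_in, x$alpha_out, x$q, x$kappa,
    x$sigma0, x$delta, x$t_max, x$sigma_cons, x$seed
  ))
  invisible(x)
}

#' Load a simulation configuration from YAML or JSON
#'
#' Missing fields take the standard defaults (see [sim_config()]); unknown
#' keys are an error so typos are caught; a `scenario` key fills the
#' perception parameters. An empty file yields the full default
#' configuration.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path),
                               call. = FALSE)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  unknown <- setdiff(names(vals), config_fields())
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  do.call(sim_config, vals)
}

#' Save a simulation configuration
#'
#' @param cfg a `sim_config`.
#' @param path destination; format chosen by extension (`.json` or YAML).
#' @return Invisibly, `path`.
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  vals <- unclass(cfg)
  if (is.na(vals$scenario)) vals$scenario <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}
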