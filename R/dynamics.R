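#' Sample initial mean opinions, optionally predisposed by identity
#'
#' With `delta = 0` every agent draws its initial mean uniformly on
#' \[-1, 1\], independent of identity. With `delta > 0` identities predispose
#' opinions: a red agent draws from Uniform\[-1, 0) with probability
#' `0.5 + delta/2` and from Uniform\[0, 1\] otherwise; blue agents are the
#' mirror image (negative with probability `0.5 - delta/2`). At `delta = 1`
#' the sign split is deterministic.
#'
#' Uses R's RNG; seed upstream for reproducibility.
#'
#' @param n number of agents.
#' @param identity character vector of `"red"`/`"blue"` labels, length `n`.
#' @param delta predisposition in \[0, 1\].
#' @return Numeric vector of `n` initial means in \[-1, 1\].
#' @export
sample_initial_means <- function(n, identity, delta = 0) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta < 0 || delta > 1) {
    stop("`delta` must be a single value in [0, 1]", call. = FALSE)
  }
  stopifnot(length(identity) == n)
  if (delta == 0) {
    return(stats::runif(n, -1, 1))
  }
  p_neg <- ifelse(identity == "red", 0.5 + delta / 2, 0.5 - delta / 2)
  neg <- stats::runif(n) < p_neg
  ifelse(neg, stats::runif(n, -1, 0), stats::runif(n, 0, 1))
}

#' Initialize a society
#'
#' Builds the rewired homophilic network, assigns fixed identities (first
#' half red, second half blue) and gives every agent a truncated-Gaussian
#' opinion with spread `sigma0` centred on a randomly sampled mean. Seeds
#' R's RNG from `config$seed`, so the whole run (network, opinions, update
#' order downstream) is reproducible from the configuration alone.
#'
#' @param config a [sim_config()].
#' @param reseed seed the RNG from `config$seed` first (default `TRUE`);
#'   set to `FALSE` to draw from the current RNG state.
#' @return An object of class `society_state`: `time`, `network`, `opinions`
#'   (grid-points x agents matrix, one normalized column per agent),
#'   `identity`, `grid` and the `config`.
#' @export
init_society <- function(config, reseed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (reseed) set.seed(config$seed)
  grid <- belief_grid()
  if (config$n == 1) {
    net <- structure(
      list(n = 1L, identity = "red",
           edges = matrix(integer(0), 0, 2),
           k_in = 0L, k_out = 0L, p = config$p),
      class = "social_network"
    )
  } else {
    net <- homophilic_lattice(config$n, config$k_in, config$k_out)
    net <- rewire_network(net, config$p)
  }
  mu0 <- sample_initial_means(config$n, net$identity, config$delta)
  opinions <- vapply(
    mu0, function(m) opinion_gaussian(m, config$sigma0, grid),
    numeric(length(grid$points))
  )
  structure(
    list(
      time = 0L, network = net, opinions = opinions,
      identity = net$identity, grid = grid, config = config
    ),
    class = "society_state"
  )
}

#' @export
print.society_state <- function(x, ...) {
  cat(sprintf(
    "<society_state> t=%d, %d agents, disagreement sigma=%.4f\n",
    x$time, x$config$n, disagreement(x)
  ))
  invisible(x)
}

#' Advance a society by asynchronous update steps
#'
#' In each step all agents are visited in a fresh uniform random order. A
#' visited agent (the listener) interacts with probability `q` with one of
#' its network neighbours chosen uniformly (the messenger): it applies the
#' Bayesian [social_update()] with `alpha_in` if the messenger shares its
#' identity and `alpha_out` otherwise, reading the messenger's current —
#' possibly already-updated-this-step — opinion. Otherwise (or if it has no
#' neighbours) it applies one [diffuse_step()]. Only listeners change;
#' identities and the network never do.
#'
#' Continues R's RNG state; reproducibility comes from seeding in
#' [init_society()].
#'
#' @param state a `society_state`.
#' @param steps number of steps to advance (default 1).
#' @return The updated `society_state`.
#' @export
society_step <- function(state, steps = 1) {
  stopifnot(inherits(state, "society_state"), steps >= 0)
  if (steps == 0) return(state)
  cfg <- state$config
  csr <- adjacency_csr(state$network)
  res <- cpp_run_society(
    state$opinions, state$grid$points,
    network_group(state$network), csr$targets, csr$offsets,
    cfg$alpha_in, cfg$alpha_out, cfg$q, cfg$kappa / state$grid$delta^2,
    as.integer(steps), cfg$sigma_cons,
    stop_at_consensus = FALSE, mean_stride = 0L
  )
  state$opinions <- res$opinions
  state$time <- state$time + as.integer(steps)
  state
}

#' Run one full simulation
#'
#' Initializes a society from the configuration and advances it `t_max`
#' steps, recording the disagreement sigma (population SD of the agents'
#' mean opinions) after every step and, optionally, every agent's mean
#' opinion on a thinned time grid. The run is fully reproducible: one seed
#' drives network topology, initial opinions and update order.
#'
#' @param config a [sim_config()].
#' @param record `"sigma"` (default) records the sigma series only;
#'   `"means"` additionally records the per-agent mean-opinion trajectory.
#' @param thin stride (in steps) for the mean-opinion trajectory.
#' @param stop_at_consensus stop the run at the first step with
#'   `sigma < sigma_cons` (default `FALSE`: run all `t_max` steps).
#' @return An object of class `sim_result`: `sigma` (length `steps_run + 1`,
#'   entry `t+1` is sigma after step `t`, starting at `t = 0`),
#'   `consensus_step` (first step with `sigma < sigma_cons`, or `NA`),
#'   `steps_run`, `final` (the final `society_state`), `means` (final agent
#'   means), `mean_trajectory` (agents x recorded-times matrix, or `NULL`)
#'   and the `config`.
#' @export
#' @examples
#' res <- run_simulation(sim_config(scenario = "B", p = 1, t_max = 50, seed = 1))
#' utils::tail(res$sigma, 3)
run_simulation <- function(config, record = c("sigma", "means"), thin = 1L,
                           stop_at_consensus = FALSE) {
  record <- match.arg(record)
  state <- init_society(config)
  cfg <- state$config
  csr <- adjacency_csr(state$network)
  res <- cpp_run_society(
    state$opinions, state$grid$points,
    network_group(state$network), csr$targets, csr$offsets,
    cfg$alpha_in, cfg$alpha_out, cfg$q, cfg$kappa / state$grid$delta^2,
    cfg$t_max, cfg$sigma_cons,
    stop_at_consensus = stop_at_consensus,
    mean_stride = if (record == "means") as.integer(thin) else 0L
  )
  state$opinions <- res$opinions
  state$time <- as.integer(res$steps_run)
  structure(
    list(
      sigma = res$sigma,
      consensus_step = if (res$consensus_step < 0) NA_integer_
                       else as.integer(res$consensus_step),
      steps_run = as.integer(res$steps_run),
      final = state,
      means = res$means,
      mean_trajectory = res$mean_trajectory,
      thin = as.integer(thin),
      config = cfg
    ),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cons <- if (is.na(x$consensus_step)) "no consensus"
          else sprintf("consensus at step %d", x$consensus_step)
  cat(sprintf(
    "<sim_result> %d steps, final sigma=%.4f, %s (threshold %g)\n",
    x$steps_run, x$sigma[length(x$sigma)], cons, x$config$sigma_cons
  ))
  invisible(x)
}

#' Disagreement: spread of the agents' mean opinions
#'
#' The population standard deviation (divisor `n`) of the per-agent opinion
#' means. A society is in consensus when this falls below the threshold
#' `sigma_cons`.
#'
#' @param x a `society_state`, a `sim_result`, or a numeric vector of agent
#'   mean opinions.
#' @return A single non-negative number.
#' @export
disagreement <- function(x) {
  mu <- if (inherits(x, "society_state")) {
    as.numeric(crossprod(x$opinions, x$grid$points))
  } else if (inherits(x, "sim_result")) {
    x$means
  } else {
    as.numeric(x)
  }
  if (length(mu) == 0) stop("need at least one agent", call. = FALSE)
  sqrt(sum((mu - mean(mu))^2) / length(mu))
}
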