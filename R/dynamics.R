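#' Configuration of the mutualistic population-dynamics model
#'
#' Holds the sampling intervals for every stochastic model parameter and the
#' simulation controls. The defaults follow the standard parameterisation of
#' the Lotka-Volterra mutualism model with a type-II functional response:
#' intrinsic growth rates drawn from \[0.85, 1.1\], intraspecific
#' competition from \[0.99, 1.01\], interspecific competition from
#' \[0.22, 0.24\] (so self-limitation always dominates), per-link mutualistic
#' strengths from \[0.19, 0.21\], handling time fixed at 0.1 for both
#' guilds, initial abundance densities from \[0, 1\], and an extinction
#' threshold of 1e-10 on the final abundance density.
#'
#' @param alpha_range Interval for intrinsic growth rates.
#' @param beta_intra_range Interval for intraspecific competition (diagonal
#'   of the within-guild competition matrix).
#' @param beta_inter_range Interval for interspecific competition (all
#'   within-guild off-diagonal pairs).
#' @param gamma_range Interval for per-link mutualistic strength; one value
#'   is drawn independently for each directed link present in the network.
#' @param handling_time Handling time of the saturating functional response,
#'   shared by plants and animals.
#' @param init_abundance_range Interval for initial abundance densities.
#' @param extinction_threshold Final abundance density below which a species
#'   counts as extinct.
#' @param n_runs Number of replicate simulations per network; every run
#'   redraws all parameters and initial abundances.
#' @param t_end Integration horizon in model time units. If the equilibrium
#'   tolerance is not met at `t_end` the horizon is doubled up to
#'   `max_extensions` times.
#' @param equilibrium_tol Largest `max |dS/dt|` accepted as settled.
#' @param max_extensions Maximum number of horizon doublings.
#' @param seed Integer seed; per-run substreams are derived from it
#'   deterministically, so results do not depend on execution order.
#' @return A `dynamics_config` list.
#' @export
dynamics_config <- function(alpha_range = c(0.85, 1.1),
                            beta_intra_range = c(0.99, 1.01),
                            beta_inter_range = c(0.22, 0.24),
                            gamma_range = c(0.19, 0.21),
                            handling_time = 0.1,
                            init_abundance_range = c(0, 1),
                            extinction_threshold = 1e-10,
                            n_runs = 1000,
                            t_end = 1000,
                            equilibrium_tol = 1e-8,
                            max_extensions = 4,
                            seed = 1L) {
  cfg <- list(alpha_range = alpha_range,
              beta_intra_range = beta_intra_range,
              beta_inter_range = beta_inter_range,
              gamma_range = gamma_range,
              handling_time = handling_time,
              init_abundance_range = init_abundance_range,
              extinction_threshold = extinction_threshold,
              n_runs = as.integer(n_runs),
              t_end = t_end,
              equilibrium_tol = equilibrium_tol,
              max_extensions = as.integer(max_extensions),
              seed = as.integer(seed))
  for (nm in c("alpha_range", "beta_intra_range", "beta_inter_range",
               "gamma_range", "init_abundance_range")) {
    iv <- cfg[[nm]]
    if (length(iv) != 2 || anyNA(iv) || any(!is.finite(iv)) || iv[1] > iv[2]) {
      stop(nm, " must be a finite interval with lower <= upper", call. = FALSE)
    }
  }
  stopifnot(cfg$extinction_threshold > 0, cfg$n_runs >= 1, cfg$t_end > 0)
  class(cfg) <- "dynamics_config"
  cfg
}

#' Read a dynamics configuration from a YAML or JSON file
#'
#' The file holds any subset of [dynamics_config()]'s arguments, field for
#' field; omitted fields keep their defaults. Arguments supplied through
#' `...` override file values, so a stored configuration can be re-run with,
#' say, a different seed or run count.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param ... Overrides passed to [dynamics_config()].
#' @return A `dynamics_config`.
#' @export
read_dynamics_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  known <- names(formals(dynamics_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(dynamics_config, vals)
}

# Deterministic 31-bit stream seed from (seed, network id, run index).
# Lehmer-style mixing keeps runs order-independent and reproducible.
derive_seed <- function(seed, id, run) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  for (ch in utf8ToInt(as.character(id))) x <- (x * 31 + ch) %% m
  x <- (x * 48271 + as.numeric(run) * 16807 + 1) %% m
  as.integer(x)
}

#' Draw one stochastic parameterisation of the model
#'
#' Every stochastic entry is drawn i.i.d. uniform from its configured
#' interval. The mutualistic strength matrices have the sparsity pattern of
#' the observed network: an entry is positive exactly where at least one
#' visit was recorded, and the two directions of a link (benefit to the
#' plant, benefit to the pollinator) are drawn independently. Observed
#' interaction frequencies set the topology only; they do not scale the
#' drawn strengths.
#'
#' @param net A preprocessed `interaction_network`.
#' @param cfg A [dynamics_config()].
#' @param seed Integer seed for this draw.
#' @return A `parameter_draw` list with growth-rate vectors (`alpha_P`,
#'   `alpha_A`), within-guild competition matrices (`B_P`, `B_A`),
#'   mutualistic-strength matrices (`Gamma_P`: plants x pollinators,
#'   `Gamma_A`: pollinators x plants), handling time `h`, and initial
#'   abundances (`S0_P`, `S0_A`).
#' @export
sample_parameters <- function(net, cfg = dynamics_config(), seed = cfg$seed) {
  n_p <- length(net$plant_ids)
  n_a <- length(net$pollinator_ids)
  if (n_p == 0 || n_a == 0) stop("empty guild; preprocess first", call. = FALSE)
  set.seed(seed)
  runif2 <- function(n, iv) runif(n, iv[1], iv[2])
  comp_matrix <- function(n) {
    b <- matrix(runif2(n * n, cfg$beta_inter_range), n, n)
    diag(b) <- runif2(n, cfg$beta_intra_range)
    b
  }
  mask <- (net$counts > 0) * 1
  gamma_p <- matrix(runif2(n_p * n_a, cfg$gamma_range), n_p, n_a) * mask
  gamma_a <- matrix(runif2(n_a * n_p, cfg$gamma_range), n_a, n_p) * t(mask)
  draw <- list(
    alpha_P = runif2(n_p, cfg$alpha_range),
    alpha_A = runif2(n_a, cfg$alpha_range),
    B_P = comp_matrix(n_p),
    B_A = comp_matrix(n_a),
    Gamma_P = gamma_p,
    Gamma_A = gamma_a,
    h = cfg$handling_time,
    S0_P = runif2(n_p, cfg$init_abundance_range),
    S0_A = runif2(n_a, cfg$init_abundance_range),
    n_p = n_p, n_a = n_a
  )
  class(draw) <- "parameter_draw"
  draw
}

#' Right-hand side of the coupled abundance ODEs
#'
#' For plant i: growth `alpha_i * S_i`, minus within-guild competition
#' `S_i * sum_j beta_ij S_j` (j over all plants, including i), plus the
#' saturating mutualistic benefit
#' `S_i * (sum_k gamma_ik S_k) / (1 + h * sum_l gamma_il S_l)` with k, l
#' over pollinators. The pollinator equations are the mirror image with the
#' guilds exchanged. The shared sum in numerator and denominator is the
#' type-II functional response: per-capita benefit saturates when partner
#' abundance is high.
#'
#' @param state Named or unnamed numeric vector: the `n_p` plant abundances
#'   followed by the `n_a` pollinator abundances.
#' @param draw A `parameter_draw`.
#' @return Numeric vector of derivatives in the same order.
#' @export
dynamics_rhs <- function(state, draw) {
  n_p <- draw$n_p
  if (length(state) != n_p + draw$n_a) {
    stop("state length does not match parameter draw", call. = FALSE)
  }
  s <- pmax(state, 0)
  s_p <- s[seq_len(n_p)]
  s_a <- s[n_p + seq_len(draw$n_a)]
  m_p <- drop(draw$Gamma_P %*% s_a)
  m_a <- drop(draw$Gamma_A %*% s_p)
  ds_p <- draw$alpha_P * s_p - s_p * drop(draw$B_P %*% s_p) +
    s_p * m_p / (1 + draw$h * m_p)
  ds_a <- draw$alpha_A * s_a - s_a * drop(draw$B_A %*% s_a) +
    s_a * m_a / (1 + draw$h * m_a)
  unname(c(ds_p, ds_a))
}

#' Integrate one parameter draw to its asymptotic state
#'
#' Integrates the coupled ODEs from the drawn initial abundances with
#' `deSolve::ode` (lsoda: adaptive, switches to an implicit method when the
#' system is stiff; rtol 1e-8, atol 1e-12, two orders below the extinction
#' threshold so threshold crossings are resolved rather than noise). If the
#' equilibrium tolerance is not met at `t_end` the horizon is doubled up to
#' `cfg$max_extensions` times; `settled = FALSE` flags trajectories still
#' moving at the final horizon. Small numerical negatives are clipped to 0.
#'
#' @param draw A `parameter_draw`.
#' @param cfg A [dynamics_config()].
#' @return A `trajectory_result` list: `final_P`, `final_A` (clipped final
#'   abundances), `extinct_P`, `extinct_A` (logical, final abundance below
#'   the extinction threshold), `settled`, `t_final`.
#' @export
integrate_dynamics <- function(draw, cfg = dynamics_config()) {
  ode_fun <- function(t, y, parms) list(dynamics_rhs(y, parms))
  y <- c(draw$S0_P, draw$S0_A)
  window <- cfg$t_end
  t_total <- 0
  for (k in 0:cfg$max_extensions) {
    sol <- deSolve::ode(y = y, times = c(0, window), func = ode_fun,
                        parms = draw, method = "lsoda",
                        rtol = 1e-8, atol = 1e-12)
    if (attr(sol, "istate")[1] < 0 || anyNA(sol[nrow(sol), -1])) {
      stop("ODE integration failed (istate ",
           attr(sol, "istate")[1], ")", call. = FALSE)
    }
    y_end <- sol[nrow(sol), -1]
    if (any(!is.finite(y_end))) stop("non-finite state", call. = FALSE)
    t_total <- t_total + window
    deriv <- dynamics_rhs(y_end, draw)
    settled <- max(abs(deriv)) < cfg$equilibrium_tol
    if (settled || k == cfg$max_extensions) break
    y <- pmax(y_end, 0)
    window <- t_total  # continuation doubles the total horizon
  }
  final <- unname(pmax(y_end, 0))
  n_p <- draw$n_p
  res <- list(final_P = final[seq_len(n_p)],
              final_A = final[n_p + seq_len(draw$n_a)],
              settled = settled,
              t_final = t_total)
  res$extinct_P = res$final_P < cfg$extinction_threshold
  res$extinct_A = res$final_A < cfg$extinction_threshold
  class(res) <- "trajectory_result"
  res
}

#' Estimate species and network persistence by replicate simulation
#'
#' Runs `cfg$n_runs` independent simulations of the network, redrawing all
#' model parameters and initial abundances each run from their configured
#' intervals. A species persists in a run when its final abundance density
#' is at or above the extinction threshold; its persistence is the fraction
#' of runs in which it persisted. Network-level persistence is the mean of
#' species persistences, overall and separately per guild. Per-run seeds are
#' derived deterministically from `cfg$seed` and the network identifier, so
#' the result is reproducible and independent of execution order.
#'
#' @param net A preprocessed `interaction_network`.
#' @param cfg A [dynamics_config()].
#' @return A `persistence_result` with `species` (tibble: `species_id`,
#'   `guild`, `persistence`), `network` (one-row tibble with mean
#'   persistence overall and per guild plus run accounting), and the
#'   resolved `cfg`.
#' @export
run_persistence <- function(net, cfg = dynamics_config()) {
  validate_network(net)
  id <- network_id(net)
  n_p <- length(net$plant_ids)
  n_a <- length(net$pollinator_ids)
  surv_p <- numeric(n_p)
  surv_a <- numeric(n_a)
  n_ok <- 0L
  n_unsettled <- 0L
  failures <- character(0)
  for (r in seq_len(cfg$n_runs)) {
    draw <- sample_parameters(net, cfg, seed = derive_seed(cfg$seed, id, r))
    traj <- tryCatch(integrate_dynamics(draw, cfg), error = function(e) e)
    if (inherits(traj, "error")) {
      failures <- c(failures, conditionMessage(traj))
      next
    }
    surv_p <- surv_p + !traj$extinct_P
    surv_a <- surv_a + !traj$extinct_A
    n_ok <- n_ok + 1L
    if (!traj$settled) n_unsettled <- n_unsettled + 1L
  }
  if (length(failures) > 0.05 * cfg$n_runs) {
    stop("more than 5% of runs failed to integrate for ", id, ": ",
         failures[1], call. = FALSE)
  }
  if (n_ok == 0) stop("no successful runs for ", id, call. = FALSE)
  species <- tibble::tibble(
    network_id = id,
    site = net$site_id,
    treatment = net$treatment,
    period = net$period,
    species_id = c(net$plant_ids, net$pollinator_ids),
    guild = c(rep("plant", n_p), rep("pollinator", n_a)),
    persistence = c(surv_p, surv_a) / n_ok
  )
  network <- tibble::tibble(
    network_id = id,
    site = net$site_id,
    treatment = net$treatment,
    period = net$period,
    persistence_all = mean(species$persistence),
    persistence_plants = mean(species$persistence[species$guild == "plant"]),
    persistence_pollinators =
      mean(species$persistence[species$guild == "pollinator"]),
    n_runs_ok = n_ok,
    n_runs_failed = length(failures),
    n_runs_unsettled = n_unsettled
  )
  structure(list(species = species, network = network, cfg = cfg),
            class = "persistence_result")
}

#' @export
print.persistence_result <- function(x, ...) {
  cat(sprintf("<persistence_result> %s: overall %.3f (plants %.3f, pollinators %.3f) over %d runs\n",
              x$network$network_id, x$network$persistence_all,
              x$network$persistence_plants, x$network$persistence_pollinators,
              x$network$n_runs_ok))
  invisible(x)
}

#' @export
tidy.persistence_result <- function(x, ...) x$species

#' @export
glance.persistence_result <- function(x, ...) x$network
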