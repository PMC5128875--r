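# Experiment orchestration: box construction at fixed concentration,
# temperature schedules (constant and alternating), and the fibrillization
# temperature scan.

AVOGADRO <- 6.02214076e23

#' Cubic box edge at a fixed molar concentration
#'
#' `L = (n_chains / (concentration * N_A))^(1/3)` expressed in Angstrom.
#' At 1 mM this reproduces the conventional edges, e.g. 237 A (rounded) for
#' 8 chains and 118 A for a single chain.
#'
#' @param n_chains Number of chains (>= 1).
#' @param concentration Molar concentration (mol/L, > 0).
#' @param round Round to the nearest integer Angstrom?
#' @return Box edge in Angstrom.
#' @examples
#' box_length(8, 1e-3)   # 237
#' box_length(1, 1e-3)   # 118
#' @export
box_length <- function(n_chains, concentration, round = TRUE) {
  if (any(n_chains < 1) || any(concentration <= 0)) {
    abort("n_chains must be >= 1 and concentration > 0")
  }
  litres <- n_chains / (concentration * AVOGADRO)
  L <- (litres * 1e27)^(1 / 3)   # 1 L = 1e27 A^3
  if (round) round(L) else L
}

#' Temperature schedule
#'
#' Constant or alternating thermostat target.  An alternating schedule
#' switches between `t1` and `t2` every `half_cycle` collisions; a constant
#' schedule is the degenerate case `t1 == t2`.
#'
#' @param kind `"constant"` or `"alternating"`.
#' @param t1,t2 Reduced temperatures (> 0).  For `kind = "constant"` only
#'   `t1` is used.
#' @param half_cycle Collisions per temperature segment (> 0).
#' @return A `temperature_schedule` list.
#' @export
temperature_schedule <- function(kind = c("constant", "alternating"),
                                 t1, t2 = t1, half_cycle = 5e9) {
  kind <- match.arg(kind)
  if (kind == "constant") t2 <- t1
  if (t1 <= 0 || t2 <= 0) abort("temperatures must be positive")
  if (half_cycle <= 0) abort("half_cycle must be positive")
  structure(list(kind = kind, t1 = t1, t2 = t2, half_cycle = half_cycle),
            class = "temperature_schedule")
}

#' Run configuration
#'
#' @param n_chains Chain count (>= 1).
#' @param concentration Molar concentration (mol/L).
#' @param budget Total collision budget (> 0).
#' @param seed RNG seed.
#' @param schedule A [temperature_schedule()].
#' @param snapshot_every Collisions between stored snapshots (0 = none).
#' @param observe_every Collisions between observable records.
#' @param kick_rate Thermostat kick rate per bead per reduced time.
#' @return A `run_config` list.
#' @export
run_config <- function(n_chains, concentration = 1e-3, budget = 1e6,
                       seed = 1L, schedule = temperature_schedule(
                         "constant", 0.2, half_cycle = budget),
                       snapshot_every = 0, observe_every = max(
                         1, round(budget / 200)), kick_rate = 0.05) {
  if (n_chains < 1 || concentration <= 0 || budget <= 0) {
    abort("invalid run configuration")
  }
  structure(list(n_chains = as.integer(n_chains),
                 concentration = concentration, budget = budget,
                 seed = as.integer(seed), schedule = schedule,
                 snapshot_every = snapshot_every,
                 observe_every = observe_every,
                 kick_rate = kick_rate),
            class = "run_config")
}

# thermostat targets per segment implied by a schedule and budget
schedule_segments <- function(schedule, budget) {
  h <- min(schedule$half_cycle, budget)
  n_seg <- ceiling(budget / h)
  starts <- (seq_len(n_seg) - 1) * h
  lens <- pmin(h, budget - starts)
  temps <- rep(c(schedule$t1, schedule$t2), length.out = n_seg)
  tibble(segment = seq_len(n_seg), start = starts, collisions = lens,
         temperature = temps)
}

#' Run a temperature schedule
#'
#' Simulates a run configuration: builds (or accepts) a random dilute
#' initial state, then advances the dynamics segment by segment with the
#' thermostat target following the schedule by collision count, recording
#' observables (total energy, kinetic temperature, hydrogen-bond count,
#' largest cluster) at the configured cadence.
#'
#' @param config A [run_config()].
#' @param table Interaction table.
#' @param state Optional initial `dmd_state` (default: random dilute
#'   configuration at the schedule's first temperature).
#' @param sequence Peptide sequence for the default initial state.
#' @return A `dmd_run`: list with `state` (final), `observables` (tibble),
#'   `snapshots` (list of bead tibbles), `segments`, `config`.
#' @export
run_schedule <- function(config, table = default_forcefield(),
                         state = NULL, sequence = ab1742_sequence()) {
  segs <- schedule_segments(config$schedule, config$budget)
  if (config$budget %% config$observe_every != 0) {
    warn("budget is not a multiple of the observation cadence; the last partial interval is recorded")
  }
  if (is.null(state)) {
    state <- make_random_config(config$n_chains, config$concentration,
                                seed = config$seed, sequence = sequence,
                                table = table,
                                temperature = segs$temperature[1])
  }
  obs <- list(); snaps <- list()
  for (k in seq_len(nrow(segs))) {
    seg_seed <- (config$seed * 48271 + k * 10007) %% 2147483629 + 1
    res <- dmd_advance(state, table,
                       n_collisions = segs$collisions[k],
                       temperature = segs$temperature[k],
                       kick_rate = config$kick_rate,
                       seed = seg_seed,
                       observe_every = config$observe_every,
                       snapshot_every = config$snapshot_every)
    state <- res$state
    o <- res$observables
    o$segment <- k
    o$target_temperature <- segs$temperature[k]
    obs[[k]] <- o
    snaps <- c(snaps, res$snapshots)
  }
  structure(list(state = state, observables = bind_rows(obs),
                 snapshots = snaps, segments = segs, config = config),
            class = "dmd_run")
}

#' @export
print.dmd_run <- function(x, ...) {
  cat("<dmd_run> ", x$config$n_chains, " chains, budget ",
      format(x$config$budget, big.mark = ","), " collisions, ",
      nrow(x$segments), " temperature segment(s)\n", sep = "")
  print(tail(x$observables, 3))
  invisible(x)
}

#' Reduced time
#'
#' Converts a physical time to the reduced unit
#' `t* = t * sqrt(k_B T / m) / sigma`.
#'
#' @param t Time.
#' @param sigma Reference length.
#' @param mass Reference mass.
#' @param temperature Reduced temperature (k_B T in energy units).
#' @return Reduced time `t*`.
#' @export
reduced_time <- function(t, sigma, mass, temperature) {
  if (sigma <= 0 || mass <= 0 || temperature <= 0) {
    abort("sigma, mass and temperature must be positive")
  }
  t * sqrt(temperature / mass) / sigma
}

#' Scan for the fibrillization temperature
#'
#' Runs the same configuration over a temperature grid and locates the
#' boundary between runs that satisfy a fibril criterion and runs that do
#' not (the temperature above which ordered aggregates cease to form).
#' Desk-scale use is intended for toy systems; the scan is embarrassingly
#' expensive for realistic budgets.
#'
#' @param temperatures Increasing vector of reduced temperatures.
#' @param criterion Function taking a `dmd_run` and returning `TRUE` when
#'   the run formed the target structure.
#' @param config_fn Function taking a temperature and returning a
#'   [run_config()].
#' @param table Interaction table.
#' @param state_fn Optional function (temperature -> initial state).
#' @return A list: `t_f` (boundary estimate, `NA` when undefined),
#'   `defined`, `flag` (`"ok"`, `"above_grid"`, `"below_grid"`), and the
#'   per-temperature `results` tibble.
#' @export
scan_fibrillization <- function(temperatures, criterion, config_fn,
                                table = default_forcefield(),
                                state_fn = NULL) {
  temperatures <- sort(temperatures)
  hits <- logical(length(temperatures))
  for (k in seq_along(temperatures)) {
    cfg <- config_fn(temperatures[k])
    st <- if (is.null(state_fn)) NULL else state_fn(temperatures[k])
    run <- run_schedule(cfg, table = table, state = st)
    hits[k] <- isTRUE(criterion(run))
  }
  results <- tibble(temperature = temperatures, fibril = hits)
  if (all(hits)) {
    return(list(t_f = NA_real_, defined = FALSE, flag = "above_grid",
                results = results))
  }
  if (!any(hits)) {
    return(list(t_f = NA_real_, defined = FALSE, flag = "below_grid",
                results = results))
  }
  last_true <- max(which(hits))
  nxt <- if (last_true < length(hits)) last_true + 1L else last_true
  list(t_f = mean(temperatures[c(last_true, nxt)]), defined = TRUE,
       flag = "ok", results = results)
}
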