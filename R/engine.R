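# R surface of the event-driven dynamics core.

kind_code <- function(kind) {
  match(kind, BEAD_KINDS) - 1L
}

aa_code <- function(aa) {
  match(aa, AA_CODES) - 1L
}

#' Advance a simulation state by a collision budget
#'
#' Runs the event-driven dynamics for exactly `n_collisions`
#' velocity-changing pair events (hard-core collisions, bond-wall
#' reflections, well crossings and bounces, hydrogen-bond events).
#' Thermostat ghost kicks and neighbour-list rebuilds are not counted.
#' Between ghost kicks total energy is conserved exactly; under a fixed seed
#' the trajectory is bit-reproducible.
#'
#' @param state A `dmd_state` (see [make_random_config()],
#'   [new_dmd_state()]).
#' @param table An `interaction_table`.
#' @param n_collisions Number of pair events to resolve (>= 0).
#' @param temperature Thermostat target T* (ignored when `kick_rate = 0`).
#' @param kick_rate Andersen ghost-kick rate per bead per reduced time;
#'   0 switches the thermostat off.
#' @param seed Engine RNG seed.
#' @param observe_every Collisions between observable records (0 = none).
#' @param snapshot_every Collisions between stored snapshots (0 = none).
#' @param contact_cut,min_contacts Inter-chain contact definition used for
#'   the largest-cluster observable.
#' @param skin Neighbour-list skin in Angstrom.
#' @param chirality_margin Chirality-wall position as a fraction of each
#'   residue's ideal signed volume.
#' @return A list: `state` (advanced `dmd_state`), `observables` (tibble),
#'   `snapshots` (list of bead tibbles with `time`, `collisions`, `pe`
#'   attributes), `counts` (named event tally), `pe`, `ke`.
#' @export
dmd_advance <- function(state, table = default_forcefield(),
                        n_collisions, temperature = 0.2, kick_rate = 0.05,
                        seed = 1L, observe_every = 0, snapshot_every = 0,
                        contact_cut = 6.5, min_contacts = 3, skin = 3,
                        chirality_margin = 0.25) {
  beads <- state$beads
  topo <- state$topology
  n <- nrow(beads)
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  vel <- as.matrix(beads[, c("vx", "vy", "vz")])
  box <- if (is.finite(state$box)) state$box else 1e6
  hbp <- rep(-1L, n)
  if (nrow(state$hb) > 0) {
    hbp[state$hb$nh] <- state$hb$co - 1L
    hbp[state$hb$co] <- state$hb$nh - 1L
  }
  w2d <- table$sc_wells$depth2
  w2r <- table$sc_wells$range2
  # chirality walls: one per side-chain residue, at a fraction of the
  # ideal signed volume, on the side of the current handedness
  chir <- topo$chirality
  if (nrow(chir) > 0) {
    fr <- residue_frame()
    cross_norm <- vnorm(vcross(fr$nh, fr$co))
    ideal <- cross_norm * table$sc_ca_dist[beads$aa[chir$sc]] *
      sin(table$sc_alpha)
    det0 <- chirality_volumes(beads, topo)$volume
    chir_m <- as.matrix(chir[, c("nh", "ca", "co", "sc")]) - 1L
    chir_margin <- sign(det0) * chirality_margin * ideal
  } else {
    chir_m <- matrix(integer(0), 0, 4)
    chir_margin <- numeric(0)
  }
  res <- cpp_dmd_run(
    xyz, vel,
    as.integer(beads$chain), as.integer(beads$residue),
    kind_code(beads$bead), aa_code(beads$aa),
    rep(table$mass, length.out = n),
    as.matrix(topo$bonds[, c("a", "b")]) - 1L,
    topo$bonds$length * (1 - topo$bonds$delta),
    topo$bonds$length * (1 + topo$bonds$delta),
    box,
    unname(table$bead_diameters[BEAD_KINDS[1:3]]),
    unname(table$sc_diameters[AA_CODES]),
    as.numeric(table$sc_wells$depth), as.numeric(table$sc_wells$range),
    if (is.null(w2d)) numeric(0) else as.numeric(w2d),
    if (is.null(w2r)) numeric(0) else as.numeric(w2r),
    table$squeeze_factor,
    table$hb_core, table$hb_range, table$eps_hb,
    table$hb_aux_min, table$hb_min_seq_sep,
    isTRUE(table$parallel_preference), cos(table$parallel_threshold),
    table$salt_bridge$res_a, aa_code(table$salt_bridge$aa_a),
    table$salt_bridge$res_b, aa_code(table$salt_bridge$aa_b),
    table$salt_bridge$factor,
    hbp,
    chir_m, chir_margin,
    n_collisions, temperature, kick_rate, as.numeric(seed),
    observe_every, snapshot_every,
    contact_cut, as.integer(min_contacts), skin)
  if (nzchar(res$error)) {
    abort(paste0("dmd engine: ", res$error), class = "fibril_engine_error")
  }
  beads$x <- res$pos[, 1]; beads$y <- res$pos[, 2]; beads$z <- res$pos[, 3]
  beads$vx <- res$vel[, 1]; beads$vy <- res$vel[, 2]
  beads$vz <- res$vel[, 3]
  hbp <- res$hb_partner
  nh_side <- which(hbp >= 0 & kind_code(beads$bead) == 0L)
  hb <- tibble(nh = nh_side, co = hbp[nh_side] + 1L)
  new_state <- new_dmd_state(beads, box = state$box, topology = topo,
                             time = state$time + res$time,
                             collisions = state$collisions + res$collisions,
                             hb = hb)
  obs <- as_tibble(res$observables)
  if (nrow(obs) > 0) {
    obs$collisions <- obs$collisions + state$collisions
    obs$time <- obs$time + state$time
  }
  snaps <- list()
  if (length(res$snapshots) > 0) {
    for (k in seq_along(res$snapshots)) {
      sb <- beads[, c("index", "chain", "residue", "bead", "aa")]
      sb$x <- res$snapshots[[k]][, 1]
      sb$y <- res$snapshots[[k]][, 2]
      sb$z <- res$snapshots[[k]][, 3]
      attr(sb, "time") <- res$snapshot_time[k] + state$time
      attr(sb, "collisions") <- res$snapshot_collisions[k] +
        state$collisions
      attr(sb, "pe") <- res$snapshot_pe[k]
      snaps[[k]] <- sb
    }
  }
  counts <- res$counts[order(names(res$counts))]
  list(state = new_state, observables = obs, snapshots = snaps,
       counts = counts, pe = res$pe, ke = res$ke)
}

#' Time to the next crossing of a pair discontinuity
#'
#' Smallest positive root of `|dr + dv t| = radius` under the cubic minimum
#' image, for the pair's current relative position and velocity, or `NA`
#' when the discontinuity is unreachable.
#'
#' @param state A `dmd_state`.
#' @param a,b Bead indices.
#' @param radius Discontinuity radius (Angstrom).
#' @return Reduced time (scalar), or `NA_real_` when unreachable.
#' @export
next_event_time <- function(state, a, b, radius) {
  beads <- state$beads
  dr <- c(beads$x[a] - beads$x[b], beads$y[a] - beads$y[b],
          beads$z[a] - beads$z[b])
  if (is.finite(state$box)) {
    dr <- dr - state$box * round(dr / state$box)
  }
  dv <- c(beads$vx[a] - beads$vx[b], beads$vy[a] - beads$vy[b],
          beads$vz[a] - beads$vz[b])
  inside <- sqrt(sum(dr^2)) < radius
  t <- cpp_pair_time(dr, dv, radius, inside)
  if (is.finite(t)) t else NA_real_
}

#' Resample a bead velocity from the thermostat
#'
#' Andersen-style ghost collision: the bead's velocity is redrawn from the
#' Maxwell-Boltzmann distribution at the target reduced temperature (each
#' component Normal with variance `T*/m`); every other bead is untouched.
#' Uses R's RNG, so the kick sequence is reproducible under [set.seed()].
#'
#' @param state A `dmd_state`.
#' @param bead Bead index.
#' @param temperature Reduced temperature (>= 0).
#' @param mass Bead mass.
#' @return The state with the bead's velocity resampled.
#' @export
ghost_kick <- function(state, bead, temperature, mass = 1) {
  if (temperature < 0) abort("temperature must be >= 0")
  sdv <- sqrt(temperature / mass)
  v <- if (sdv > 0) rnorm(3, 0, sdv) else c(0, 0, 0)
  state$beads$vx[bead] <- v[1]
  state$beads$vy[bead] <- v[2]
  state$beads$vz[bead] <- v[3]
  state
}

#' Instantaneous kinetic temperature
#'
#' `T* = 2 KE / (3 N)` in reduced units (k_B = 1), with
#' `KE = sum m v^2 / 2`.
#'
#' @param state A `dmd_state`.
#' @param mass Bead mass (scalar or per-bead vector).
#' @return Reduced kinetic temperature.
#' @export
kinetic_temperature <- function(state, mass = 1) {
  b <- state$beads
  ke <- 0.5 * sum(mass * (b$vx^2 + b$vy^2 + b$vz^2))
  2 * ke / (3 * nrow(b))
}
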