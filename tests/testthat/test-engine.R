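# Event-driven dynamics core: event timing, impulse rules, conservation,
# thermostat moments, determinism, constraint integrity.

test_that("next event time matches closed-form and fine-step kinematics", {
  st <- two_bead_state(d = 10, v = 1)   # head-on, closing speed 2
  expect_equal(next_event_time(st, 1, 2, 4), 3)
  # receding pair beyond all ranges: unreachable
  st$beads$vx <- c(-1, 1)
  expect_true(is.na(next_event_time(st, 1, 2, 4)))
  # oblique approaches agree with a brute-force fine-step integrator
  set.seed(71)
  for (k in 1:25) {
    dr <- runif(3, -8, 8)
    dr <- dr / sqrt(sum(dr^2)) * runif(1, 5, 9)
    dv <- rnorm(3, 0, 0.7)
    st <- two_bead_state(d = 5)
    st$beads[1, c("x", "y", "z")] <- as.list(dr)
    st$beads[2, c("x", "y", "z")] <- list(0, 0, 0)
    st$beads[1, c("vx", "vy", "vz")] <- as.list(dv)
    st$beads[2, c("vx", "vy", "vz")] <- list(0, 0, 0)
    t_engine <- next_event_time(st, 1, 2, 4)
    t_oracle <- oracle_crossing_time(dr, dv, 4)
    if (is.na(t_oracle)) {
      expect_true(is.na(t_engine) || t_engine > 50)
    } else {
      expect_equal(t_engine, t_oracle, tolerance = 1e-6)
    }
  }
})

test_that("equal-mass head-on core collision exchanges velocities", {
  tab <- two_bead_table()
  st <- two_bead_state(d = 4.5, v = 0.5, table = tab)  # inside the well
  r <- dmd_advance(st, tab, n_collisions = 1, kick_rate = 0, seed = 1)
  expect_equal(r$state$beads$vx, c(-0.5, 0.5))
  expect_equal(r$state$beads$vy, c(0, 0))
})

test_that("insufficient escape energy reflects at the outer wall", {
  tab <- two_bead_table(eps = 1)
  # bound pair, small kinetic energy: every outer-wall attempt bounces
  st <- two_bead_state(d = 5, v = 0.2, table = tab)
  st$beads$vx <- c(-0.2, 0.2)  # receding inside the well
  r <- dmd_advance(st, tab, n_collisions = 1, kick_rate = 0, seed = 1)
  expect_equal(unname(r$counts["bounce"]), 1)
  expect_equal(r$state$beads$vx, c(0.2, -0.2))
})

test_that("well capture converts potential into kinetic energy exactly", {
  tab <- two_bead_table(eps = 1)
  set.seed(5)
  for (k in 1:50) {
    # random approach geometry outside the well
    dirv <- rnorm(3); dirv <- dirv / sqrt(sum(dirv^2))
    st <- two_bead_state(d = 8, v = 0, table = tab)
    st$beads[2, c("x", "y", "z")] <- as.list(8 * dirv)
    v <- -dirv * runif(1, 0.3, 1) + rnorm(3, 0, 0.2)
    st$beads[2, c("vx", "vy", "vz")] <- as.list(v)
    e0 <- total_ke(st)   # potential zero outside
    r <- dmd_advance(st, tab, n_collisions = 1, kick_rate = 0, seed = k)
    e1 <- total_ke(r$state) + r$pe
    expect_lt(abs(e1 - e0), 1e-12)
  }
})

test_that("a bound pair conserves energy over many events", {
  tab <- two_bead_table(eps = 1)
  st <- two_bead_state(d = 4.5, v = 0.6, table = tab)
  e0 <- total_ke(st) - 1   # inside the well
  r <- dmd_advance(st, tab, n_collisions = 1e4, kick_rate = 0, seed = 5)
  expect_lt(abs(total_ke(r$state) + r$pe - e0), 1e-8)
})

test_that("momentum is conserved across pair events", {
  tab <- two_bead_table(eps = 1)
  st <- two_bead_state(d = 4.5, v = 0.6, table = tab)
  st$beads$vy <- c(0.3, -0.1)
  p0 <- colSums(as.matrix(st$beads[, c("vx", "vy", "vz")]))
  r <- dmd_advance(st, tab, n_collisions = 500, kick_rate = 0, seed = 2)
  p1 <- colSums(as.matrix(r$state$beads[, c("vx", "vy", "vz")]))
  expect_equal(p1, p0, tolerance = 1e-12)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  tab <- default_forcefield()
  st <- make_random_config(2, 1e-3, seed = 9, sequence = "KLVFFAE",
                           first_residue = 16L)
  r1 <- dmd_advance(st, tab, 5000, temperature = 0.25, kick_rate = 0.1,
                    seed = 7)
  r2 <- dmd_advance(st, tab, 5000, temperature = 0.25, kick_rate = 0.1,
                    seed = 7)
  expect_identical(r1$state$beads, r2$state$beads)
  expect_identical(r1$pe, r2$pe)
})

test_that("zero-collision advances leave the configuration unchanged", {
  tab <- two_bead_table()
  st <- two_bead_state(d = 8, v = 0.1, table = tab)
  r <- dmd_advance(st, tab, n_collisions = 0, kick_rate = 0, seed = 1)
  expect_equal(r$state$beads$x, st$beads$x)
  expect_equal(r$state$collisions, 0)
})

test_that("ghost kicks resample Maxwell-Boltzmann components", {
  st <- two_bead_state(d = 8)
  set.seed(42)
  temperature <- 0.2
  vs <- replicate(3e4, {
    s <- ghost_kick(st, 1, temperature)
    s$beads$vx[1]
  })
  se <- sqrt(temperature / length(vs))
  expect_lt(abs(mean(vs)), 3 * se)
  se_var <- temperature * sqrt(2 / (length(vs) - 1))
  expect_lt(abs(var(vs) - temperature), 3 * se_var)
  # zero temperature is the zero-velocity limit
  s0 <- ghost_kick(st, 1, 0)
  expect_equal(unlist(s0$beads[1, c("vx", "vy", "vz")]),
               c(vx = 0, vy = 0, vz = 0))
  # fixed seed reproduces the kick sequence
  set.seed(11); k1 <- ghost_kick(st, 1, 0.3)$beads$vx[1]
  set.seed(11); k2 <- ghost_kick(st, 1, 0.3)$beads$vx[1]
  expect_identical(k1, k2)
})

test_that("kinetic temperature is the quadratic velocity form", {
  st <- two_bead_state(d = 8, v = 0)
  expect_equal(kinetic_temperature(st), 0)
  st$beads$vx <- c(1, -1); st$beads$vy <- c(0.5, 0)
  t1 <- kinetic_temperature(st)
  st2 <- st
  st2$beads[, c("vx", "vy", "vz")] <- st$beads[, c("vx", "vy", "vz")] * 3
  expect_equal(kinetic_temperature(st2), 9 * t1)
})

test_that("multi-chain dynamics keep every hard constraint intact", {
  tab <- default_forcefield()
  st <- make_random_config(2, 1e-3, seed = 21, sequence = "KLVFFAE",
                           first_residue = 16L)
  topo <- st$topology
  r <- dmd_advance(st, tab, n_collisions = 3e4, temperature = 0.25,
                   kick_rate = 0.1, seed = 4)
  viol <- check_constraints(r$state, topo, tab, box = st$box)
  expect_equal(nrow(viol), 0)
})

test_that("L-isomer handedness is preserved along trajectories", {
  tab <- default_forcefield()
  st <- make_random_config(2, 1e-3, seed = 11)
  topo <- st$topology
  s0 <- sign(chirality_volumes(st$beads, topo)$volume)
  r <- dmd_advance(st, tab, n_collisions = 1e5, temperature = 0.3,
                   kick_rate = 0.1, seed = 3)
  s1 <- sign(chirality_volumes(r$state$beads, topo)$volume)
  expect_identical(s1, s0)
})
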