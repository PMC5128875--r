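# Box construction, temperature schedules, reduced time and the
# fibrillization-temperature scan.

test_that("box edges reproduce the conventional 1 mM values", {
  expect_equal(box_length(8, 1e-3), 237)
  expect_equal(box_length(1, 1e-3), 118)
  # volume scales linearly with chain count before rounding
  expect_equal(box_length(64, 1e-3, round = FALSE),
               2 * box_length(8, 1e-3, round = FALSE))
})

test_that("box length is monotone in chains and concentration", {
  L <- box_length(1:12, 1e-3, round = FALSE)
  expect_true(all(diff(L) > 0))
  expect_lt(box_length(4, 2e-3, round = FALSE),
            box_length(4, 1e-3, round = FALSE))
  expect_equal(box_length(1:12, 1e-3, round = FALSE) /
                 box_length(1, 1e-3, round = FALSE),
               (1:12)^(1 / 3))
  expect_error(box_length(0, 1e-3))
  expect_error(box_length(2, -1))
})

test_that("reduced time follows t sqrt(kT/m)/sigma", {
  expect_equal(reduced_time(0, 3.8, 1, 0.2), 0)
  t1 <- reduced_time(5, 3.8, 1, 0.2)
  expect_equal(reduced_time(5, 7.6, 1, 0.2), t1 / 2)
  expect_equal(reduced_time(5, 3.8, 1, 0.8), 2 * t1)
  expect_error(reduced_time(1, -1, 1, 0.2))
})

test_that("schedules validate and enumerate segments correctly", {
  sch <- temperature_schedule("alternating", 0.206, 0.20, half_cycle = 100)
  segs <- fibrildmd:::schedule_segments(sch, 400)
  # thermostat target changes exactly 3 times, at collisions H, 2H, 3H
  expect_equal(nrow(segs), 4)
  expect_equal(segs$start, c(0, 100, 200, 300))
  expect_equal(segs$temperature, c(0.206, 0.20, 0.206, 0.20))
  expect_equal(sum(segs$temperature[-1] != segs$temperature[-4]), 3)
  # constant schedule is the degenerate alternating case
  expect_equal(temperature_schedule("constant", 0.2)$t2, 0.2)
  expect_error(temperature_schedule("alternating", -0.1, 0.2))
})

test_that("a constant run equals an alternating run with equal targets", {
  cfg1 <- run_config(1, budget = 4000, seed = 31,
                     schedule = temperature_schedule("constant", 0.22,
                                                    half_cycle = 1000),
                     observe_every = 1000, kick_rate = 0.2)
  cfg2 <- run_config(1, budget = 4000, seed = 31,
                     schedule = temperature_schedule("alternating", 0.22,
                                                    0.22,
                                                    half_cycle = 1000),
                     observe_every = 1000, kick_rate = 0.2)
  r1 <- run_schedule(cfg1, sequence = "KLVFFAE")
  r2 <- run_schedule(cfg2, sequence = "KLVFFAE")
  expect_identical(r1$state$beads, r2$state$beads)
})

test_that("alternating targets produce two kinetic-temperature plateaus", {
  cfg <- run_config(1, budget = 2e5, seed = 5,
                    schedule = temperature_schedule("alternating",
                                                    0.3, 0.2,
                                                    half_cycle = 5e4),
                    observe_every = 5e3, kick_rate = 0.5)
  r <- run_schedule(cfg, sequence = ab1742_sequence())
  o <- r$observables
  # drop the first record of each segment (relaxation into the new target)
  keep <- o |>
    dplyr::group_by(segment) |>
    dplyr::filter(dplyr::row_number() > 2) |>
    dplyr::ungroup()
  plateau <- keep |>
    dplyr::group_by(.data$target_temperature) |>
    dplyr::summarise(t_avg = mean(.data$t_avg))
  expect_equal(plateau$t_avg, plateau$target_temperature, tolerance = 0.02)
})

test_that("run bookkeeping matches the budget/cadence arithmetic", {
  cfg <- run_config(1, budget = 6000, seed = 2, observe_every = 1500,
                    kick_rate = 0.2)
  r <- run_schedule(cfg, sequence = "KLVFFAE")
  expect_equal(r$state$collisions, 6000)
  expect_equal(nrow(r$observables), 4)
  expect_equal(r$observables$collisions, c(1500, 3000, 4500, 6000))
})

test_that("the temperature scan brackets a toy binding crossover", {
  # two-bead square-well system: "fibril" criterion = mostly bound.
  tab <- two_bead_table(eps = 1, lambda = 1.5, sigma = 4)
  box <- 18
  crit_fraction <- function(temperature) {
    st <- two_bead_state(d = 4.5, v = sqrt(temperature), box = box,
                         table = tab)
    r <- dmd_advance(st, tab, n_collisions = 6000,
                     temperature = temperature,
                     kick_rate = 0.5, seed = round(1000 * temperature),
                     observe_every = 200)
    # time-weighted bound fraction (event-time sampling is biased)
    o <- r$observables
    dt <- diff(c(0, o$time))
    sum(-o$pe_avg * dt) / sum(dt)
  }
  temps <- c(0.25, 0.35, 0.7, 1.2, 2.5)
  hits <- vapply(temps, function(tt) crit_fraction(tt) > 0.5, logical(1))
  # analytic crossover: bound fraction = 1/2
  f <- function(tt) analytic_bound_fraction(1, 4, 1.5, box, tt) - 0.5
  t_half <- uniroot(f, c(0.2, 5))$root
  expect_true(any(hits) && !all(hits))
  last_true <- max(which(hits))
  bracket <- temps[c(last_true, min(last_true + 1, length(temps)))]
  # the bracketing pair straddles the analytic crossover
  expect_lt(abs(mean(bracket) - t_half), diff(bracket) / 2 + 0.1)
  # flag semantics on degenerate grids
  res <- scan_fibrillization(
    c(0.1, 0.2), function(run) FALSE,
    function(tt) run_config(1, budget = 50, seed = 1, kick_rate = 0.2))
  expect_false(res$defined)
  expect_equal(res$flag, "below_grid")
})
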