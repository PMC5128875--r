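# Force-field module: topology arity, parameter tables, step potentials,
# hydrogen-bond eligibility, salt-bridge enhancement, static energy.

test_that("peptide topology has the four-sphere arity with glycine at three", {
  top <- build_peptide(ab1742_sequence(), 1, first_residue = 17)
  expect_equal(nchar(top$sequence), 26)
  expect_equal(length(unique(top$beads$residue)), 26)
  # 26 x 4 beads minus the 5 glycines (25, 29, 33, 37, 38) with no SC bead
  expect_equal(nrow(top$beads), 99)
  gly <- top$beads[top$beads$aa == "G", ]
  expect_setequal(unique(gly$residue), c(25, 29, 33, 37, 38))
  expect_false(any(gly$bead == "SC"))
  # chirality quadruples for every residue carrying a side chain
  expect_equal(nrow(top$chirality), 21)
  # multi-chain replication
  top3 <- build_peptide(ab1742_sequence(), 3, first_residue = 17)
  expect_equal(nrow(top3$beads), 3 * 99)
  expect_equal(nrow(top3$bonds), 3 * nrow(top$bonds))
})

test_that("invalid sequences and chain counts are rejected", {
  expect_error(build_peptide("", 1), class = "fibril_invalid_sequence")
  expect_error(build_peptide("AXZ", 1), class = "fibril_invalid_sequence")
  expect_error(build_peptide("AVA", 0))
})

test_that("all bond lengths are positive with tolerances in range", {
  top <- build_peptide(ab1742_sequence(), 1)
  expect_true(all(top$bonds$length > 0))
  expect_true(all(top$bonds$delta > 0 & top$bonds$delta < 0.1))
})

test_that("the shipped default table loads and validates", {
  tab <- default_forcefield()
  expect_s3_class(tab, "interaction_table")
  expect_equal(tab$eps_hb, 1)
  expect_true(all(abs(tab$sc_wells$depth - t(tab$sc_wells$depth)) < 1e-12))
  sig <- outer(tab$sc_diameters, tab$sc_diameters, function(a, b) (a + b) / 2)
  expect_true(all(tab$sc_wells$range > sig))
})

test_that("table validation names the offending pair", {
  tab <- default_forcefield()
  tab$sc_wells$range["F", "W"] <- 1.0
  tab$sc_wells$range["W", "F"] <- 1.0
  expect_error(validate_forcefield(tab), "F-W|W-F")
  tab <- default_forcefield()
  tab$sc_wells$depth["A", "C"] <- 99
  expect_error(validate_forcefield(tab), "not symmetric")
})

test_that("write-then-load round-trips the table exactly", {
  tab <- default_forcefield()
  dir <- withr::local_tempdir()
  write_forcefield(tab, dir)
  tab2 <- load_forcefield(file.path(dir, "geometry.yaml"),
                          file.path(dir, "wells.yaml"))
  expect_equal(tab2, tab)
})

test_that("pair step potential follows square-well semantics", {
  tab <- default_forcefield()
  sc <- function(aa, res, chain = 1) list(kind = "SC", aa = aa,
                                          residue = res, chain = chain)
  # inside the well: -depth; radii strictly increasing
  rng <- tab$sc_wells$range["L", "V"]
  core <- (tab$sc_diameters["L"] + tab$sc_diameters["V"]) / 2
  p <- pair_step_potential(sc("L", 17, 1), sc("V", 18, 2), rng - 0.1, tab)
  expect_equal(p$energy, -tab$sc_wells$depth["L", "V"], ignore_attr = TRUE)
  expect_true(all(diff(p$radii) > 0))
  # beyond all ranges: zero with no remaining outward discontinuities
  p <- pair_step_potential(sc("L", 17, 1), sc("V", 18, 2), rng + 5, tab)
  expect_equal(p$energy, 0)
  expect_length(p$radii, 0)
  # below the squeeze distance: forbidden
  bb <- list(kind = "CA", aa = "L", residue = 18, chain = 1)
  sq <- tab$squeeze_factor *
    (tab$sc_diameters["L"] + tab$bead_diameters["CA"]) / 2
  p <- pair_step_potential(sc("L", 17, 1), bb, sq - 0.05, tab)
  expect_identical(p$energy, Inf)
  # bonded pair inside the walls: zero energy, outer wall ahead
  p <- pair_step_potential(bb, sc("L", 18, 1), 2.6, tab, bonded = 2.6)
  expect_equal(p$energy, 0)
})

test_that("effective well depth applies kappa only to the salt bridge", {
  tab <- default_forcefield()
  base <- tab$sc_wells$depth["D", "K"]
  expect_equal(effective_well_depth("D", 23, "K", 28, tab),
               tab$salt_bridge$factor * base, ignore_attr = TRUE)
  tab1 <- tab
  tab1$salt_bridge$factor <- 1
  expect_equal(effective_well_depth("D", 23, "K", 28, tab1), base,
               ignore_attr = TRUE)
  # same amino acids at other positions stay unenhanced
  expect_equal(effective_well_depth("D", 24, "K", 28, tab),
               base, ignore_attr = TRUE)
  expect_equal(effective_well_depth("L", 17, "V", 18, tab),
               tab$sc_wells$depth["L", "V"], ignore_attr = TRUE)
})

test_that("hydrogen-bond eligibility enforces the directional criteria", {
  tab <- default_forcefield()
  u2 <- make_fibril("U", 2)
  topo <- attr(u2, "topology")
  hb <- assign_hbonds(u2, topo, tab)
  expect_gt(nrow(hb), 0)
  k <- which(hb$chain_nh != hb$chain_co)[1]
  expect_true(hb_eligible(u2, topo, hb$nh[k], hb$co[k], tab))
  # occupancy blocks a second bond on the same bead
  expect_false(hb_eligible(u2, topo, hb$nh[k], hb$co[k], tab,
                           occupied = hb$nh[k]))
  # wrong bead kinds are a domain error
  ca <- u2$index[u2$bead == "CA"][1]
  expect_error(hb_eligible(u2, topo, ca, hb$co[k], tab), "NH bead")
  # same-chain pairs closer than the sequence exclusion are ineligible
  beads <- u2
  nh20 <- beads$index[beads$bead == "NH" & beads$residue == 20 &
                        beads$chain == 1]
  co18 <- beads$index[beads$bead == "CO" & beads$residue == 18 &
                        beads$chain == 1]
  expect_false(hb_eligible(u2, topo, nh20, co18, tab))
})

test_that("antiparallel strands are rejected when the parallel bias is on", {
  tab <- default_forcefield()
  u1 <- make_fibril("U", 1)
  topo1 <- attr(u1, "topology")
  # second chain rotated 180 degrees about the z axis: antiparallel strands
  u2 <- u1
  u2$chain <- 2L
  u2 <- fibrildmd:::transform_structure(
    u2, rot = fibrildmd:::rotation_z(pi), shift = c(25, 10, 2))
  comb <- dplyr::bind_rows(u1, u2)
  comb$index <- seq_len(nrow(comb))
  topo <- build_peptide(ab1742_sequence(), 2, 17L, tab)
  beads <- comb
  nh <- beads$index[beads$bead == "NH" & beads$chain == 2 &
                      beads$residue == 20]
  co <- beads$index[beads$bead == "CO" & beads$chain == 1 &
                      beads$residue == 20]
  # force the distance criterion to be the only difference: move chain 2 so
  # this NH sits inside the HB range of the chain-1 CO
  target <- unlist(beads[beads$index == co, c("x", "y", "z")]) + c(0, 0, 4)
  cur <- unlist(beads[beads$index == nh, c("x", "y", "z")])
  beads[beads$chain == 2, c("x", "y", "z")] <-
    beads[beads$chain == 2, c("x", "y", "z")] +
    matrix(target - cur, sum(beads$chain == 2), 3, byrow = TRUE)
  expect_false(hb_eligible(beads, topo, nh, co, tab))
  tab_off <- tab
  tab_off$parallel_preference <- FALSE
  res <- hb_eligible(beads, topo, nh, co, tab_off)
  expect_type(res, "logical")
})

test_that("total energy matches the brute-force contact enumeration", {
  tab <- default_forcefield()
  u <- make_fibril("U", 3)
  topo <- attr(u, "topology")
  hb <- assign_hbonds(u, topo, tab)
  expect_equal(total_energy(u, topo, tab, hbonds = hb),
               oracle_energy(u, tab, hb))
  # dilute configuration: all pairs beyond range
  far <- make_coil(2, seed = 4, spacing = 120)
  topo2 <- attr(far, "topology")
  hb2 <- assign_hbonds(far, topo2, tab)
  inter <- hb2[hb2$chain_nh != hb2$chain_co, ]
  expect_equal(nrow(inter), 0)
})

test_that("energy is invariant under rigid transforms", {
  tab <- default_forcefield()
  u <- make_fibril("U", 3)
  topo <- attr(u, "topology")
  e0 <- total_energy(u, topo, tab)
  rot <- fibrildmd:::random_rotation()
  u2 <- fibrildmd:::transform_structure(u, rot = rot, shift = c(11, -7, 3))
  expect_lt(abs(total_energy(u2, topo, tab) - e0), 1e-9)
})

test_that("kappa = 1 with the bias off reduces to the unenhanced table", {
  tab <- default_forcefield()
  tab0 <- tab
  tab0$salt_bridge$factor <- 1
  u <- make_fibril("U", 2, table = tab)
  topo <- attr(u, "topology")
  hb <- assign_hbonds(u, topo, tab)
  e_enh <- total_energy(u, topo, tab, hbonds = hb)
  e_base <- total_energy(u, topo, tab0, hbonds = hb)
  # the difference is exactly the extra salt-bridge well depth
  n_sb <- {
    sc <- u[u$bead == "SC" & u$residue %in% c(23, 28), ]
    cnt <- 0
    for (c1 in unique(sc$chain)) for (c2 in unique(sc$chain)) {
      a <- sc[sc$chain == c1 & sc$residue == 23, ]
      b <- sc[sc$chain == c2 & sc$residue == 28, ]
      if (nrow(a) && nrow(b)) {
        d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
        if (d <= tab$sc_wells$range["D", "K"]) cnt <- cnt + 1
      }
    }
    cnt
  }
  expect_equal(e_enh - e_base,
               -(tab$salt_bridge$factor - 1) * tab$sc_wells$depth["D", "K"] *
                 n_sb, ignore_attr = TRUE)
})

test_that("step potentials are consistent with the total energy", {
  # summing per-pair step levels at actual separations reproduces
  # total_energy on a fixture whose HB assignment is unambiguous
  tab <- default_forcefield()
  u <- make_fibril("U", 2)
  topo <- attr(u, "topology")
  hb <- assign_hbonds(u, topo, tab)
  xyz <- as.matrix(u[, c("x", "y", "z")])
  sc <- u[u$bead == "SC", ]
  esum <- 0
  for (i in seq_len(nrow(sc) - 1)) {
    for (j in (i + 1):nrow(sc)) {
      a <- sc[i, ]; b <- sc[j, ]
      if (a$chain == b$chain && abs(a$residue - b$residue) <= 1) next
      d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
      p <- pair_step_potential(
        list(kind = "SC", aa = a$aa, residue = a$residue, chain = a$chain),
        list(kind = "SC", aa = b$aa, residue = b$residue, chain = b$chain),
        d, tab)
      esum <- esum + p$energy
    }
  }
  esum <- esum - tab$eps_hb * nrow(hb)
  expect_equal(esum, total_energy(u, topo, tab, hbonds = hb))
})
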