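# Shared fixtures and independent oracles used across the suite.

default_tab <- fibrildmd::default_forcefield()

# brute-force O(n^2) energy oracle: enumerate every pair at its current
# separation, summing well depths for side-chain pairs within range plus
# -eps per hydrogen bond in the supplied registry.  Independent of
# total_energy()'s vectorized path.
oracle_energy <- function(structure, table, hbonds) {
  beads <- if (is.data.frame(structure)) structure else structure$beads
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  n <- nrow(beads)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (beads$bead[i] != "SC" || beads$bead[j] != "SC") next
      if (beads$chain[i] == beads$chain[j] &&
          abs(beads$residue[i] - beads$residue[j]) <= 1) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      rng <- table$sc_wells$range[beads$aa[i], beads$aa[j]]
      if (d <= rng) {
        e <- e - effective_well_depth(beads$aa[i], beads$residue[i],
                                      beads$aa[j], beads$residue[j],
                                      table)
      }
    }
  }
  e - table$eps_hb * nrow(hbonds)
}

# reference BFS over an explicit chain-contact adjacency matrix
oracle_clusters <- function(structure, cutoff, min_contacts) {
  beads <- if (is.data.frame(structure)) structure else structure$beads
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  chains <- unique(beads$chain)
  nc <- length(chains)
  adj <- matrix(FALSE, nc, nc)
  for (a in seq_len(nc)) {
    for (b in seq_len(nc)) {
      if (a >= b) next
      ia <- which(beads$chain == chains[a])
      ib <- which(beads$chain == chains[b])
      cnt <- 0L
      for (i in ia) {
        d2 <- (xyz[ib, 1] - xyz[i, 1])^2 + (xyz[ib, 2] - xyz[i, 2])^2 +
          (xyz[ib, 3] - xyz[i, 3])^2
        cnt <- cnt + sum(d2 <= cutoff^2)
      }
      adj[a, b] <- adj[b, a] <- cnt >= min_contacts
    }
  }
  comp <- rep(NA_integer_, nc)
  cid <- 0L
  for (s in seq_len(nc)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(chains, comp)
}

# fine-step ballistic integrator detecting the first crossing of `radius`
oracle_crossing_time <- function(dr, dv, radius, t_max = 50, dt = 1e-4) {
  inside <- sqrt(sum(dr^2)) < radius
  t <- 0
  while (t < t_max) {
    t <- t + dt
    d <- sqrt(sum((dr + dv * t)^2))
    if ((inside && d >= radius) || (!inside && d <= radius)) {
      # bisect the bracketing step
      lo <- t - dt; hi <- t
      for (k in 1:60) {
        mid <- (lo + hi) / 2
        d <- sqrt(sum((dr + dv * mid)^2))
        cross <- if (inside) d >= radius else d <= radius
        if (cross) hi <- mid else lo <- mid
      }
      return((lo + hi) / 2)
    }
  }
  NA_real_
}

# bare two-bead system: two side-chain beads of amino acid `aa` on
# separate chains, with a customised A-A square well
two_bead_table <- function(eps = 1, lambda = 1.5, sigma = 4) {
  tab <- default_tab
  tab$sc_diameters["A"] <- sigma
  tab$sc_wells$depth["A", "A"] <- eps
  tab$sc_wells$range["A", "A"] <- lambda * sigma
  tab
}

two_bead_state <- function(d, v = 0.5, box = 30, table = two_bead_table()) {
  beads <- tibble::tibble(index = 1:2, chain = 1:2, residue = c(1L, 1L),
                          bead = "SC", aa = "A",
                          x = c(0, d), y = 0, z = 0,
                          vx = c(v, -v), vy = 0, vz = 0)
  topo <- list(beads = beads,
               bonds = tibble::tibble(a = integer(0), b = integer(0),
                                      length = numeric(0),
                                      delta = numeric(0)),
               chirality = tibble::tibble())
  fibrildmd::new_dmd_state(beads, box = box, topology = topo)
}

total_ke <- function(state) {
  with(state$beads, 0.5 * sum(vx^2 + vy^2 + vz^2))
}

# analytic canonical bound-time fraction of a square-well pair in a
# periodic cube: relative coordinate uniform over the box, Boltzmann
# weight e^{beta eps} inside the well shell
analytic_bound_fraction <- function(eps, sigma, lambda, box, temperature) {
  vw <- 4 / 3 * pi * ((lambda * sigma)^3 - sigma^3)
  vfree <- box^3 - 4 / 3 * pi * (lambda * sigma)^3
  w <- vw * exp(eps / temperature)
  w / (w + vfree)
}


# a U tetramer butted against a BH trimer: centroids aligned in x/z, bead
# clouds separated by ~2.5 A in y so the aggregate is a single cluster
compose_u_bh <- function() {
  u4 <- fibrildmd::make_fibril("U", 4)
  bh3 <- fibrildmd::make_beta_helix(3)
  bh3$chain <- bh3$chain + 4L
  cu <- colMeans(as.matrix(u4[, c("x", "y", "z")]))
  cb <- colMeans(as.matrix(bh3[, c("x", "y", "z")]))
  shift <- c(cu[1] - cb[1], max(u4$y) + 20 - min(bh3$y), cu[3] - cb[3])
  bh3 <- fibrildmd:::transform_structure(bh3, shift = shift)
  # close the actual gap to ~2.5 A along y (two correction passes)
  for (k in 1:2) {
    xa <- as.matrix(u4[, c("x", "y", "z")])
    xb <- as.matrix(bh3[, c("x", "y", "z")])
    d2 <- outer(xa[, 1], xb[, 1], "-")^2 +
      outer(xa[, 2], xb[, 2], "-")^2 +
      outer(xa[, 3], xb[, 3], "-")^2
    gap <- sqrt(min(d2)) - 2.5
    bh3 <- fibrildmd:::transform_structure(bh3, shift = c(0, -gap, 0))
  }
  comb <- dplyr::bind_rows(u4, bh3)
  comb$index <- seq_len(nrow(comb))
  comb
}
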