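# Synthetic conformer generators: idealized fibrillar templates (U-shape,
# S-shape serpentines, D alternatives), the beta-helix aggregate, random
# coils, noise perturbation, and random dilute initial configurations.

# serpentine layout conventions per fibrillar class (residues 17..42).
# Turn placements are package conventions chosen to give mutually
# distinguishable intra-peptide distance profiles; the U turn places D23
# against K28 and F19 against I32/L34 across the strand gap.
fibril_shapes <- function() {
  list(
    U  = list(turns = list(c(24, 27)), gaps = 11.4, xshift = 0),
    S1 = list(turns = list(c(23, 26), c(33, 36)), gaps = c(11.4, 11.4),
              xshift = c(0, 0)),
    S2 = list(turns = list(c(21, 24), c(31, 34)), gaps = c(11.8, 11.4),
              xshift = c(0, 0)),
    S3 = list(turns = list(c(26, 29), c(35, 38)), gaps = c(11.4, 11.4),
              xshift = c(0, 0)),
    D1 = list(turns = list(c(22, 25)), gaps = 13.4, xshift = -2),
    D2 = list(turns = list(c(29, 32)), gaps = 11.4, xshift = 0))
}

# CA trace of one chain of a serpentine shape in the z = 0 plane
serpentine_ca <- function(shape_def, first_res = 17L, n_res = 26L,
                          dx = 3.35) {
  res <- seq.int(first_res, length.out = n_res)
  turns <- shape_def$turns
  w <- sqrt(BB_BONDS[["ca_ca"]]^2 - dx^2) / 2
  # strand blocks
  starts <- c(first_res, vapply(turns, function(t) t[2] + 1, numeric(1)))
  ends <- c(vapply(turns, function(t) t[1] - 1, numeric(1)),
            first_res + n_res - 1)
  zs <- shape_def$zshift
  if (is.null(zs)) zs <- 0
  zs <- rep(zs, length.out = length(starts) - 1L)
  ca <- matrix(NA_real_, n_res, 3)
  rownames(ca) <- res
  ybase <- 0; anchor <- 0; zbase <- 0
  for (k in seq_along(starts)) {
    d <- (-1)^(k - 1)
    rr <- starts[k]:ends[k]
    if (k > 1) {
      gap <- shape_def$gaps[k - 1]
      xs <- shape_def$xshift[k - 1] * dx
      ybase <- ybase + gap
      anchor <- anchor + xs
      zbase <- zbase + zs[k - 1]
    }
    x <- anchor + d * (rr - starts[k]) * dx
    y <- ybase - ((-1)^rr) * w
    ca[as.character(rr), ] <- cbind(x, y, zbase)
    anchor <- x[length(x)]
  }
  # turns: circular-arc bridges between strand ends
  for (k in seq_along(turns)) {
    t0 <- turns[[k]][1]; t1 <- turns[[k]][2]
    p0 <- ca[as.character(t0 - 1L), ]
    p1 <- ca[as.character(t1 + 1L), ]
    away <- colMeans(ca[!is.na(ca[, 1]), , drop = FALSE])
    pts <- arc_bridge(p0, p1, n_in = t1 - t0 + 1L, away = away)
    ca[as.character(t0:t1), ] <- pts
  }
  ca
}

# raise an error naming the worst offending pair of an overlap audit
stop_on_overlap <- function(viol, beads, what) {
  viol <- viol[viol$type %in% c("core", "squeeze"), , drop = FALSE]
  if (nrow(viol) == 0) return(invisible(NULL))
  k <- which.min(viol$dist - viol$limit)
  a <- viol$a[k]; b <- viol$b[k]
  abort(sprintf(
    "%s template has a hard overlap: %s%d:%s (chain %s) vs %s%d:%s (chain %s), %.2f A < %.2f A",
    what, beads$aa[a], beads$residue[a], beads$bead[a], beads$chain[a],
    beads$aa[b], beads$residue[b], beads$bead[b], beads$chain[b],
    viol$dist[k], viol$limit[k]), class = "fibril_generation_error")
}

# does a freshly built single chain satisfy all hard constraints?
chain_is_valid <- function(ch, topo1, table) {
  v <- check_constraints(ch, topo1, table)
  !any(v$type %in% c("core", "squeeze"))
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Build an idealized fibrillar conformer
#'
#' Stacks `n_chains` in-register copies of a strand-turn-strand template:
#' the U-shape hairpin (turn 24-27, D23 side chain facing K28 and F19 facing
#' I32/L34 across the strand gap), three S-shape serpentines with distinct
#' turn placements, or two schematic D alternatives.  Chains are stacked
#' along z at a constant CA rise; at zero jitter the stack is audited
#' against the hard-core and squeeze constraints of the interaction table.
#'
#' @param shape One of `"U"`, `"S1"`, `"S2"`, `"S3"`, `"D1"`, `"D2"`.
#' @param n_chains Number of stacked chains (>= 1).
#' @param rise Inter-chain CA rise in Angstrom.
#' @param jitter Isotropic Gaussian displacement amplitude (per-coordinate
#'   standard deviation, Angstrom) applied to every bead.
#' @param seed RNG seed for the jitter.
#' @param register_shift Integer: shift chain `c` by `c * register_shift`
#'   CA positions along the strand axis (used to build out-of-register
#'   fixtures).
#' @param table Interaction table (geometry source and overlap audit).
#' @return A bead tibble (topology order) with attributes `topology` and
#'   `shape`.
#' @examples
#' u8 <- make_fibril("U", 2)
#' @export
make_fibril <- function(shape = c("U", "S1", "S2", "S3", "D1", "D2"),
                        n_chains, rise = 4.9, jitter = 0, seed = NULL,
                        register_shift = 0, table = default_forcefield()) {
  shape <- match.arg(shape)
  if (n_chains < 1) abort("n_chains must be >= 1")
  def <- fibril_shapes()[[shape]]
  ca <- serpentine_ca(def)
  seq_aa <- strsplit(ab1742_sequence(), "")[[1]]
  res_no <- 17:42
  chain1 <- build_chain_beads(ca, seq_aa, res_no, 1L, table)
  chains <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    ch <- chain1
    ch$chain <- c
    shift <- c(register_shift * 3.35 * (c - 1L), 0, rise * (c - 1L))
    ch <- transform_structure(ch, shift = shift)
    chains[[c]] <- ch
  }
  out <- bind_rows(chains)
  out$index <- seq_len(nrow(out))
  out <- out[, c("index", "chain", "residue", "bead", "aa",
                 "x", "y", "z")]
  topo <- build_peptide(ab1742_sequence(), n_chains, 17L, table)
  if (jitter > 0) {
    out <- perturb_structure(out, jitter, seed = seed)
  } else {
    viol <- check_constraints(out, topo, table)
    stop_on_overlap(viol, out, shape)
  }
  structure(out, topology = topo, shape = shape)
}

#' Build a beta-helix (BH) aggregate
#'
#' A helically wound inter-chain beta-sheet: every chain is a single
#' extended strand, and successive chains are stacked with a constant rise
#' and a constant twist about the stacking axis, so all backbone hydrogen
#' bonds are inter-chain.
#'
#' @param n_chains Number of chains (>= 2; the motif is inter-chain by
#'   definition).
#' @param twist Per-chain rotation in radians.
#' @param rise Inter-chain rise in Angstrom.
#' @param jitter,seed As in [make_fibril()].
#' @param table Interaction table.
#' @return A bead tibble with attributes `topology` and `shape = "BH"`.
#' @export
make_beta_helix <- function(n_chains, twist = 6 * pi / 180, rise = 4.9,
                            jitter = 0, seed = NULL,
                            table = default_forcefield()) {
  if (n_chains < 2) {
    abort("a beta-helix aggregate needs at least 2 chains")
  }
  ca <- strand_zigzag(26L)
  seq_aa <- strsplit(ab1742_sequence(), "")[[1]]
  chain1 <- build_chain_beads(ca, seq_aa, 17:42, 1L, table)
  centre <- colMeans(as.matrix(chain1[chain1$bead == "CA",
                                      c("x", "y", "z")]))
  chains <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    ch <- chain1
    ch$chain <- c
    rot <- rotation_z(twist * (c - 1L))
    ch <- transform_structure(ch, shift = -centre)
    ch <- transform_structure(ch, rot = rot,
                              shift = centre + c(0, 0, rise * (c - 1L)))
    chains[[c]] <- ch
  }
  out <- bind_rows(chains)
  out$index <- seq_len(nrow(out))
  out <- out[, c("index", "chain", "residue", "bead", "aa", "x", "y", "z")]
  topo <- build_peptide(ab1742_sequence(), n_chains, 17L, table)
  if (jitter > 0) {
    out <- perturb_structure(out, jitter, seed = seed)
  } else {
    viol <- check_constraints(out, topo, table)
    stop_on_overlap(viol, out, "BH")
  }
  structure(out, topology = topo, shape = "BH")
}

# One self-avoiding random-coil CA trace.  Growth is closure-aware: a step
# is accepted only when the backbone-placement azimuth equation still has a
# root, so the assembled chain satisfies all amide pseudo-bond walls.
coil_ca <- function(n_res, max_try = 400L, sc_d = rep(2.6, n_res),
                    sc_alpha = SC_ALPHA_DEFAULT) {
  L <- BB_BONDS[["ca_ca"]]
  k <- bb_constants()
  target <- BB_BONDS[["nh_co"]]
  seg_frame <- function(u) {
    ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    n1 <- vunit(vcross(u, ref))
    list(u = u, n1 = n1, n2 = vcross(u, n1))
  }
  psi_root <- function(prev_nh, p_from, frame) {
    f <- function(p) {
      co <- p_from + k$aC * frame$u +
        k$rC * (cos(p) * frame$n1 + sin(p) * frame$n2)
      vnorm(co - prev_nh) - target
    }
    grid <- seq(-pi, pi, length.out = 73L)
    fv <- vapply(grid, f, numeric(1))
    for (g in seq_len(length(grid) - 1L)) {
      if (fv[g] * fv[g + 1L] <= 0) {
        return(uniroot(f, grid[c(g, g + 1L)], tol = 1e-10)$root)
      }
    }
    NA_real_
  }
  for (attempt in seq_len(max_try)) {
    ca <- matrix(NA_real_, n_res, 3)
    ca[1, ] <- c(0, 0, 0)
    dir <- vunit(rnorm(3))
    ca[2, ] <- ca[1, ] + L * dir
    fr <- seg_frame(dir)
    psi_all <- numeric(n_res - 1L)
    psi_prev <- runif(1, -pi, pi)
    psi_all[1] <- psi_prev
    sc <- matrix(NA_real_, n_res, 3)   # side-chain screen positions
    ok <- TRUE
    for (i in 3:n_res) {
      nh_prev <- ca[i - 1, ] - k$bN * fr$u -
        k$rN * (cos(psi_prev) * fr$n1 + sin(psi_prev) * fr$n2)
      placed <- FALSE
      for (try in seq_len(60L)) {
        bend <- runif(1, 45, 80) * pi / 180
        phi <- runif(1, -pi, pi)
        newdir <- cos(bend) * fr$u +
          sin(bend) * (cos(phi) * fr$n1 + sin(phi) * fr$n2)
        cand <- ca[i - 1, ] + L * newdir
        prev <- ca[seq_len(max(i - 3L, 0L)), , drop = FALSE]
        if (nrow(prev) > 0 &&
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) <= 4.6) next
        nfr <- seg_frame(newdir)
        p <- psi_root(nh_prev, ca[i - 1, ], nfr)
        if (is.na(p)) next
        # screen the side chain of residue i-1 (now fully determined)
        co_prev <- ca[i - 1, ] + k$aC * nfr$u +
          k$rC * (cos(p) * nfr$n1 + sin(p) * nfr$n2)
        sc_cand <- place_sidechain(nh_prev, ca[i - 1, ], co_prev,
                                   sc_d[i - 1], sc_alpha)
        far <- ca[seq_len(max(i - 4L, 0L)), , drop = FALSE]
        if (nrow(far) > 0 &&
            min(sqrt(rowSums(sweep(far, 2, sc_cand)^2))) <= 4.3) next
        sc_far <- sc[seq_len(max(i - 4L, 0L)), , drop = FALSE]
        sc_far <- sc_far[!is.na(sc_far[, 1]), , drop = FALSE]
        if (nrow(sc_far) > 0 &&
            min(sqrt(rowSums(sweep(sc_far, 2, sc_cand)^2))) <= 4.6) next
        if (min(sqrt(rowSums(sweep(
          matrix(cand, 1), 2, sc_cand)^2))) <= 3.1) next
        sc[i - 1, ] <- sc_cand
        ca[i, ] <- cand
        fr <- nfr
        psi_prev <- p
        psi_all[i - 1L] <- p
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(structure(ca, psi = psi_all))
  }
  abort("failed to generate a self-avoiding coil",
        class = "fibril_generation_error")
}

#' Build random-coil chains
#'
#' Self-avoiding random coils with valid backbone closure, placed far apart
#' so that no inter-chain contacts exist.
#'
#' @param n_chains Number of chains.
#' @param seed RNG seed.
#' @param spacing Centre-to-centre distance between consecutive chains
#'   (Angstrom).
#' @param table Interaction table.
#' @param max_residual Largest tolerated deviation of the intra-residue
#'   NH-CO pseudo-bond from its ideal length, as a fraction of the bond
#'   tolerance.
#' @return A bead tibble with attributes `topology`, `shape = "coil"`.
#' @export
make_coil <- function(n_chains = 1L, seed = NULL, spacing = 60,
                      table = default_forcefield(), max_residual = 1) {
  seq_aa <- strsplit(ab1742_sequence(), "")[[1]]
  tol <- max_residual * table$bond_delta * BB_BONDS[["nh_co"]]
  topo1 <- build_peptide(ab1742_sequence(), 1L, 17L, table)
  with_seed(seed, {
    chains <- vector("list", n_chains)
    for (c in seq_len(n_chains)) {
      scd <- ifelse(seq_aa == "G", 0, table$sc_ca_dist[seq_aa])
      for (k in seq_len(50L)) {
        ca <- coil_ca(26L, sc_d = scd, sc_alpha = table$sc_alpha)
        ch <- build_chain_beads(ca, seq_aa, 17:42, c, table)
        if (attr(ch, "max_residual") <= tol &&
            chain_is_valid(ch, topo1, table)) break
        ch <- NULL
      }
      if (is.null(ch)) {
        abort("failed to close a coil backbone",
              class = "fibril_generation_error")
      }
      ch <- transform_structure(ch, rot = random_rotation(),
                                shift = c(spacing * (c - 1L), 0, 0))
      chains[[c]] <- ch
    }
    out <- bind_rows(chains)
    out$index <- seq_len(nrow(out))
    out <- out[, c("index", "chain", "residue", "bead", "aa",
                   "x", "y", "z")]
    topo <- build_peptide(ab1742_sequence(), n_chains, 17L, table)
    structure(out, topology = topo, shape = "coil")
  })
}

#' Perturb a structure with isotropic Gaussian noise
#'
#' Adds an iid Gaussian displacement (standard deviation `amplitude` per
#' coordinate) to every bead.  Amplitude 0 returns the input unchanged.
#'
#' @param structure Bead tibble.
#' @param amplitude Per-coordinate standard deviation in Angstrom (>= 0).
#' @param seed RNG seed (reproducible perturbation).
#' @return The perturbed tibble (attributes preserved).
#' @export
perturb_structure <- function(structure, amplitude, seed = NULL) {
  if (amplitude < 0) abort("amplitude must be >= 0")
  if (amplitude == 0) return(structure)
  with_seed(seed, {
    n <- nrow(structure)
    structure$x <- structure$x + rnorm(n, 0, amplitude)
    structure$y <- structure$y + rnorm(n, 0, amplitude)
    structure$z <- structure$z + rnorm(n, 0, amplitude)
    structure
  })
}

#' Random dilute initial configuration
#'
#' Places `n_chains` self-avoiding random coils at random positions and
#' orientations in the cubic box fixed by the concentration, rejection
#' sampling against inter-chain proximity, and draws Maxwell-Boltzmann
#' velocities at the given reduced temperature.
#'
#' @param n_chains Number of chains (>= 1).
#' @param concentration Molar concentration (mol/L); the box edge follows
#'   from [box_length()].
#' @param seed RNG seed.
#' @param sequence One-letter sequence (default the Aβ17-42 fragment).
#' @param first_residue First residue number.
#' @param table Interaction table.
#' @param temperature Reduced temperature for the initial velocities.
#' @param min_gap Minimum inter-chain bead distance accepted during
#'   placement (Angstrom).
#' @param max_try Placement attempts per chain before giving up.
#' @return A `dmd_state`: list with `beads` (tibble incl. `vx`, `vy`, `vz`),
#'   `box`, `time`, `collisions`, `hb` (empty registry) and `topology`.
#' @export
make_random_config <- function(n_chains, concentration = 1e-3, seed = NULL,
                               sequence = ab1742_sequence(),
                               first_residue = 17L,
                               table = default_forcefield(),
                               temperature = 0.2, min_gap = 8,
                               max_try = 200L) {
  if (n_chains < 1) abort("n_chains must be >= 1")
  L <- box_length(n_chains, concentration, round = FALSE)
  seq_aa <- strsplit(sequence, "")[[1]]
  res_no <- seq.int(first_residue, length.out = length(seq_aa))
  topo <- build_peptide(sequence, n_chains, first_residue, table)
  topo1 <- build_peptide(sequence, 1L, first_residue, table)
  with_seed(seed, {
    placed <- list()
    occ <- NULL
    for (c in seq_len(n_chains)) {
      done <- FALSE
      scd <- ifelse(seq_aa == "G", 0, table$sc_ca_dist[seq_aa])
      for (k in seq_len(max_try)) {
        ca <- coil_ca(length(seq_aa), sc_d = scd,
                      sc_alpha = table$sc_alpha)
        ch <- build_chain_beads(ca, seq_aa, res_no, c, table)
        if (attr(ch, "max_residual") >
            table$bond_delta * BB_BONDS[["nh_co"]]) next
        if (!chain_is_valid(ch, topo1, table)) next
        ch <- transform_structure(ch, rot = random_rotation())
        xyz <- as.matrix(ch[, c("x", "y", "z")])
        xyz <- sweep(xyz, 2, colMeans(xyz))
        shift <- runif(3, 0, L)
        xyz <- sweep(xyz, 2, shift, "+")
        if (!is.null(occ)) {
          # minimum-image inter-chain separation
          dx <- outer(xyz[, 1], occ[, 1], "-")
          dy <- outer(xyz[, 2], occ[, 2], "-")
          dz <- outer(xyz[, 3], occ[, 3], "-")
          dx <- dx - L * round(dx / L)
          dy <- dy - L * round(dy / L)
          dz <- dz - L * round(dz / L)
          if (min(dx^2 + dy^2 + dz^2) < min_gap^2) next
        }
        ch$x <- xyz[, 1]; ch$y <- xyz[, 2]; ch$z <- xyz[, 3]
        occ <- rbind(occ, xyz)
        placed[[c]] <- ch
        done <- TRUE
        break
      }
      if (!done) {
        abort(paste0("could not place chain ", c,
                     " without overlap (density too high?)"),
              class = "fibril_generation_error")
      }
    }
    beads <- bind_rows(placed)
    beads$index <- seq_len(nrow(beads))
    beads <- beads[, c("index", "chain", "residue", "bead", "aa",
                       "x", "y", "z")]
    n <- nrow(beads)
    sdv <- sqrt(temperature / table$mass)
    beads$vx <- rnorm(n, 0, sdv)
    beads$vy <- rnorm(n, 0, sdv)
    beads$vz <- rnorm(n, 0, sdv)
    new_dmd_state(beads, box = L, topology = topo)
  })
}

#' Construct a simulation state
#'
#' @param beads Bead tibble with positions (and optionally velocities;
#'   zero-filled when absent).
#' @param box Cubic box edge (Angstrom); `Inf` for an open box.
#' @param topology The `peptide_topology`.
#' @param time,collisions Starting clock values.
#' @param hb Optional hydrogen-bond registry (tibble with `nh`, `co`).
#' @return A `dmd_state`.
#' @export
new_dmd_state <- function(beads, box, topology, time = 0, collisions = 0,
                          hb = NULL) {
  if (is.null(beads$vx)) beads$vx <- 0
  if (is.null(beads$vy)) beads$vy <- 0
  if (is.null(beads$vz)) beads$vz <- 0
  if (is.null(hb)) hb <- tibble(nh = integer(0), co = integer(0))
  structure(list(beads = beads, box = box, time = time,
                 collisions = collisions, hb = hb, topology = topology),
            class = "dmd_state")
}

#' @export
print.dmd_state <- function(x, ...) {
  cat("<dmd_state> ", nrow(x$beads), " beads, box ",
      formatC(x$box, digits = 6), " A, t* = ", formatC(x$time, digits = 6),
      ", collisions = ", formatC(x$collisions, format = "d"),
      ", HBs = ", nrow(x$hb), "\n", sep = "")
  invisible(x)
}
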