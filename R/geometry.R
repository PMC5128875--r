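# Internal geometric machinery for building idealized conformers: CA path
# generators (zigzag strands, turn arcs), backbone bead placement by azimuth
# root-finding, and side-chain placement in the local residue frame.

vnorm <- function(v) sqrt(sum(v^2))
vunit <- function(v) v / vnorm(v)
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# derived backbone placement constants for a CA-CA segment of length ca_ca:
# CO(i) sits at axial offset aC / radial rC from CA(i); NH(i+1) at axial
# offset bN back from CA(i+1) / radial rN, on the opposite azimuth.
bb_constants <- function(bonds = BB_BONDS) {
  L <- bonds[["ca_ca"]]
  aC <- (L^2 + bonds[["ca_co"]]^2 - bonds[["co_ca"]]^2) / (2 * L)
  rC <- sqrt(bonds[["ca_co"]]^2 - aC^2)
  aN <- (L^2 + bonds[["ca_nh"]]^2 - bonds[["nh_ca"]]^2) / (2 * L)
  bN <- L - aN
  rN <- sqrt(bonds[["nh_ca"]]^2 - bN^2)
  list(aC = aC, rC = rC, bN = bN, rN = rN, L = L)
}

# zigzag beta-strand CA trace along +x in the z = 0 plane.
# phase flips which residues sit at +y vertices.
strand_zigzag <- function(n, dx = 3.35, phase = 0L,
                          origin = c(0, 0, 0), dir = +1) {
  w <- sqrt(BB_BONDS[["ca_ca"]]^2 - dx^2) / 2
  i <- seq_len(n) - 1L
  cbind(origin[1] + dir * i * dx,
        origin[2] + ((-1)^(i + phase)) * w,
        origin[3])
}

# circular-arc bridge: n_in interior points between p0 and p1, all chords of
# length `step`, bulging away from `away` (a point the arc should avoid).
# Solves the circle radius so that (n_in + 1) equal chords span the gap.
arc_bridge <- function(p0, p1, n_in, step = BB_BONDS[["ca_ca"]],
                       away = NULL) {
  chord <- vnorm(p1 - p0)
  m <- n_in + 1L
  if (m * step <= chord) {
    abort("turn span too short to bridge the strand gap")
  }
  f <- function(R) 2 * R * sin(m * asin(step / (2 * R))) - chord
  lo <- step / 2 + 1e-9
  hi <- 1e4
  if (f(lo) * f(hi) > 0) abort("turn arc is infeasible")
  R <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  arc_angle <- 2 * m * asin(step / (2 * R))
  # arc in the plane through p0, p1 and the bulge direction
  mid <- (p0 + p1) / 2
  u <- vunit(p1 - p0)
  bulge <- if (is.null(away)) c(1, 0, 0) else vunit(mid - away)
  bulge <- bulge - sum(bulge * u) * u
  if (vnorm(bulge) < 1e-8) bulge <- c(0, 0, 1) - sum(c(0, 0, 1) * u) * u
  bulge <- vunit(bulge)
  h <- sqrt(max(R^2 - (chord / 2)^2, 0))
  # reflex arcs (> pi) wrap around a centre on the bulge side of the chord
  centre <- if (arc_angle > pi) mid + h * bulge else mid - h * bulge
  a0 <- atan2(sum((p0 - centre) * bulge), sum((p0 - centre) * u))
  a1 <- atan2(sum((p1 - centre) * bulge), sum((p1 - centre) * u))
  cw <- (a1 - a0) %% (2 * pi)    # counter-clockwise sweep
  ccw <- (a0 - a1) %% (2 * pi)   # clockwise sweep
  ang <- if (abs(cw - arc_angle) <= abs(ccw - arc_angle)) {
    seq(a0, a0 + cw, length.out = m + 1L)[2:m]
  } else {
    seq(a0, a0 - ccw, length.out = m + 1L)[2:m]
  }
  t(vapply(ang, function(a) centre + R * (cos(a) * u + sin(a) * bulge),
           numeric(3)))
}

# per-segment orthonormal frames along a CA polyline
segment_frames <- function(ca) {
  ns <- nrow(ca) - 1L
  U <- N1 <- N2 <- matrix(0, ns, 3)
  zhat <- c(0, 0, 1)
  for (i in seq_len(ns)) {
    u <- vunit(ca[i + 1L, ] - ca[i, ])
    ref <- if (abs(sum(u * zhat)) > 0.9) c(1, 0, 0) else zhat
    n1 <- vunit(vcross(u, ref))
    U[i, ] <- u; N1[i, ] <- n1; N2[i, ] <- vcross(u, n1)
  }
  list(U = U, N1 = N1, N2 = N2)
}

# Place NH and CO beads along a CA polyline (all segments ~ ca_ca long).
# One azimuth angle psi per segment positions CO(i) and NH(i+1) on opposite
# sides of the segment axis; psi is solved residue-by-residue so that the
# intra-residue NH-CO pseudo-bond (N-CA-C angle) is satisfied.  Termini get
# their own azimuth solves.  Returns NH/CO matrices and max residual.
place_backbone <- function(ca, psi_init = NULL, psi_given = NULL) {
  n <- nrow(ca); ns <- n - 1L
  k <- bb_constants()
  fr <- segment_frames(ca)
  rad <- function(i, p) cos(p) * fr$N1[i, ] + sin(p) * fr$N2[i, ]
  co_pos <- function(i, p) ca[i, ] + k$aC * fr$U[i, ] + k$rC * rad(i, p)
  nh_pos <- function(i, p) ca[i + 1L, ] - k$bN * fr$U[i, ] - k$rN * rad(i, p)

  psi <- numeric(ns)
  target <- BB_BONDS[["nh_co"]]
  solve_next <- function(prev_nh, i, prefer) {
    f <- function(p) vnorm(co_pos(i, p) - prev_nh) - target
    grid <- seq(-pi, pi, length.out = 181L)
    fv <- vapply(grid, f, numeric(1))
    roots <- c()
    for (g in seq_len(length(grid) - 1L)) {
      if (fv[g] * fv[g + 1L] <= 0 && is.finite(fv[g])) {
        roots <- c(roots, uniroot(f, grid[c(g, g + 1L)], tol = 1e-12)$root)
      }
    }
    if (length(roots) == 0) {
      return(grid[which.min(abs(fv))])
    }
    sc <- -abs(sin(roots) - sin(prefer)) - abs(cos(roots) - cos(prefer)) / 4
    roots[which.max(sc)]
  }
  if (!is.null(psi_given)) {
    psi <- psi_given
  } else {
    psi[1] <- if (is.null(psi_init)) pi / 2 else psi_init
    if (ns > 1) {
      # two passes: the second re-seeds segment 1 from the converged
      # period-2 pattern so the chain start matches the interior pleat
      for (pass in 1:2) {
        for (i in 2:ns) {
          prev_nh <- nh_pos(i - 1L, psi[i - 1L])
          psi[i] <- solve_next(prev_nh, i, prefer = psi[max(i - 2L, 1L)])
        }
        if (ns >= 3L) psi[1] <- psi[3L] else break
      }
    }
  }
  NH <- CO <- matrix(NA_real_, n, 3)
  for (i in seq_len(ns)) {
    CO[i, ] <- co_pos(i, psi[i])
    NH[i + 1L, ] <- nh_pos(i, psi[i])
  }
  # Terminal amide beads carry only two constraints (to their CA and to
  # the residue's other amide bead), i.e. a full circle of solutions:
  # place them on that sphere-intersection circle, at the point that best
  # continues the interior pleat pattern (same-parity residue offset).
  circle_point <- function(centre, anchor, r_centre, r_anchor, target_off) {
    # points P with |P - centre| = r_centre and |P - anchor| = r_anchor
    e <- vunit(anchor - centre)
    dca <- vnorm(anchor - centre)
    x <- (dca^2 + r_centre^2 - r_anchor^2) / (2 * dca)
    rad2 <- r_centre^2 - x^2
    if (rad2 <= 0) return(centre + r_centre * vunit(target_off))
    rr <- sqrt(rad2)
    w <- target_off - sum(target_off * e) * e
    if (vnorm(w) < 1e-9) {
      ref <- if (abs(e[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      w <- ref - sum(ref * e) * e
    }
    centre + x * e + rr * vunit(w)
  }
  ref_off <- if (n >= 3L) NH[3L, ] - ca[3L, ] else NH[2L, ] - ca[2L, ]
  NH[1, ] <- circle_point(ca[1, ], CO[1, ], BB_BONDS[["nh_ca"]], target,
                          ref_off)
  ref_off <- if (n >= 3L) CO[n - 2L, ] - ca[n - 2L, ] else
    CO[n - 1L, ] - ca[n - 1L, ]
  CO[n, ] <- circle_point(ca[n, ], NH[n, ], BB_BONDS[["ca_co"]], target,
                          ref_off)

  resid <- vapply(seq_len(n), function(i) {
    abs(vnorm(NH[i, ] - CO[i, ]) - target)
  }, numeric(1))
  list(NH = NH, CO = CO, psi = psi, max_residual = max(resid))
}

# side-chain bead from the residue's NH/CA/CO beads; positive-determinant
# (L-isomer) branch
place_sidechain <- function(nh, ca, co, d, alpha) {
  u1 <- vunit(nh - ca); u2 <- vunit(co - ca)
  tv <- vunit(-(u1 + u2))
  nv <- vunit(vcross(u1, u2))
  ca + d * (cos(alpha) * tv + sin(alpha) * nv)
}

# assemble one chain (CA path -> full bead tibble rows in topology order)
build_chain_beads <- function(ca, aa, res_no, chain_id, table) {
  bb <- place_backbone(ca, psi_given = attr(ca, "psi"))
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    kinds <- if (aa[i] == "G") c("NH", "CA", "CO") else BEAD_KINDS
    xyz <- rbind(bb$NH[i, ], ca[i, ], bb$CO[i, ])
    if (aa[i] != "G") {
      sc <- place_sidechain(bb$NH[i, ], ca[i, ], bb$CO[i, ],
                            table$sc_ca_dist[[aa[i]]], table$sc_alpha)
      xyz <- rbind(xyz, sc)
    }
    rows[[i]] <- tibble(chain = chain_id, residue = res_no[i],
                        bead = kinds, aa = aa[i],
                        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  structure(bind_rows(rows), max_residual = bb$max_residual)
}

# rigid-body helpers -------------------------------------------------------

rotation_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_rotation <- function() {
  # uniform random rotation from a normalized quaternion
  q <- rnorm(4); q <- q / vnorm(q)
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b),
           a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

transform_structure <- function(structure, rot = diag(3),
                                shift = c(0, 0, 0)) {
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(rot)
  structure$x <- xyz[, 1] + shift[1]
  structure$y <- xyz[, 2] + shift[2]
  structure$z <- xyz[, 3] + shift[3]
  structure
}

# Kabsch optimal rotation of point set P onto Q (both centred n x 3)
kabsch <- function(P, Q) {
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}
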