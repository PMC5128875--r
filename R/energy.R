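# Static (configuration-level) energetics: constraint auditing, geometric
# hydrogen-bond assignment, and total square-well energy of a structure.

# coordinates of a structure in topology bead order
structure_xyz <- function(structure) {
  if (is.list(structure) && !is.data.frame(structure) &&
      !is.null(structure$beads)) {
    structure <- structure$beads
  }
  as.matrix(structure[, c("x", "y", "z")])
}

structure_beads <- function(structure) {
  if (is.list(structure) && !is.data.frame(structure) &&
      !is.null(structure$beads)) {
    return(structure$beads)
  }
  structure
}

# all-pairs separation matrix with optional cubic minimum image
pair_dist_matrix <- function(xyz, box = NULL) {
  dx <- outer(xyz[, 1], xyz[, 1], "-")
  dy <- outer(xyz[, 2], xyz[, 2], "-")
  dz <- outer(xyz[, 3], xyz[, 3], "-")
  if (!is.null(box) && is.finite(box)) {
    dx <- dx - box * round(dx / box)
    dy <- dy - box * round(dy / box)
    dz <- dz - box * round(dz / box)
  }
  sqrt(dx^2 + dy^2 + dz^2)
}

# index lookup (chain, residue, kind) -> bead index, NA when absent
bead_index_lookup <- function(beads) {
  key <- paste(beads$chain, beads$residue, beads$bead, sep = "|")
  setNames(beads$index, key)
}

lookup_idx <- function(lk, chain, residue, kind) {
  v <- unname(lk[paste(chain, residue, kind, sep = "|")])
  ifelse(is.na(v), NA_integer_, v)
}

#' Audit hard constraints of a configuration
#'
#' Checks every bonded pair against its walls and every non-bonded pair
#' against its hard-core (or squeeze) distance.
#'
#' @param structure Bead tibble (or simulation state) in topology order.
#' @param topology The `peptide_topology`.
#' @param table An `interaction_table`.
#' @param box Optional cubic box edge for minimum-image distances.
#' @param tol Violation tolerance in Angstrom.
#' @return Tibble of violations (empty when the configuration is valid):
#'   columns `a`, `b`, `type`, `dist`, `limit`.
#' @export
check_constraints <- function(structure, topology,
                              table = default_forcefield(), box = NULL,
                              tol = 1e-9) {
  beads <- structure_beads(structure)
  xyz <- structure_xyz(structure)
  n <- nrow(beads)
  D <- pair_dist_matrix(xyz, box)
  out <- list()

  bd <- topology$bonds
  dists <- D[cbind(bd$a, bd$b)]
  lo <- bd$length * (1 - bd$delta); hi <- bd$length * (1 + bd$delta)
  bad <- which(dists < lo - tol | dists > hi + tol)
  if (length(bad) > 0) {
    out$bond <- tibble(a = bd$a[bad], b = bd$b[bad], type = "bond",
                       dist = dists[bad],
                       limit = ifelse(dists[bad] < lo[bad], lo[bad], hi[bad]))
  }

  # non-bonded core / squeeze audit
  diam <- ifelse(beads$bead == "SC", table$sc_diameters[beads$aa],
                 table$bead_diameters[beads$bead])
  core <- outer(diam, diam, function(a, b) (a + b) / 2)
  same_chain <- outer(beads$chain, beads$chain, "==")
  dres <- abs(outer(beads$residue, beads$residue, "-"))
  squeeze <- same_chain & dres <= 1
  core[squeeze] <- core[squeeze] * table$squeeze_factor
  bonded <- matrix(FALSE, n, n)
  bonded[cbind(bd$a, bd$b)] <- TRUE
  bonded[cbind(bd$b, bd$a)] <- TRUE
  viol <- which(upper.tri(D) & !bonded & (D < core - tol), arr.ind = TRUE)
  if (nrow(viol) > 0) {
    out$core <- tibble(a = viol[, 1], b = viol[, 2],
                       type = ifelse(squeeze[viol], "squeeze", "core"),
                       dist = D[viol], limit = core[viol])
  }
  if (length(out) == 0) {
    return(tibble(a = integer(0), b = integer(0), type = character(0),
                  dist = numeric(0), limit = numeric(0)))
  }
  bind_rows(out)
}

# eligibility of a candidate NH-CO hydrogen bond (geometry criteria only;
# occupancy is supplied by the caller)
hb_geometry_ok <- function(beads, xyz, lk, nh, co, table, D = NULL,
                           box = NULL) {
  dist2 <- function(a, b) {
    if (!is.null(D)) return(D[a, b])
    d <- xyz[a, ] - xyz[b, ]
    if (!is.null(box) && is.finite(box)) d <- d - box * round(d / box)
    vnorm(d)
  }
  ri <- beads$residue[nh]; ci <- beads$chain[nh]
  rj <- beads$residue[co]; cj <- beads$chain[co]
  if (ci == cj && abs(ri - rj) < table$hb_min_seq_sep) return(FALSE)
  d <- dist2(nh, co)
  if (d > table$hb_range || d < table$hb_core) return(FALSE)
  aux <- c(lookup_idx(lk, ci, ri, "CA"), lookup_idx(lk, ci, ri - 1, "CO"))
  for (a in aux[!is.na(aux)]) {
    if (dist2(a, co) < table$hb_aux_min) return(FALSE)
  }
  aux <- c(lookup_idx(lk, cj, rj, "CA"), lookup_idx(lk, cj, rj + 1, "NH"))
  for (a in aux[!is.na(aux)]) {
    if (dist2(a, nh) < table$hb_aux_min) return(FALSE)
  }
  if (isTRUE(table$parallel_preference)) {
    s1a <- lookup_idx(lk, ci, ri - 1, "CA"); s1b <- lookup_idx(lk, ci, ri + 1, "CA")
    s2a <- lookup_idx(lk, cj, rj - 1, "CA"); s2b <- lookup_idx(lk, cj, rj + 1, "CA")
    if (!anyNA(c(s1a, s1b, s2a, s2b))) {
      u1 <- vunit(xyz[s1b, ] - xyz[s1a, ])
      u2 <- vunit(xyz[s2b, ] - xyz[s2a, ])
      if (sum(u1 * u2) < cos(table$parallel_threshold)) return(FALSE)
    }
  }
  TRUE
}

#' Is a candidate hydrogen bond eligible?
#'
#' Evaluates the directional hydrogen-bond criteria between an NH bead and a
#' CO bead: centre distance within the HB well, auxiliary neighbour-distance
#' constraints, minimum same-chain sequence separation, single occupancy
#' against the supplied registry, and (when the parallel-preference bias is
#' on) near-parallel local strand directions.
#'
#' @param structure Bead tibble (or state) in topology order.
#' @param topology The `peptide_topology`.
#' @param nh,co Bead indices of the NH and CO beads.
#' @param table An `interaction_table`.
#' @param occupied Integer vector of bead indices already committed to a
#'   hydrogen bond.
#' @param box Optional box edge for minimum-image distances.
#' @return Logical.
#' @export
hb_eligible <- function(structure, topology, nh, co,
                        table = default_forcefield(),
                        occupied = integer(0), box = NULL) {
  beads <- structure_beads(structure)
  if (beads$bead[nh] != "NH" || beads$bead[co] != "CO") {
    abort("hb_eligible expects an NH bead and a CO bead, in that order")
  }
  if (nh %in% occupied || co %in% occupied) return(FALSE)
  xyz <- structure_xyz(structure)
  lk <- bead_index_lookup(beads)
  hb_geometry_ok(beads, xyz, lk, nh, co, table, box = box)
}

#' Geometric hydrogen-bond assignment
#'
#' Assigns backbone hydrogen bonds to a static configuration: all NH-CO
#' pairs satisfying the eligibility criteria are collected and greedily
#' committed in order of increasing distance under single occupancy per NH
#' and per CO.
#'
#' @inheritParams check_constraints
#' @return Tibble with columns `nh`, `co` (bead indices), `dist`,
#'   `chain_nh`, `res_nh`, `chain_co`, `res_co`.
#' @export
assign_hbonds <- function(structure, topology, table = default_forcefield(),
                          box = NULL) {
  beads <- structure_beads(structure)
  xyz <- structure_xyz(structure)
  lk <- bead_index_lookup(beads)
  D <- pair_dist_matrix(xyz, box)
  nh_idx <- beads$index[beads$bead == "NH"]
  co_idx <- beads$index[beads$bead == "CO"]
  sub <- D[nh_idx, co_idx, drop = FALSE]
  cand <- which(sub <= table$hb_range & sub >= table$hb_core,
                arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble(nh = integer(0), co = integer(0), dist = numeric(0),
                  chain_nh = integer(0), res_nh = integer(0),
                  chain_co = integer(0), res_co = integer(0)))
  }
  nh <- nh_idx[cand[, 1]]; co <- co_idx[cand[, 2]]
  d <- sub[cand]
  ord <- order(d, nh, co)
  nh <- nh[ord]; co <- co[ord]; d <- d[ord]
  taken <- rep(FALSE, nrow(beads))
  keep <- logical(length(nh))
  for (k in seq_along(nh)) {
    if (taken[nh[k]] || taken[co[k]]) next
    if (hb_geometry_ok(beads, xyz, lk, nh[k], co[k], table, D = D)) {
      keep[k] <- TRUE
      taken[nh[k]] <- TRUE; taken[co[k]] <- TRUE
    }
  }
  nh_k <- nh[keep]; co_k <- co[keep]
  tibble(nh = nh_k, co = co_k, dist = d[keep],
         chain_nh = beads$chain[nh_k], res_nh = beads$residue[nh_k],
         chain_co = beads$chain[co_k], res_co = beads$residue[co_k])
}

#' Total interaction energy of a configuration
#'
#' Sums the square-well energies of all side-chain pairs at their current
#' separations (with the salt-bridge enhancement where applicable) plus
#' -epsilon_HB per assigned backbone hydrogen bond.  Reported in epsilon_HB
#' units; negative for bound systems.
#'
#' @inheritParams check_constraints
#' @param hbonds Optional precomputed hydrogen-bond table (from
#'   [assign_hbonds()] or a simulation registry); computed geometrically
#'   when `NULL`.
#' @return Energy in epsilon_HB units (scalar).
#' @export
total_energy <- function(structure, topology, table = default_forcefield(),
                         box = NULL, hbonds = NULL) {
  beads <- structure_beads(structure)
  xyz <- structure_xyz(structure)
  viol <- check_constraints(structure, topology, table, box = box)
  if (any(viol$type %in% c("core", "squeeze") &
          viol$dist < viol$limit - 1e-6)) {
    abort("hard-core overlap: configuration is inconsistent with the table",
          class = "fibril_inconsistent_state")
  }
  sc <- beads[beads$bead == "SC", ]
  e_sc <- 0
  if (nrow(sc) > 1) {
    D <- pair_dist_matrix(xyz[sc$index, , drop = FALSE], box)
    ut <- which(upper.tri(D), arr.ind = TRUE)
    same_chain <- sc$chain[ut[, 1]] == sc$chain[ut[, 2]]
    dres <- abs(sc$residue[ut[, 1]] - sc$residue[ut[, 2]])
    ok <- !(same_chain & dres <= 1)
    aa_a <- sc$aa[ut[, 1]]; aa_b <- sc$aa[ut[, 2]]
    depth <- table$sc_wells$depth[cbind(aa_a, aa_b)]
    range1 <- table$sc_wells$range[cbind(aa_a, aa_b)]
    # salt-bridge enhancement
    sb <- table$salt_bridge
    res_a <- sc$residue[ut[, 1]]; res_b <- sc$residue[ut[, 2]]
    hit <- (aa_a == sb$aa_a & res_a == sb$res_a &
              aa_b == sb$aa_b & res_b == sb$res_b) |
      (aa_b == sb$aa_a & res_b == sb$res_a &
         aa_a == sb$aa_b & res_a == sb$res_b)
    depth[hit] <- depth[hit] * sb$factor
    d <- D[ut]
    inside1 <- ok & d <= range1
    e_sc <- -sum(depth[inside1])
    if (!is.null(table$sc_wells$range2)) {
      depth2 <- table$sc_wells$depth2[cbind(aa_a, aa_b)]
      range2 <- table$sc_wells$range2[cbind(aa_a, aa_b)]
      inside2 <- ok & !inside1 & d <= range2 & depth2 != 0
      e_sc <- e_sc - sum(depth2[inside2])
    }
  }
  if (is.null(hbonds)) {
    hbonds <- assign_hbonds(structure, topology, table, box = box)
  }
  e_sc - table$eps_hb * nrow(hbonds)
}
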