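# Interaction tables: geometry, squeeze constraints, square wells, hydrogen
# bonding, salt-bridge enhancement and the parallel-preference gate.

#' Build the package's default interaction table in code
#'
#' Constructs the default coarse-grained parameter set: per-bead hard
#' diameters, CA-to-side-chain geometry, squeeze factor, the 20x20
#' square-well matrix (hydrophobicity-weighted depths plus opposite-charge
#' attraction), and the hydrogen-bond parameters with the D23-K28 salt-bridge
#' enhancement and parallel-preference gate.  The shipped YAML tables under
#' `inst/extdata/forcefield` are a serialization of this object.
#'
#' @param sc_alpha Elevation angle (radians) of the side-chain centroid above
#'   the NH-CA-CO plane.
#' @param well_scale Prefactor of the hydrophobic well depths (epsilon_HB).
#' @param charge_depth Extra depth for oppositely charged side-chain pairs.
#' @param well_lambda Well range as a multiple of the pair hard diameter.
#' @return An `interaction_table` object.
#' @keywords internal
build_default_table <- function(sc_alpha = SC_ALPHA_DEFAULT,
                                well_scale = 0.30,
                                charge_depth = 0.35,
                                well_lambda = 1.5) {
  n <- length(AA_CODES)
  h <- AA_HYDRO[AA_CODES]
  q <- AA_CHARGE[AA_CODES]
  sig <- AA_SC_DIAMETER[AA_CODES]

  depth <- outer(h, h, function(a, b) well_scale * sqrt(a * b))
  qprod <- outer(q, q)
  depth[qprod < 0] <- depth[qprod < 0] + charge_depth
  depth[qprod > 0] <- 0
  depth <- round(depth, 4)
  range <- round(well_lambda * outer(sig, sig, function(a, b) (a + b) / 2), 4)
  dimnames(depth) <- dimnames(range) <- list(AA_CODES, AA_CODES)

  sc_nh <- sc_co <- numeric(n)
  fr <- residue_frame()
  for (i in seq_len(n)) {
    sc <- sc_in_frame(AA_SC_CA_DIST[AA_CODES[i]], sc_alpha)
    sc_nh[i] <- sqrt(sum((sc - fr$nh)^2))
    sc_co[i] <- sqrt(sum((sc - fr$co)^2))
  }
  tab <- list(
    schema_version = 1L,
    bead_diameters = BB_DIAMETER,
    sc_diameters = sig,
    sc_ca_dist = AA_SC_CA_DIST[AA_CODES],
    sc_nh_dist = round(setNames(sc_nh, AA_CODES), 4),
    sc_co_dist = round(setNames(sc_co, AA_CODES), 4),
    sc_alpha = round(sc_alpha, 6),
    bonds = BB_BONDS,
    bond_delta = 0.025,
    sc_bond_delta = 0.01,
    squeeze_factor = 0.75,
    sc_wells = list(depth = depth, range = range,
                    depth2 = NULL, range2 = NULL),
    eps_hb = 1,
    hb_range = 4.5,
    hb_core = round(mean(BB_DIAMETER[c("NH", "CO")]), 4),
    hb_aux_min = 4.5,
    hb_min_seq_sep = 4L,
    salt_bridge = list(res_a = 23L, aa_a = "D", res_b = 28L, aa_b = "K",
                       factor = 2),
    parallel_preference = TRUE,
    parallel_threshold = round(pi / 2, 6),
    mass = 1)
  class(tab) <- "interaction_table"
  validate_forcefield(tab)
}

#' Validate an interaction table
#'
#' Checks symmetry of the well matrices, positivity of all geometric
#' distances, and that every well range exceeds the corresponding hard
#' diameter.  Validation failures name the offending amino-acid pair.
#'
#' @param table An `interaction_table` (or plain list with the same fields).
#' @return The validated table, invisibly classed as `interaction_table`.
#' @export
validate_forcefield <- function(table) {
  need <- c("bead_diameters", "sc_diameters", "sc_ca_dist", "sc_nh_dist",
            "sc_co_dist", "bonds", "bond_delta", "sc_bond_delta",
            "squeeze_factor",
            "sc_wells", "eps_hb", "hb_range", "hb_core", "hb_aux_min",
            "hb_min_seq_sep", "salt_bridge", "parallel_preference",
            "parallel_threshold")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    abort(paste0("interaction table is missing entries: ",
                 paste(miss, collapse = ", ")))
  }
  if (any(table$bead_diameters <= 0) || any(table$sc_diameters <= 0)) {
    abort("all hard-sphere diameters must be positive")
  }
  if (any(table$bonds <= 0)) abort("all bond lengths must be positive")
  if (table$bond_delta <= 0 || table$bond_delta >= 0.1) {
    abort("bond_delta must lie in (0, 0.1)")
  }
  if (table$sc_bond_delta <= 0 || table$sc_bond_delta > table$bond_delta) {
    abort("sc_bond_delta must lie in (0, bond_delta]")
  }
  if (table$squeeze_factor <= 0 || table$squeeze_factor > 1) {
    abort("squeeze_factor must lie in (0, 1]")
  }
  for (mn in c("depth", "range")) {
    m <- table$sc_wells[[mn]]
    if (!is.matrix(m) || !identical(dim(m), c(20L, 20L))) {
      abort(paste0("sc_wells$", mn, " must be a 20x20 matrix"))
    }
    bad <- which(abs(m - t(m)) > 1e-12, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- bad[1, 1]; j <- bad[1, 2]
      abort(paste0("sc_wells$", mn, " is not symmetric at pair ",
                   AA_CODES[i], "-", AA_CODES[j]))
    }
  }
  sig <- outer(table$sc_diameters, table$sc_diameters,
               function(a, b) (a + b) / 2)
  bad <- which(table$sc_wells$range <= sig, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    abort(paste0("well range does not exceed the hard diameter for pair ",
                 AA_CODES[i], "-", AA_CODES[j]))
  }
  if (any(table$sc_wells$range <= 0)) abort("well ranges must be positive")
  if (!is.null(table$sc_wells$range2)) {
    if (is.null(table$sc_wells$depth2)) {
      abort("sc_wells$range2 given without sc_wells$depth2")
    }
    bad <- which(table$sc_wells$range2 <= table$sc_wells$range,
                 arr.ind = TRUE)
    bad <- bad[table$sc_wells$depth2[bad] != 0, , drop = FALSE]
    if (length(bad) > 0 && nrow(bad) > 0) {
      i <- bad[1, 1]; j <- bad[1, 2]
      abort(paste0("outer well range must exceed the inner range for pair ",
                   AA_CODES[i], "-", AA_CODES[j]))
    }
  }
  if (table$hb_range <= table$hb_core) {
    abort("hb_range must exceed hb_core")
  }
  if (table$eps_hb <= 0) abort("eps_hb must be positive")
  if (table$salt_bridge$factor < 1) {
    abort("salt_bridge factor must be >= 1")
  }
  class(table) <- "interaction_table"
  table
}

#' Load interaction parameter tables from YAML config files
#'
#' Reads the geometry table (bead diameters, bond lengths, side-chain
#' anchoring distances, squeeze factor, hydrogen-bond and bias parameters)
#' and the 20x20 side-chain square-well matrices, validates them, and
#' returns an `interaction_table`.
#'
#' @param geometry Path to the geometry YAML file.
#' @param wells Path to the well-matrix YAML file.
#' @return A validated `interaction_table`.
#' @seealso [default_forcefield()], [write_forcefield()]
#' @export
load_forcefield <- function(geometry = fibril_config("geometry.yaml"),
                            wells = fibril_config("wells.yaml")) {
  g <- yaml::read_yaml(geometry)
  w <- yaml::read_yaml(wells)
  as_mat <- function(x, what) {
    if (is.null(x)) return(NULL)
    m <- do.call(rbind, lapply(x, function(row) unlist(row)))
    if (!identical(dim(m), c(20L, 20L))) {
      abort(paste0(what, " in ", wells, " is not a 20x20 matrix"))
    }
    dimnames(m) <- list(AA_CODES, AA_CODES)
    m
  }
  tab <- list(
    schema_version = as.integer(g$schema_version),
    bead_diameters = unlist(g$bead_diameters)[c("NH", "CA", "CO")],
    sc_diameters = unlist(g$sc_diameters)[AA_CODES],
    sc_ca_dist = unlist(g$sc_ca_dist)[AA_CODES],
    sc_nh_dist = unlist(g$sc_nh_dist)[AA_CODES],
    sc_co_dist = unlist(g$sc_co_dist)[AA_CODES],
    sc_alpha = g$sc_alpha,
    bonds = unlist(g$bonds)[names(BB_BONDS)],
    bond_delta = g$bond_delta,
    sc_bond_delta = if (is.null(g$sc_bond_delta)) 0.01 else g$sc_bond_delta,
    squeeze_factor = g$squeeze_factor,
    sc_wells = list(depth = as_mat(w$depth, "depth"),
                    range = as_mat(w$range, "range"),
                    depth2 = as_mat(w$depth2, "depth2"),
                    range2 = as_mat(w$range2, "range2")),
    eps_hb = g$eps_hb,
    hb_range = g$hb_range,
    hb_core = g$hb_core,
    hb_aux_min = g$hb_aux_min,
    hb_min_seq_sep = as.integer(g$hb_min_seq_sep),
    salt_bridge = list(res_a = as.integer(g$salt_bridge$res_a),
                       aa_a = g$salt_bridge$aa_a,
                       res_b = as.integer(g$salt_bridge$res_b),
                       aa_b = g$salt_bridge$aa_b,
                       factor = g$salt_bridge$factor),
    parallel_preference = isTRUE(g$parallel_preference),
    parallel_threshold = g$parallel_threshold,
    mass = if (is.null(g$mass)) 1 else g$mass)
  if (anyNA(unlist(tab[c("bead_diameters", "sc_diameters", "sc_ca_dist",
                         "sc_nh_dist", "sc_co_dist", "bonds")]))) {
    abort("geometry config is missing amino-acid or bond entries")
  }
  validate_forcefield(tab)
}

#' Write an interaction table to YAML config files
#'
#' Inverse of [load_forcefield()]: serializes the geometry and well-matrix
#' components so that loading them back reproduces the table exactly.
#'
#' @param table An `interaction_table`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_forcefield <- function(table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat_list <- function(m) {
    if (is.null(m)) return(NULL)
    lapply(seq_len(nrow(m)), function(i) as.list(setNames(m[i, ], AA_CODES)))
  }
  g <- list(
    schema_version = table$schema_version,
    bead_diameters = as.list(table$bead_diameters),
    sc_diameters = as.list(table$sc_diameters),
    sc_ca_dist = as.list(table$sc_ca_dist),
    sc_nh_dist = as.list(table$sc_nh_dist),
    sc_co_dist = as.list(table$sc_co_dist),
    sc_alpha = table$sc_alpha,
    bonds = as.list(table$bonds),
    bond_delta = table$bond_delta,
    sc_bond_delta = table$sc_bond_delta,
    squeeze_factor = table$squeeze_factor,
    eps_hb = table$eps_hb,
    hb_range = table$hb_range,
    hb_core = table$hb_core,
    hb_aux_min = table$hb_aux_min,
    hb_min_seq_sep = table$hb_min_seq_sep,
    salt_bridge = table$salt_bridge,
    parallel_preference = table$parallel_preference,
    parallel_threshold = table$parallel_threshold,
    mass = table$mass)
  w <- list(depth = mat_list(table$sc_wells$depth),
            range = mat_list(table$sc_wells$range),
            depth2 = mat_list(table$sc_wells$depth2),
            range2 = mat_list(table$sc_wells$range2))
  w <- w[!vapply(w, is.null, TRUE)]
  yaml::write_yaml(g, file.path(dir, "geometry.yaml"))
  yaml::write_yaml(w, file.path(dir, "wells.yaml"))
  invisible(dir)
}

#' Path to a shipped configuration file
#' @param file File name under `inst/extdata/forcefield`.
#' @return Absolute path.
#' @export
fibril_config <- function(file) {
  p <- system.file("extdata", "forcefield", file, package = "fibrildmd")
  if (p == "") abort(paste0("shipped config not found: ", file))
  p
}

#' Default interaction table
#'
#' Loads (and caches) the package's shipped parameter set.
#'
#' @return An `interaction_table`.
#' @export
default_forcefield <- function() {
  if (is.null(.fibril_cache$default_table)) {
    .fibril_cache$default_table <- load_forcefield()
  }
  .fibril_cache$default_table
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table>\n")
  cat("  eps_hb:", x$eps_hb, " hb_range:", x$hb_range, "A\n")
  cat("  salt bridge:", x$salt_bridge$aa_a, x$salt_bridge$res_a, "-",
      x$salt_bridge$aa_b, x$salt_bridge$res_b, "factor", x$salt_bridge$factor,
      "\n")
  cat("  parallel preference:", x$parallel_preference, "\n")
  cat("  bond tolerance:", x$bond_delta, " squeeze factor:",
      x$squeeze_factor, "\n")
  invisible(x)
}

# hard diameter between two beads identified by (kind, aa)
pair_hard_diameter <- function(kind_a, aa_a, kind_b, aa_b, table) {
  d_of <- function(kind, aa) {
    if (kind == "SC") table$sc_diameters[[aa]] else table$bead_diameters[[kind]]
  }
  (d_of(kind_a, aa_a) + d_of(kind_b, aa_b)) / 2
}

#' Effective square-well depth for a bead pair
#'
#' Returns the side-chain well depth for an amino-acid pair, multiplied by the
#' salt-bridge enhancement factor when the two beads are the designated
#' salt-bridge partners (by default the D23 and K28 side chains, on any two
#' chains or within one chain).
#'
#' @param aa_a,aa_b One-letter amino-acid codes of the two side chains.
#' @param res_a,res_b Residue numbers of the two beads.
#' @param table An `interaction_table`.
#' @return Well depth in units of epsilon_HB.
#' @export
effective_well_depth <- function(aa_a, res_a, aa_b, res_b,
                                 table = default_forcefield()) {
  base <- table$sc_wells$depth[aa_a, aa_b]
  sb <- table$salt_bridge
  hit <- (aa_a == sb$aa_a && res_a == sb$res_a &&
            aa_b == sb$aa_b && res_b == sb$res_b) ||
    (aa_b == sb$aa_a && res_b == sb$res_a &&
       aa_a == sb$aa_b && res_a == sb$res_b)
  if (hit) base * sb$factor else base
}

#' Piecewise-constant pair potential
#'
#' Energy level and discontinuity radii for a pair of beads at a given
#' separation, under the square-well / hard-sphere model.  Bonded pairs are
#' described by their two hard walls; side-chain pairs by their hard core and
#' well step(s); candidate hydrogen-bond pairs (NH-CO) by core plus the HB
#' well; all other pairs by the hard core alone.  Side-chain beads against
#' backbone beads of the same or adjacent residue use the reduced squeeze
#' distance as their core.
#'
#' @param bead_a,bead_b Lists (or one-row data frames) with fields `kind`,
#'   `aa`, `chain`, `residue`.
#' @param separation Centre distance in Angstrom (> 0).
#' @param table An `interaction_table`.
#' @param bonded One of `"none"`, or an ideal bond length (numeric) if the
#'   pair is bonded.
#' @return A list with `energy` (epsilon_HB units; `Inf` inside a forbidden
#'   region) and `radii`, the increasing vector of discontinuity radii at or
#'   beyond `separation` (outward discontinuities).
#' @export
pair_step_potential <- function(bead_a, bead_b, separation,
                                table = default_forcefield(),
                                bonded = "none") {
  if (separation <= 0) abort("separation must be positive")
  a <- as.list(bead_a); b <- as.list(bead_b)
  if (!identical(bonded, "none")) {
    l <- as.numeric(bonded)
    lo <- l * (1 - table$bond_delta); hi <- l * (1 + table$bond_delta)
    if (separation < lo || separation > hi) {
      return(list(energy = Inf, radii = numeric(0)))
    }
    return(list(energy = 0, radii = hi))
  }
  same_chain <- identical(a$chain, b$chain)
  dres <- if (same_chain) abs(a$residue - b$residue) else Inf
  core <- pair_hard_diameter(a$kind, a$aa, b$kind, b$aa, table)
  squeeze <- same_chain && dres <= 1
  if (squeeze) core <- core * table$squeeze_factor

  radii <- core
  levels <- c(Inf, 0)
  if (!squeeze && a$kind == "SC" && b$kind == "SC") {
    d1 <- effective_well_depth(a$aa, a$residue, b$aa, b$residue, table)
    r1 <- table$sc_wells$range[a$aa, b$aa]
    if (d1 != 0) {
      radii <- c(core, r1); levels <- c(Inf, -d1, 0)
      if (!is.null(table$sc_wells$range2)) {
        d2 <- table$sc_wells$depth2[a$aa, b$aa]
        r2 <- table$sc_wells$range2[a$aa, b$aa]
        if (d2 != 0) {
          radii <- c(core, r1, r2); levels <- c(Inf, -d1, -d2, 0)
        }
      }
    }
  }
  kinds <- sort(c(a$kind, b$kind))
  if (!squeeze && identical(kinds, c("CO", "NH")) &&
      (!same_chain || dres >= table$hb_min_seq_sep)) {
    radii <- c(table$hb_core, table$hb_range)
    levels <- c(Inf, -table$eps_hb, 0)
  }
  idx <- findInterval(separation, radii) + 1L
  list(energy = levels[idx], radii = radii[radii >= separation])
}

# squeeze (minimum non-bonded) distance between a side chain and a
# neighbouring backbone bead
squeeze_distance <- function(aa, backbone_kind, table = default_forcefield()) {
  table$squeeze_factor *
    (table$sc_diameters[[aa]] + table$bead_diameters[[backbone_kind]]) / 2
}
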