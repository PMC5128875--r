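# Structure-analysis layer: intra-peptide CA distance profiles, the Pearson
# similarity statistic, polymorph classification, in-register scoring,
# secondary-structure content, oligomer clustering, frame averaging and
# population heat maps.

#' Long-range CA pair index set
#'
#' All residue pairs `(i, j)` with `start <= i < j <= end` and
#' `j - i >= min_separation`.  The default separation of 5 encodes pairs
#' "separated by more than 4 residues".
#'
#' @param start,end Inclusive residue range.
#' @param min_separation Minimum residue separation.
#' @return Tibble with columns `i`, `j`, ordered by `(i, j)`.
#' @examples
#' nrow(ca_pairs(17, 40))  # 190
#' nrow(ca_pairs(17, 42))  # 231
#' @export
ca_pairs <- function(start, end, min_separation = 5L) {
  if (end < start) abort("end must be >= start")
  res <- seq.int(start, end)
  g <- expand.grid(i = res, j = res)
  g <- g[g$j - g$i >= min_separation, c("i", "j")]
  g <- g[order(g$i, g$j), ]
  as_tibble(g)
}

#' Chain-averaged intra-peptide CA distance profile
#'
#' For every long-range residue pair, the CA-CA distance within a chain,
#' averaged over all chains of the structure.  Invariant under rigid-body
#' motion of the structure.
#'
#' @param structure Bead tibble with CA beads covering the residue range on
#'   every chain (any other beads are ignored).
#' @param range Inclusive residue range `c(start, end)`.
#' @param min_separation Minimum residue separation (default 5).
#' @return A `distance_profile`: tibble with `i`, `j`, `dist` and
#'   attributes `range`, `min_separation`, `n_chains`.
#' @export
distance_profile <- function(structure, range = c(17, 42),
                             min_separation = 5L) {
  beads <- structure_beads(structure)
  ca <- beads[beads$bead == "CA", ]
  res <- seq.int(range[1], range[2])
  pairs <- ca_pairs(range[1], range[2], min_separation)
  chains <- unique(ca$chain)
  acc <- matrix(0, nrow(pairs), length(chains))
  for (k in seq_along(chains)) {
    cc <- ca[ca$chain == chains[k], ]
    miss <- setdiff(res, cc$residue)
    if (length(miss) > 0) {
      abort(paste0("chain ", chains[k], " is missing residue(s) ",
                   paste(head(miss, 3), collapse = ", "),
                   " in range ", range[1], "-", range[2]),
            class = "fibril_missing_data")
    }
    xyz <- as.matrix(cc[match(res, cc$residue), c("x", "y", "z")])
    d <- xyz[match(pairs$i, res), ] - xyz[match(pairs$j, res), ]
    acc[, k] <- sqrt(rowSums(d^2))
  }
  out <- pairs
  out$dist <- rowMeans(acc)
  structure(out, range = range, min_separation = min_separation,
            n_chains = length(chains), class = c("distance_profile",
                                                 class(out)))
}

#' Pearson similarity between two distance profiles
#'
#' The Pearson correlation coefficient between the two profiles' distance
#' vectors: one covariance over two standard deviations.  A similarity of 1
#' means identical intra-peptide distance patterns.
#'
#' @param profile_a,profile_b `distance_profile`s over identical pair sets.
#' @param reference_id Optional label for the reference profile.
#' @return A `similarity_score`: list with `r`, `reference_id`, `range`,
#'   `n_pairs`.
#' @export
pearson_similarity <- function(profile_a, profile_b, reference_id = NULL) {
  if (!identical(cbind(profile_a$i, profile_a$j),
                 cbind(profile_b$i, profile_b$j))) {
    abort("profiles are over different pair sets")
  }
  if (nrow(profile_a) < 3) abort("need at least 3 pairs")
  va <- var(profile_a$dist); vb <- var(profile_b$dist)
  if (va == 0 || vb == 0) {
    abort("similarity undefined: a profile has zero variance",
          class = "fibril_undefined_score")
  }
  structure(list(r = cor(profile_a$dist, profile_b$dist),
                 reference_id = reference_id,
                 range = attr(profile_a, "range"),
                 n_pairs = nrow(profile_a)),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat("<similarity_score> r = ", formatC(x$r, digits = 4),
      if (!is.null(x$reference_id)) paste0(" vs ", x$reference_id),
      " (", x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

#' Reference profile library for polymorph classification
#'
#' Distance profiles of the idealized conformer templates (U, S1, S2, S3,
#' D1, D2 eight-chain stacks and the three-chain beta-helix) at zero jitter.
#' User-supplied reference structures (e.g. read from PDB files) can be
#' appended as additional rows.
#'
#' @param range Residue range of the profiles.
#' @param min_separation Minimum residue separation.
#' @param n_chains Chains per fibrillar template.
#' @return Tibble with columns `class` and `profile` (list column).
#' @export
reference_library <- function(range = c(17, 42), min_separation = 5L,
                              n_chains = 8L) {
  key <- paste0("reflib_", range[1], "_", range[2], "_", min_separation,
                "_", n_chains)
  if (!is.null(.fibril_cache[[key]])) return(.fibril_cache[[key]])
  classes <- c("U", "S1", "S2", "S3", "D1", "D2")
  profs <- lapply(classes, function(cl) {
    distance_profile(make_fibril(cl, n_chains), range, min_separation)
  })
  bh <- distance_profile(make_beta_helix(3L), range, min_separation)
  lib <- tibble(class = c(classes, "BH"), profile = c(profs, list(bh)))
  .fibril_cache[[key]] <- lib
  lib
}

#' In-register score of a stacked structure
#'
#' Fraction of inter-chain backbone hydrogen bonds that join equivalent
#' residue positions under parallel in-register stacking.  In this model's
#' backbone geometry the amide of residue `i` donates to the carbonyl of
#' residue `i - 1` on the neighbour chain, so an inter-chain bond is
#' in-register when `res(NH) - res(CO) = 1`; a stack shifted by one CA
#' position scores 0.
#'
#' @param structure Bead tibble (full backbone required).
#' @param table Interaction table (hydrogen-bond criteria).
#' @param hbonds Optional precomputed bond table ([assign_hbonds()] format
#'   or a state registry with `nh`, `co` columns).
#' @param box Optional box edge.
#' @return Fraction in `[0, 1]`, with attribute `n_hb` (number of
#'   inter-chain bonds).  `NA` (flagged by `n_hb = 0`) when the structure
#'   has no inter-chain hydrogen bonds.
#' @export
in_register_score <- function(structure, table = default_forcefield(),
                              hbonds = NULL, box = NULL) {
  beads <- structure_beads(structure)
  if (is.null(hbonds)) {
    topo <- attr(structure, "topology")
    hbonds <- assign_hbonds(structure, topo, table, box = box)
  }
  if (!("chain_nh" %in% names(hbonds))) {
    hbonds$chain_nh <- beads$chain[hbonds$nh]
    hbonds$chain_co <- beads$chain[hbonds$co]
    hbonds$res_nh <- beads$residue[hbonds$nh]
    hbonds$res_co <- beads$residue[hbonds$co]
  }
  inter <- hbonds[hbonds$chain_nh != hbonds$chain_co, ]
  if (nrow(inter) == 0) {
    return(structure(NA_real_, n_hb = 0L))
  }
  structure(mean(inter$res_nh - inter$res_co == 1L),
            n_hb = nrow(inter))
}

#' Cluster chains by inter-chain contacts
#'
#' Connected components of the chain-contact graph: two chains are in
#' contact when at least `min_contacts` of their bead pairs are within
#' `cutoff`.
#'
#' @param structure Bead tibble.
#' @param cutoff Contact distance in Angstrom.
#' @param min_contacts Minimum number of bead-pair contacts.
#' @param box Optional box edge (minimum image).
#' @return Tibble with `chain` and `cluster` (1 = largest), plus attribute
#'   `sizes` (descending cluster sizes).
#' @export
cluster_chains <- function(structure, cutoff = 6.5, min_contacts = 3L,
                           box = NULL) {
  beads <- structure_beads(structure)
  chains <- unique(beads$chain)
  nc <- length(chains)
  if (nc == 1) {
    out <- tibble(chain = chains, cluster = 1L)
    attr(out, "sizes") <- 1L
    return(out)
  }
  xyz <- structure_xyz(structure)
  D <- pair_dist_matrix(xyz, box)
  edges <- NULL
  for (a in seq_len(nc - 1)) {
    ia <- which(beads$chain == chains[a])
    for (b in (a + 1):nc) {
      ib <- which(beads$chain == chains[b])
      if (sum(D[ia, ib] <= cutoff) >= min_contacts) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  g <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)
  sizes <- sort(comp$csize, decreasing = TRUE)
  rank <- match(comp$membership, order(comp$csize, decreasing = TRUE))
  out <- tibble(chain = chains, cluster = rank)
  attr(out, "sizes") <- sizes
  out
}

#' Classify a structure into a polymorph class
#'
#' Computes the chain-averaged distance profile of the largest chain
#' cluster and compares it against the reference library.  The class of the
#' best-matching reference is assigned when its similarity exceeds the
#' fibrillar threshold; a cluster whose chains individually match two
#' different classes (at least `hybrid_min_chains` chains each) is a
#' hybrid; small aggregates are labelled `"M+SO"` (monomer / small
#' oligomer); everything else is disordered.
#'
#' @param structure Bead tibble.
#' @param reference Reference library tibble ([reference_library()]).
#' @param energy Optional total interaction energy to report.
#' @param threshold Fibrillar similarity threshold (default 0.8, the
#'   heat-map red-region boundary).
#' @param in_register_threshold Score above which the stack counts as
#'   in-register.
#' @param min_fibril_chains Smallest cluster size eligible for a fibrillar
#'   class.
#' @param hybrid_min_chains Smallest sub-aggregate size considered in
#'   hybrid detection.
#' @param range,min_separation Profile settings (must match the library).
#' @param table Interaction table (hydrogen bonds for the register score).
#' @param cutoff,min_contacts Contact definition for chain clustering.
#' @param box Optional box edge.
#' @return A `structure_label`: list with `class`, `in_register`,
#'   `scores` (tibble: reference class vs r), `energy`, `cluster_sizes`,
#'   `chain_classes`.
#' @export
classify_structure <- function(structure, reference = reference_library(
                                 range, min_separation),
                               energy = NULL, threshold = 0.8,
                               in_register_threshold = 0.9,
                               min_fibril_chains = 3L,
                               hybrid_min_chains = 3L,
                               range = c(17, 42), min_separation = 5L,
                               table = default_forcefield(),
                               cutoff = 6.5, min_contacts = 3L,
                               box = NULL) {
  if (nrow(reference) == 0) {
    abort("empty reference library", class = "fibril_config_error")
  }
  beads <- structure_beads(structure)
  cl <- cluster_chains(structure, cutoff, min_contacts, box)
  sizes <- attr(cl, "sizes")
  big <- cl$chain[cl$cluster == 1]
  score_profile <- function(prof) {
    vapply(reference$profile, function(ref) {
      pearson_similarity(prof, ref)$r
    }, numeric(1))
  }
  label <- function(class, in_register = FALSE, scores = NULL,
                    chain_classes = NULL) {
    structure(list(class = class, in_register = in_register,
                   scores = scores, energy = energy,
                   cluster_sizes = sizes, chain_classes = chain_classes),
              class = "structure_label")
  }
  if (sizes[1] < min_fibril_chains) {
    return(label("M+SO"))
  }
  sub <- beads[beads$chain %in% big, ]
  prof <- distance_profile(sub, range, min_separation)
  r <- score_profile(prof)
  scores <- tibble(reference = reference$class, r = r)
  # per-chain matches for hybrid detection
  chain_cls <- vapply(big, function(ch) {
    p <- distance_profile(beads[beads$chain == ch, ], range, min_separation)
    rr <- score_profile(p)
    if (max(rr) >= threshold) reference$class[which.max(rr)] else
      NA_character_
  }, character(1))
  tabcls <- base::table(chain_cls[!is.na(chain_cls)])
  major <- names(tabcls)[tabcls >= hybrid_min_chains]
  if (length(major) >= 2) {
    return(label("hybrid", scores = scores,
                 chain_classes = tibble(chain = big, class = chain_cls)))
  }
  if (max(r) >= threshold) {
    irs <- in_register_score(structure, table, box = box)
    ir <- !is.na(irs) && irs >= in_register_threshold
    return(label(reference$class[which.max(r)], in_register = ir,
                 scores = scores,
                 chain_classes = tibble(chain = big, class = chain_cls)))
  }
  label("disordered", scores = scores,
        chain_classes = tibble(chain = big, class = chain_cls))
}

#' @export
print.structure_label <- function(x, ...) {
  cat("<structure_label> class:", x$class,
      if (isTRUE(x$in_register)) "(in-register)", "\n")
  if (!is.null(x$scores)) {
    best <- x$scores[order(-x$scores$r), ]
    cat("  best matches:",
        paste0(head(best$reference, 3), " (r=",
               formatC(head(best$r, 3), digits = 3), ")",
               collapse = ", "), "\n")
  }
  if (!is.null(x$energy)) cat("  energy:", x$energy, "eps_HB\n")
  invisible(x)
}

#' Secondary-structure content
#'
#' Per-residue assignment from CA pseudo-dihedral windows plus the backbone
#' hydrogen-bond pattern: a residue is helical when a CA(i)..CA(i+3)
#' distance window is helix-like; it is a beta-strand when its local
#' backbone is extended *and* the residue participates in a backbone
#' hydrogen bond; everything else (including chain termini outside the
#' windows) is coil/turn.
#'
#' @param structure Bead tibble.
#' @param table Interaction table.
#' @param helix_cut CA(i)-CA(i+3) distance below which the window is
#'   helix-like (Angstrom).
#' @param extend_cut CA(i)-CA(i+2) distance above which the backbone is
#'   extended (Angstrom).
#' @param hbonds Optional precomputed hydrogen-bond table.
#' @param box Optional box edge.
#' @return Tibble with one row: `alpha`, `beta`, `coil` (fractions summing
#'   to 1).
#' @export
secondary_structure_fractions <- function(structure,
                                          table = default_forcefield(),
                                          helix_cut = 6.5,
                                          extend_cut = 6.0,
                                          hbonds = NULL, box = NULL) {
  beads <- structure_beads(structure)
  if (is.null(hbonds)) {
    topo <- attr(structure, "topology")
    if (is.null(topo)) {
      abort("structure lacks a topology attribute; pass hbonds explicitly")
    }
    hbonds <- assign_hbonds(structure, topo, table, box = box)
  }
  hb_res <- unique(rbind(
    data.frame(chain = beads$chain[hbonds$nh],
               residue = beads$residue[hbonds$nh]),
    data.frame(chain = beads$chain[hbonds$co],
               residue = beads$residue[hbonds$co])))
  ca <- beads[beads$bead == "CA", ]
  n_alpha <- n_beta <- n_coil <- 0L
  for (ch in unique(ca$chain)) {
    cc <- ca[ca$chain == ch, ]
    cc <- cc[order(cc$residue), ]
    xyz <- as.matrix(cc[, c("x", "y", "z")])
    nr <- nrow(cc)
    dwin <- function(i, k) {
      if (i + k >= 1 && i + k <= nr) {
        sqrt(sum((xyz[i, ] - xyz[i + k, ])^2))
      } else NA_real_
    }
    for (i in seq_len(nr)) {
      h3 <- c(dwin(i, 3L), dwin(i, -3L))
      helix <- any(h3 <= helix_cut, na.rm = TRUE)
      e2 <- c(dwin(i, 2L), dwin(i, -2L))
      extended <- any(e2 >= extend_cut, na.rm = TRUE)
      has_hb <- any(hb_res$chain == ch & hb_res$residue == cc$residue[i])
      if (helix) n_alpha <- n_alpha + 1L
      else if (extended && has_hb) n_beta <- n_beta + 1L
      else n_coil <- n_coil + 1L
    }
  }
  tot <- n_alpha + n_beta + n_coil
  tibble(alpha = n_alpha / tot, beta = n_beta / tot, coil = n_coil / tot)
}

#' Average consecutive frames after rigid superposition
#'
#' Superposes every frame onto the first (Kabsch least-squares rotation
#' after centroid matching) and returns the per-bead mean coordinates.
#'
#' @param frames List of bead tibbles with identical bead order.
#' @param align Superpose frames before averaging?
#' @return A bead tibble (attributes of the first frame preserved).
#' @export
frame_average <- function(frames, align = TRUE) {
  if (length(frames) < 1) abort("need at least one frame")
  ref <- frames[[1]]
  key <- function(f) paste(f$chain, f$residue, f$bead)
  for (f in frames[-1]) {
    if (!identical(key(f), key(ref))) {
      abort("frames have mismatched topologies")
    }
  }
  xyz0 <- as.matrix(ref[, c("x", "y", "z")])
  c0 <- colMeans(xyz0)
  acc <- sweep(xyz0, 2, c0)
  for (f in frames[-1]) {
    xyz <- as.matrix(f[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, colMeans(xyz))
    if (align) {
      R <- kabsch(xyz, sweep(xyz0, 2, c0))
      xyz <- xyz %*% R
    }
    acc <- acc + xyz
  }
  acc <- acc / length(frames)
  out <- ref
  out$x <- acc[, 1] + c0[1]
  out$y <- acc[, 2] + c0[2]
  out$z <- acc[, 3] + c0[3]
  out
}

#' Population heat map over (similarity, energy)
#'
#' Selects the final fraction of frames of every trajectory, scores each
#' frame against a reference profile, and bins the (r, energy) points into
#' a normalized 2-D density.
#'
#' @param frames Tibble with columns `trajectory`, `frame` (ordering within
#'   trajectory), `structure` (list of bead tibbles), `energy`; or
#'   precomputed `r` instead of `structure`.
#' @param reference A `distance_profile` to score against (ignored when
#'   `frames$r` exists).
#' @param tail_fraction Fraction of final frames kept per trajectory.
#' @param r_breaks,e_breaks Bin edges (energy edges default to the data
#'   range).
#' @param range,min_separation Profile settings.
#' @return A `population_heatmap`: list with `density` (matrix, sums to 1),
#'   `r_breaks`, `e_breaks`, `points` (tibble of scored frames).
#' @export
population_heatmap <- function(frames, reference = NULL,
                               tail_fraction = 0.30,
                               r_breaks = seq(-1, 1, by = 0.05),
                               e_breaks = NULL,
                               range = c(17, 42), min_separation = 5L) {
  if (tail_fraction <= 0 || tail_fraction > 1) {
    abort("tail_fraction must be in (0, 1]")
  }
  sel <- frames |>
    group_by(.data$trajectory) |>
    arrange(.data$frame, .by_group = TRUE) |>
    filter(dplyr::row_number() > n() - ceiling(tail_fraction * n())) |>
    ungroup()
  if (nrow(sel) == 0) abort("no frames selected")
  if (!("r" %in% names(sel))) {
    if (is.null(reference)) abort("reference profile required")
    sel$r <- vapply(sel$structure, function(s) {
      pearson_similarity(distance_profile(s, range, min_separation),
                         reference)$r
    }, numeric(1))
  }
  if (is.null(e_breaks)) {
    rng <- range(sel$energy)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    e_breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = 41)
  }
  ri <- cut(sel$r, r_breaks, include.lowest = TRUE, labels = FALSE)
  ei <- cut(sel$energy, e_breaks, include.lowest = TRUE, labels = FALSE)
  dens <- matrix(0, length(r_breaks) - 1, length(e_breaks) - 1)
  for (k in seq_along(ri)) {
    if (!is.na(ri[k]) && !is.na(ei[k])) {
      dens[ri[k], ei[k]] <- dens[ri[k], ei[k]] + 1
    }
  }
  dens <- dens / sum(dens)
  structure(list(density = dens, r_breaks = r_breaks, e_breaks = e_breaks,
                 points = sel[, intersect(c("trajectory", "frame", "r",
                                            "energy"), names(sel))]),
            class = "population_heatmap")
}

#' @export
print.population_heatmap <- function(x, ...) {
  cat("<population_heatmap> ", nrow(x$points), " frames, ",
      nrow(x$density), " x ", ncol(x$density), " bins (density sums to ",
      formatC(sum(x$density), digits = 6), ")\n", sep = "")
  invisible(x)
}
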