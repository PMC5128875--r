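# Peptide topology: beads, bonded constraints and chirality bookkeeping for
# the four-sphere-per-residue representation.

#' Build a coarse-grained peptide topology
#'
#' Expands a one-letter sequence into the four-sphere-per-residue
#' representation: NH, CA and CO united backbone beads plus one side-chain
#' (SC) bead per non-glycine residue.  Returns the bead table, the full
#' bonded-constraint list (bonds and the pseudo-bonds fixing backbone angles
#' and side-chain anchoring), and the per-residue bead quadruples whose
#' signed volume encodes L-isomer handedness.
#'
#' @param sequence One-letter amino-acid string (e.g. [ab1742_sequence()]).
#' @param n_chains Number of identical chains (>= 1).
#' @param first_residue Residue number of the first position (17 for the
#'   Aβ17-42 fragment).
#' @param table Interaction table supplying side-chain anchoring distances
#'   and the bond tolerance.
#' @return A `peptide_topology` list: `sequence`, `n_chains`,
#'   `first_residue`, `beads` (tibble: `index`, `chain`, `residue`, `bead`,
#'   `aa`), `bonds` (tibble: `a`, `b`, `length`, `delta`) and
#'   `chirality` (tibble of NH/CA/CO/SC index quadruples).
#' @examples
#' top <- build_peptide(ab1742_sequence(), 1, first_residue = 17)
#' nrow(top$beads)  # 99 beads: 26 x 4 minus 5 glycines
#' @export
build_peptide <- function(sequence, n_chains, first_residue = 17L,
                          table = default_forcefield()) {
  if (!is.character(sequence) || length(sequence) != 1 ||
      nchar(sequence) == 0) {
    abort("sequence must be a non-empty one-letter amino-acid string",
          class = "fibril_invalid_sequence")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(aa), AA_CODES)
  if (length(bad) > 0) {
    abort(paste0("unknown residue code(s): ", paste(bad, collapse = ", ")),
          class = "fibril_invalid_sequence")
  }
  if (!is.numeric(n_chains) || n_chains < 1 || n_chains != round(n_chains)) {
    abort("n_chains must be a positive integer")
  }
  n_chains <- as.integer(n_chains)
  nres <- length(aa)
  res_no <- seq.int(first_residue, length.out = nres)

  one_chain <- do.call(rbind, lapply(seq_len(nres), function(i) {
    kinds <- if (aa[i] == "G") c("NH", "CA", "CO") else BEAD_KINDS
    data.frame(residue = res_no[i], bead = kinds, aa = aa[i])
  }))
  beads <- do.call(rbind, lapply(seq_len(n_chains), function(c) {
    cbind(chain = c, one_chain)
  }))
  beads <- tibble(index = seq_len(nrow(beads)), chain = beads$chain,
                  residue = beads$residue, bead = beads$bead, aa = beads$aa)

  delta <- table$bond_delta
  bl <- table$bonds
  per_chain <- nrow(one_chain)
  idx_of <- function(chain, residue, kind) {
    off <- (chain - 1L) * per_chain
    loc <- which(one_chain$residue == residue & one_chain$bead == kind)
    if (length(loc) == 0) NA_integer_ else off + loc
  }
  bonds <- list(); chir <- list()
  for (c in seq_len(n_chains)) {
    for (i in seq_len(nres)) {
      r <- res_no[i]
      nh <- idx_of(c, r, "NH"); ca <- idx_of(c, r, "CA")
      co <- idx_of(c, r, "CO"); sc <- idx_of(c, r, "SC")
      bonds[[length(bonds) + 1]] <- data.frame(
        a = c(nh, ca, nh), b = c(ca, co, co),
        length = c(bl[["nh_ca"]], bl[["ca_co"]], bl[["nh_co"]]),
        delta = delta)
      if (!is.na(sc)) {
        a <- aa[i]
        bonds[[length(bonds) + 1]] <- data.frame(
          a = c(sc, sc, sc), b = c(ca, nh, co),
          length = c(table$sc_ca_dist[[a]], table$sc_nh_dist[[a]],
                     table$sc_co_dist[[a]]),
          delta = table$sc_bond_delta)
        chir[[length(chir) + 1]] <- data.frame(
          chain = c, residue = r, nh = nh, ca = ca, co = co, sc = sc)
      }
      if (i < nres) {
        r2 <- res_no[i + 1]
        nh2 <- idx_of(c, r2, "NH"); ca2 <- idx_of(c, r2, "CA")
        bonds[[length(bonds) + 1]] <- data.frame(
          a = c(co, ca, co, ca), b = c(nh2, nh2, ca2, ca2),
          length = c(bl[["co_nh"]], bl[["ca_nh"]], bl[["co_ca"]],
                     bl[["ca_ca"]]),
          delta = delta)
      }
    }
  }
  bonds <- as_tibble(do.call(rbind, bonds))
  structure(list(sequence = paste(aa, collapse = ""), n_chains = n_chains,
                 first_residue = as.integer(first_residue),
                 beads = beads, bonds = bonds,
                 chirality = as_tibble(do.call(rbind, chir))),
            class = "peptide_topology")
}

#' @export
print.peptide_topology <- function(x, ...) {
  cat("<peptide_topology> ", x$n_chains, " chain(s) x ",
      nchar(x$sequence), " residues (", x$first_residue, "..",
      x$first_residue + nchar(x$sequence) - 1L, "), ",
      nrow(x$beads), " beads, ", nrow(x$bonds), " bonded constraints\n",
      sep = "")
  invisible(x)
}

#' Signed chirality volume of each residue
#'
#' Triple product det(NH-CA, CO-CA, SC-CA) per residue.  All residues of an
#' L-isomer chain built by this package have positive sign, and the sign is
#' conserved along any valid trajectory.
#'
#' @param structure A bead tibble with columns `chain`, `residue`, `bead`,
#'   `x`, `y`, `z`.
#' @param topology The corresponding `peptide_topology`.
#' @return Tibble with `chain`, `residue`, `volume`.
#' @export
chirality_volumes <- function(structure, topology) {
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  ch <- topology$chirality
  vol <- vapply(seq_len(nrow(ch)), function(k) {
    v1 <- xyz[ch$nh[k], ] - xyz[ch$ca[k], ]
    v2 <- xyz[ch$co[k], ] - xyz[ch$ca[k], ]
    v3 <- xyz[ch$sc[k], ] - xyz[ch$ca[k], ]
    det(rbind(v1, v2, v3))
  }, numeric(1))
  tibble(chain = ch$chain, residue = ch$residue, volume = vol)
}
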