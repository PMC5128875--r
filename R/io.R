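# PDB input/output for coarse-grained frames and reference structures.

#' Read CA coordinates from a PDB file
#'
#' Reads a standard PDB file (model 1 when several models are present) and
#' returns the C-alpha atoms within a residue range, keyed by author chain
#' identifier and residue number.  Chains missing any residue in the range
#' are excluded with a warning.
#'
#' @param path PDB file path.
#' @param residue_range Inclusive `c(start, end)` residue range.
#' @param offset Added to the file's residue numbers before range selection
#'   (for references using a different numbering convention).
#' @return Bead tibble (`bead = "CA"`) with chain, residue, aa and
#'   coordinates.
#' @export
read_reference_calpha <- function(path, residue_range = c(17, 42),
                                  offset = 0L) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) {
                    abort(paste0("failed to parse PDB file ", path, ": ",
                                 conditionMessage(e)),
                          class = "fibril_parse_error")
                  })
  at <- pdb$atom
  at <- at[at$elety == "CA", ]
  at$resno <- at$resno + offset
  at <- at[at$resno >= residue_range[1] & at$resno <= residue_range[2], ]
  if (nrow(at) == 0) {
    abort("no CA atoms found in the requested residue range",
          class = "fibril_empty_selection")
  }
  need <- seq.int(residue_range[1], residue_range[2])
  keep <- character(0)
  for (ch in unique(at$chain)) {
    have <- at$resno[at$chain == ch]
    miss <- setdiff(need, have)
    if (length(miss) == 0) {
      keep <- c(keep, ch)
    } else {
      warn(paste0("chain ", ch, " excluded: missing residue(s) ",
                  paste(head(miss, 5), collapse = ", ")))
    }
  }
  if (length(keep) == 0) {
    abort("no chain covers the full residue range",
          class = "fibril_empty_selection")
  }
  at <- at[at$chain %in% keep & !duplicated(paste(at$chain, at$resno)), ]
  at <- at[order(match(at$chain, keep), at$resno), ]
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  aa1[!(aa1 %in% AA_CODES)] <- "A"
  tibble(index = seq_len(nrow(at)), chain = at$chain, residue = at$resno,
         bead = "CA", aa = aa1, x = at$x, y = at$y, z = at$z)
}

#' Write a coarse-grained frame as PDB
#'
#' Backbone beads map to atom names N / CA / C and the side-chain bead to
#' the pseudo-atom CB; chains get consecutive letters.  The file
#' round-trips through [read_reference_calpha()] for its CA content at the
#' format's 1e-3 Angstrom precision.
#'
#' @param structure Bead tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(structure, path) {
  beads <- structure_beads(structure)
  atom_name <- c(NH = "N", CA = "CA", CO = "C", SC = "CB")[beads$bead]
  chains <- unique(beads$chain)
  chain_id <- rep(c(LETTERS, letters, 0:9), length.out = length(chains))
  aa3 <- bio3d::aa123(beads$aa)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
    seq_len(nrow(beads)),
    ifelse(nchar(atom_name) < 4, paste0(" ", atom_name), atom_name),
    aa3, chain_id[match(beads$chain, chains)], beads$residue,
    beads$x, beads$y, beads$z, 1, 0)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}
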