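# Amino-acid level constants for the four-sphere-per-residue model.
# One-letter codes, alphabetical.  Glycine carries no side-chain sphere; its
# entries exist only so the 20x20 tables are complete.

AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Aβ17-42 fragment (LVFFAEDVGSNKGAIIGLMVGGVVIA), residues numbered 17..42

#' Aβ17-42 sequence
#'
#' One-letter sequence of the amyloid-beta 17-42 fragment used throughout the
#' package examples.  Residues are conventionally numbered 17 to 42.
#'
#' @return A length-one character string (26 residues).
#' @examples
#' nchar(ab1742_sequence())
#' @export
ab1742_sequence <- function() "LVFFAEDVGSNKGAIIGLMVGGVVIA"

# side-chain sphere hard diameters (Angstrom); coarse sizes growing with
# side-chain volume, capped below the inter-sheet stacking rise
AA_SC_DIAMETER <- c(
  A = 2.7, C = 3.6, D = 3.9, E = 4.2, F = 4.6, G = 2.0, H = 4.3, I = 4.3,
  K = 4.4, L = 4.3, M = 4.3, N = 3.8, P = 3.8, Q = 4.1, R = 4.6, S = 3.3,
  T = 3.7, V = 4.0, W = 4.7, Y = 4.6)

# distance from the CA united atom to the side-chain centroid (Angstrom)
AA_SC_CA_DIST <- c(
  A = 1.55, C = 2.05, D = 2.45, E = 2.90, F = 2.90, G = 0.00, H = 3.10,
  I = 2.30, K = 3.00, L = 2.60, M = 2.95, N = 2.45, P = 1.85, Q = 3.00,
  R = 3.40, S = 1.90, T = 1.95, V = 1.95, W = 3.40, Y = 3.20)

# hydrophobic interaction weight in [0, 1] driving the square-well depths
AA_HYDRO <- c(
  A = 0.25, C = 0.50, D = 0.05, E = 0.05, F = 0.70, G = 0.10, H = 0.15,
  I = 0.65, K = 0.05, L = 0.65, M = 0.60, N = 0.05, P = 0.20, Q = 0.05,
  R = 0.05, S = 0.10, T = 0.20, V = 0.50, W = 0.70, Y = 0.50)

AA_CHARGE <- c(
  A = 0, C = 0, D = -1, E = -1, F = 0, G = 0, H = 0, I = 0, K = 1, L = 0,
  M = 0, N = 0, P = 0, Q = 0, R = 1, S = 0, T = 0, V = 0, W = 0, Y = 0)

# backbone united-atom hard diameters (Angstrom)
BB_DIAMETER <- c(NH = 3.3, CA = 3.7, CO = 3.5)

# backbone bond / pseudo-bond ideal lengths (Angstrom)
BB_BONDS <- c(
  nh_ca = 1.46,   # N(i) - CA(i)
  ca_co = 1.51,   # CA(i) - C(i)
  co_nh = 1.33,   # C(i) - N(i+1), peptide bond
  nh_co = 2.45,   # N(i) - C(i), fixes the N-CA-C angle
  ca_nh = 2.41,   # CA(i) - N(i+1)
  co_ca = 2.45,   # C(i) - CA(i+1)
  ca_ca = 3.80)   # CA(i) - CA(i+1)

BEAD_KINDS <- c("NH", "CA", "CO", "SC")

# default side-chain elevation above the backbone plane (radians); kept
# shallow so stacked chains do not push side chains into the next layer
SC_ALPHA_DEFAULT <- 12 * pi / 180

# canonical rigid residue triangle: CA at origin, NH on +x, CO in the xy
# plane; SC is placed off this frame at elevation sc_alpha.  Used both to
# derive the SC-NH / SC-CO pseudo-bond lengths and by the conformer builders.
residue_frame <- function() {
  nh <- c(BB_BONDS[["nh_ca"]], 0, 0)
  cosg <- (BB_BONDS[["nh_ca"]]^2 + BB_BONDS[["ca_co"]]^2 -
             BB_BONDS[["nh_co"]]^2) /
    (2 * BB_BONDS[["nh_ca"]] * BB_BONDS[["ca_co"]])
  g <- acos(cosg)
  co <- BB_BONDS[["ca_co"]] * c(cos(g), sin(g), 0)
  list(nh = nh, ca = c(0, 0, 0), co = co)
}

# SC centroid in the canonical residue frame for a given CA-SC distance and
# elevation angle; the positive-z branch defines the L-isomer.
sc_in_frame <- function(d, alpha) {
  fr <- residue_frame()
  u1 <- fr$nh / sqrt(sum(fr$nh^2))
  u2 <- fr$co / sqrt(sum(fr$co^2))
  tv <- -(u1 + u2)
  tv <- tv / sqrt(sum(tv^2))
  nv <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  nv <- nv / sqrt(sum(nv^2))
  d * (cos(alpha) * tv + sin(alpha) * nv)
}
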