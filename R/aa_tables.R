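# Embedded per-amino-acid constant tables.
#
# Physicochemical scales are fixed published encodings; the pipeline treats
# them as opaque per-residue constants, so no test depends on an individual
# numeric entry, only on table shape and injectivity.

#' Standard amino-acid one-letter codes (alphabetical)
#'
#' Canonical ordering used for all 20-column profile vectors in this package.
#' @export
AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname AA_CODES
#' @export
AA_THREE <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

AA_FROM_THREE <- stats::setNames(names(AA_THREE), AA_THREE)

# van der Waals radii by element (Angstrom); fallback for rare elements is C.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- VDW_RADII[["C"]]
  unname(r)
}

# Theoretical maximum accessible surface areas (A^2), Tien et al. 2013.
# Denominator for all five relative-accessibility components (see vignette).
MAX_ASA <- c(A = 129.0, C = 167.0, D = 193.0, E = 223.0, F = 240.0,
             G = 104.0, H = 224.0, I = 197.0, K = 236.0, L = 201.0,
             M = 224.0, N = 195.0, P = 159.0, Q = 225.0, R = 274.0,
             S = 155.0, T = 172.0, V = 174.0, W = 285.0, Y = 263.0)

# HQI8: eight representative AAindex physicochemical clusters.
# Rows follow AA_CODES order.
HQI8_ACCESSIONS <- c("BLAM930101", "BIOV880101", "MAXF760101", "TSAJ990101",
                     "NAKH920108", "CEDJ970104", "LIFS790101", "MIYS990104")

HQI8_TABLE <- matrix(c(
  # BLAM930101 BIOV880101 MAXF760101 TSAJ990101 NAKH920108 CEDJ970104 LIFS790101 MIYS990104
     0.96,   16.0, 1.43,  89.3,  9.25, 7.9, 0.92, -0.04,  # A
     0.42,  168.0, 0.94, 102.5,  1.07, 1.9, 1.16, -0.38,  # C
     0.42,  -78.0, 0.92, 114.4,  2.23, 5.5, 0.48,  0.19,  # D
     0.53, -106.0, 1.67, 138.8,  2.62, 7.1, 0.61,  0.23,  # E
     0.59,  189.0, 1.19, 190.8,  9.24, 3.9, 1.25, -0.38,  # F
     0.00,  -13.0, 0.46,  63.8,  6.09, 7.1, 0.61,  0.09,  # G
     0.57,   50.0, 0.98, 157.5,  2.05, 2.1, 0.93, -0.04,  # H
     0.84,  151.0, 1.04, 163.0,  9.85, 5.2, 1.81, -0.34,  # I
     0.73, -141.0, 1.27, 165.1,  2.29, 6.7, 0.70,  0.33,  # K
     0.92,  145.0, 1.36, 163.1, 13.98, 8.6, 1.30, -0.37,  # L
     0.86,  124.0, 1.53, 165.8,  3.71, 2.4, 1.19, -0.30,  # M
     0.39,  -74.0, 0.64, 122.4,  2.22, 4.0, 0.60,  0.13,  # N
     -2.50,  -20.0, 0.49, 121.6,  2.53, 5.3, 0.40,  0.19,  # P
     0.80,  -73.0, 1.22, 146.9,  1.82, 4.4, 0.95,  0.14,  # Q
     0.77,  -70.0, 1.18, 190.3,  1.92, 4.9, 0.93,  0.07,  # R
     0.53,  -70.0, 0.70,  94.2,  4.67, 6.6, 0.82,  0.12,  # S
     0.54,  -38.0, 0.78, 119.6,  4.68, 5.3, 1.12,  0.03,  # T
     0.63,  123.0, 0.98, 138.2,  9.51, 6.8, 1.81, -0.29,  # V
     0.58,  145.0, 1.01, 226.4,  2.65, 1.2, 1.54, -0.33,  # W
     0.72,   53.0, 0.69, 194.6,  3.58, 3.1, 1.53, -0.29   # Y
), nrow = 20, byrow = TRUE,
   dimnames = list(AA_CODES, HQI8_ACCESSIONS))

# Atchley et al. 2005 factor scores: polarity, secondary structure,
# molecular volume, codon diversity, electrostatic charge.
AA_FACTOR_NAMES <- c("f_polarity", "f_secondary_structure",
                     "f_molecular_volume", "f_codon_diversity", "f_charge")

AA_FACTORS <- matrix(c(
  -0.591, -1.302, -0.733,  1.570, -0.146,  # A
  -1.343,  0.465, -0.862, -1.020, -0.255,  # C
   1.050,  0.302, -3.656, -0.259, -3.242,  # D
   1.357, -1.453,  1.477,  0.113, -0.837,  # E
  -1.006, -0.590,  1.891, -0.397,  0.412,  # F
  -0.384,  1.652,  1.330,  1.045,  2.064,  # G
   0.336, -0.417, -1.673, -1.474, -0.078,  # H
  -1.239, -0.547,  2.131,  0.393,  0.816,  # I
   1.831, -0.561,  0.533, -0.277,  1.648,  # K
  -1.019, -0.987, -1.505,  1.266, -0.912,  # L
  -0.663, -1.524,  2.219, -1.005,  1.212,  # M
   0.945,  0.828,  1.299, -0.169,  0.933,  # N
   0.189,  2.081, -1.628,  0.421, -1.392,  # P
   0.931, -0.179, -3.005, -0.503, -1.853,  # Q
   1.538, -0.055,  1.502,  0.440,  2.897,  # R
  -0.228,  1.399, -4.760,  0.670, -2.647,  # S
  -0.032,  0.326,  2.213,  0.908,  1.313,  # T
  -1.337, -0.279, -0.544,  1.242, -1.262,  # V
  -0.595,  0.009,  0.672, -2.128, -0.184,  # W
   0.260,  0.830,  3.097, -0.838,  1.512   # Y
), nrow = 20, byrow = TRUE,
   dimnames = list(AA_CODES, AA_FACTOR_NAMES))
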