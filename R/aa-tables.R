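## Published amino-acid constant tables. All indexed by the 20 standard
## one-letter codes in the fixed order used throughout the package.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "T", "S", "W", "Y", "V")

## Average residue masses (Da), Expasy; free amino acid = residue + one water.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  T = 101.1051, S = 87.0782,  W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

## Elemental composition of the FREE amino acids (C, H, N, O, S); a chain of n
## residues carries n - 1 fewer waters.
AA_ATOMS <- matrix(c(
  ## C   H   N  O  S
     3,  7,  1, 2, 0,   # A
     6, 14,  4, 2, 0,   # R
     4,  8,  2, 3, 0,   # N
     4,  7,  1, 4, 0,   # D
     3,  7,  1, 2, 1,   # C
     5, 10,  2, 3, 0,   # Q
     5,  9,  1, 4, 0,   # E
     2,  5,  1, 2, 0,   # G
     6,  9,  3, 2, 0,   # H
     6, 13,  1, 2, 0,   # I
     6, 13,  1, 2, 0,   # L
     6, 14,  2, 2, 0,   # K
     5, 11,  1, 2, 1,   # M
     9, 11,  1, 2, 0,   # F
     5,  9,  1, 2, 0,   # P
     4,  9,  1, 3, 0,   # T
     3,  7,  1, 3, 0,   # S
    11, 12,  2, 2, 0,   # W
     9, 11,  1, 3, 0,   # Y
     5, 11,  1, 2, 0    # V
), nrow = 20, byrow = TRUE,
  dimnames = list(AA_ORDER, c("C", "H", "N", "O", "S")))

## Kyte-Doolittle hydropathy scale.
AA_KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  T = -0.7, S = -0.8, W = -0.9, Y = -1.3, V =  4.2
)

## Guruprasad dipeptide instability weight values DIWV(x, y): row = first
## residue, column = the residue following it.
AA_DIWV <- matrix(c(
  1, 1, 1, -7.49, 44.94, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1,
  1, 58.28, 13.34, 1, 1, 20.26, 1, -7.49, 20.26, 1, 1, 1, 1, 1, 20.26, 44.94, 1, 58.28, -6.54, 1,
  1, 1, 1, 1, -1.88, -6.54, 1, -14.03, 1, 44.94, 1, 24.68, 1, -14.03, -1.88, 1, -7.49, -9.37, 1, 1,
  1, -6.54, 1, 1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, -6.54, 1, 20.26, -14.03, 1, 1, 1,
  1, 1, 1, 20.26, 1, -6.54, 1, 1, 33.6, 1, 20.26, 1, 33.6, 1, 20.26, 1, 33.6, 24.68, 1, -6.54,
  1, 1, 1, 20.26, -6.54, 20.26, 20.26, 1, 1, 1, 1, 1, 1, -6.54, 20.26, 44.94, 1, 1, -6.54, -6.54,
  1, 1, 1, 20.26, 44.94, 20.26, 33.6, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, -14.03, 1, 1,
  -7.49, 1, -7.49, 1, 1, 1, -6.54, 13.34, 1, -7.49, 1, -7.49, 1, 1, 1, 1, -7.49, 13.34, -7.49, 1,
  1, 1, 24.68, 1, 1, 1, 1, -9.37, 1, 44.94, 1, 24.68, 1, -9.37, -1.88, 1, -6.54, -1.88, 44.94, 1,
  1, 1, 1, 1, 1, 1, 44.94, 1, 13.34, 1, 20.26, -7.49, 1, 1, -1.88, 1, 1, 1, 1, -7.49,
  1, 20.26, 1, 1, 1, 33.6, 1, 1, 1, 1, 1, -7.49, 1, 1, 20.26, 1, 1, 24.68, 1, 1,
  1, 33.6, 1, 1, 1, 24.64, 1, -7.49, 1, -7.49, -7.49, 1, 33.6, 1, -6.54, 1, 1, 1, 1, -7.49,
  13.34, -6.54, 1, 1, 1, -6.54, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, 44.94, -1.88, 1, 24.68, 1,
  1, 1, 1, 13.34, 1, 1, 1, 1, 1, 1, 1, -14.03, 1, 1, 20.26, 1, 1, 1, 33.601, 1,
  20.26, -6.54, 1, -6.54, -6.54, 20.26, 18.38, 1, 1, 1, 1, 1, -6.54, 20.26, 20.26, 20.26, 1, -1.88, 1, 20.26,
  1, 20.26, 1, 1, 33.6, 20.26, 20.26, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 1, 1, 1, 1,
  1, 1, -14.03, 1, 1, -6.54, 20.26, -7.49, 1, 1, 1, 1, 1, 13.34, 1, 1, 1, -14.03, 1, 1,
  -14.03, 1, 13.34, 1, 1, 1, 1, -9.37, 24.68, 1, 13.34, 1, 24.68, 1, 1, 1, -14.03, 1, 1, -7.49,
  24.68, -15.91, 1, 24.68, 1, 1, -6.54, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -7.49, -9.37, 13.34, 1,
  1, 1, 1, -14.03, 1, 1, 1, -7.49, 1, 1, 1, -1.88, 1, 1, 20.26, 1, -7.49, 1, -6.54, 1
), nrow = 20, byrow = TRUE,
  dimnames = rep(list(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")), 2))
## the table above is laid out with S before T; reindex to the package order
AA_DIWV <- AA_DIWV[AA_ORDER, AA_ORDER]

## EMBOSS pKa set used for the theoretical pI.
PKA_EMBOSS <- c(Nterm = 8.6, Cterm = 3.6,
                C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
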