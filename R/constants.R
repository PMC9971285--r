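# Physical constants used throughout the package. A single embedded table keeps
# mass arithmetic reproducible across platforms and independent of any runtime
# lookup. Element masses are monoisotopic (Da).

.element_masses <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069,
  P = 30.97376151,
  Se = 79.9165218
)

.electron_mass <- 0.00054858

# Proton mass used for m/z conversion of protonated ions (MH^n+).
.proton_mass <- 1.00728

# Elemental composition of the 20 canonical amino-acid residues (the in-chain
# residue, i.e. amino acid minus water).
.residue_formulas <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.sum_formula_mass <- function(counts) {
  sum(.element_masses[names(counts)] * counts)
}

.residue_mass_values <- vapply(.residue_formulas, .sum_formula_mass, numeric(1))

.water_mass <- .sum_formula_mass(c(H = 2, O = 1))

.canonical_residues <- names(.residue_formulas)
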