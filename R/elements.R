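# Element property tables: covalent radii (single-bond, Angstrom), default
# valences for implicit-hydrogen completion, and the metal set used to
# recognize central atoms.

.covalent_radius <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  K = 2.03, Ca = 1.76, Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39,
  Fe = 1.32, Co = 1.26, Ni = 1.24, Cu = 1.32, Zn = 1.22, Ga = 1.22,
  Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20,
  Rb = 2.20, Sr = 1.95, Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54,
  Tc = 1.47, Ru = 1.46, Rh = 1.42, Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39,
  Cs = 2.44, Ba = 2.15, La = 2.07, Hf = 1.75, Ta = 1.70, W = 1.62,
  Re = 1.51, Os = 1.44, Ir = 1.41, Pt = 1.36, Au = 1.36, Hg = 1.32,
  Tl = 1.45, Pb = 1.46, Bi = 1.48
)

# elements treated as metals when validating the central atom
.metal_elements <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn",
  "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo",
  "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs", "Ba", "La",
  "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi"
)

# allowed valences (lowest first) for neutral atoms of the SMILES organic
# subset plus a few bracket elements; used for implicit H counts
.default_valences <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = c(1, 3, 5, 7), Br = 1, I = c(1, 3, 5, 7),
  Si = 4, Se = c(2, 4, 6), As = c(3, 5), H = 1
)

covalent_radius <- function(element) {
  r <- .covalent_radius[element]
  if (any(is.na(r))) {
    stop("no covalent radius tabulated for element(s): ",
         paste(unique(element[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

is_metal_element <- function(element) element %in% .metal_elements
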