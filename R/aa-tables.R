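# Amino-acid reference tables: average residue masses (Da), one/three letter
# codes, and the mean residue volume used for the coarse-grained scattering
# form factor (1.21 A^3/Da at vbar = 0.73 mL/g).

AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS <- 18.01524

AA_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", E = "GLU",
  Q = "GLN", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

AA_ONE <- setNames(names(AA_THREE), AA_THREE)

# volume per Dalton for proteins (vbar 0.73 mL/g); mean residue ~134 A^3
A3_PER_DA <- 1.21

#' Average amino-acid residue masses
#'
#' Average (isotope-weighted) residue masses in Daltons for the 20 standard
#' amino acids, i.e. the mass contributed by each residue inside a peptide
#' chain (one water is added per chain by [sequence_mass_kda()]).
#'
#' @return A named numeric vector of 20 residue masses (Da).
#' @export
#' @examples
#' aa_masses()[["G"]]
aa_masses <- function() AA_MASS

check_residues <- function(residues, what = "sequence") {
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), names(AA_MASS))
  if (length(bad) > 0) {
    abort(sprintf("%s contains non-standard residue code(s): %s",
                  what, paste(bad, collapse = ", ")))
  }
  invisible(residues)
}
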