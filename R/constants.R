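#' Physical constants used throughout the package
#'
#' Energies are in kJ/mol, temperatures in kelvin, distances in nm and
#' masses in Da. The gas constant is used both as R (van't Hoff algebra)
#' and as kB expressed per mole (Boltzmann inversion), so every free
#' energy the package reports is molar.
#'
#' @format A named list:
#' \describe{
#'   \item{R_kJ}{gas constant, 8.314e-3 kJ mol^-1 K^-1}
#'   \item{proton_mass}{mass of a proton, Da}
#'   \item{water_mono}{monoisotopic mass of H2O, Da}
#'   \item{amide_correction}{mass change (Da) when the C-terminal -OH is
#'     replaced by -NH2 (C-terminal amidation)}
#'   \item{tmao_mass}{monoisotopic mass of trimethylamine N-oxide, Da}
#'   \item{avogadro}{Avogadro's number, mol^-1}
#' }
#' @export
peptherm_constants <- list(
  R_kJ             = 8.314e-3,
  proton_mass      = 1.00728,
  water_mono       = 18.0105646,
  water_avg        = 18.01528,
  amide_correction = -0.98402,
  tmao_mass        = 75.068,
  avogadro         = 6.02214076e23
)

# Monoisotopic residue masses (Da), standard 20 amino acids.
.residue_mono <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

# Average residue masses (Da), for low-resolution spectra.
.residue_avg <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594,
  N = 114.1038, D = 115.0886, Q = 128.1307, K = 128.1741,
  E = 129.1155, M = 131.1926, H = 137.1411, F = 147.1766,
  R = 156.1875, Y = 163.1760, W = 186.2132
)

#' Nominal concentration of n molecules in a cubic periodic box
#'
#' @param n_molecules number of solute molecules in the box
#' @param box_edge_nm box edge length, nm
#' @param avogadro Avogadro's number; the default is the exact SI value
#' @return concentration in mol/L
#' @examples
#' box_concentration(2, 8) # two peptide chains in an 8 nm box, ~6.5 mM
#' @export
box_concentration <- function(n_molecules, box_edge_nm,
                              avogadro = peptherm_constants$avogadro) {
  stopifnot(n_molecules >= 0, box_edge_nm > 0)
  volume_L <- (box_edge_nm * 1e-9)^3 * 1e3 # m^3 -> L
  n_molecules / (avogadro * volume_L)
}

# Run an expression with a private RNG stream so generators are pure
# functions of (parameters, seed) and never disturb the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
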