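#' Monoisotopic mass bookkeeping
#'
#' Constants and constructors for amino-acid residue masses, cross-linker
#' reagents and peptide modifications.  All masses are monoisotopic and in
#' daltons (Da); all residue positions used throughout the package are
#' 1-based and inclusive.
#'
#' @name masses
NULL

# Monoisotopic residue (not free amino acid) masses, Da.
.RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_MASS  <- 18.0105646
.PROTON_MASS <- 1.00727646

#' Standard monoisotopic mass table
#'
#' @return A list with `residue_masses` (named numeric vector over the 20
#'   standard residues), `water_mass` and `proton_mass`, all in Da.
#' @examples
#' tab <- mass_table()
#' tab$residue_masses[["G"]]
#' @export
mass_table <- function() {
  list(
    residue_masses = .RESIDUE_MASSES,
    water_mass     = .WATER_MASS,
    proton_mass    = .PROTON_MASS
  )
}

#' Define an MS-cleavable cross-linker
#'
#' An MS-cleavable reagent bridges two residues; during MS2 the bridge is
#' cleaved asymmetrically, leaving a light or a heavy "stub" on each
#' peptide.  The two stub forms of the same fragment produce the signature
#' doublet, separated by `stub_heavy_mass - stub_light_mass` (one sulfur
#' for DSSO).
#'
#' @param name Reagent name.
#' @param intact_bridge_mass Mass added to the sum of the two peptide
#'   masses in the intact cross-linked precursor, Da.
#' @param stub_light_mass,stub_heavy_mass Masses of the two cleavage stubs,
#'   Da; the heavy stub must be heavier.
#' @param reactive_sites Character vector of reactive residue letters.
#' @param protein_n_terminus_reactive Whether the protein N-terminus is
#'   also a reactive site.
#' @return A list of class `xl_crosslinker`; `doublet_delta` is the
#'   stub mass difference.
#' @examples
#' dsso <- crosslinker_dsso()
#' dsso$doublet_delta   # one sulfur, 31.97207 Da
#' @export
crosslinker <- function(name, intact_bridge_mass, stub_light_mass,
                        stub_heavy_mass, reactive_sites = "K",
                        protein_n_terminus_reactive = FALSE) {
  stopifnot(stub_heavy_mass > stub_light_mass, intact_bridge_mass > 0)
  structure(list(
    name = name,
    intact_bridge_mass = intact_bridge_mass,
    stub_light_mass = stub_light_mass,
    stub_heavy_mass = stub_heavy_mass,
    doublet_delta = stub_heavy_mass - stub_light_mass,
    reactive_sites = reactive_sites,
    protein_n_terminus_reactive = protein_n_terminus_reactive
  ), class = "xl_crosslinker")
}

#' @rdname crosslinker
#' @details `crosslinker_dsso()` returns DSSO with stub compositions
#'   C3H2O (alkene, 54.01057 Da) and C3H2OS (thiol, 85.98264 Da) and an
#'   intact bridge of 158.00376 Da; the doublet spacing equals one sulfur
#'   (31.97207 Da).  `crosslinker_dsbso()` is the enrichable Azide-A-DSBSO
#'   analogue sharing the sulfoxide cleavage chemistry (same stub pair on
#'   the peptide side, larger intact bridge carrying the azide handle).
#' @export
crosslinker_dsso <- function() {
  crosslinker("DSSO",
              intact_bridge_mass = 158.00376,
              stub_light_mass = 54.01057,
              stub_heavy_mass = 85.98264,
              reactive_sites = "K",
              protein_n_terminus_reactive = TRUE)
}

#' @rdname crosslinker
#' @export
crosslinker_dsbso <- function() {
  crosslinker("Azide-A-DSBSO",
              intact_bridge_mass = 308.03883,
              stub_light_mass = 54.01057,
              stub_heavy_mass = 85.98264,
              reactive_sites = "K",
              protein_n_terminus_reactive = TRUE)
}

#' Define a peptide modification
#'
#' @param target Residue letter (or `"N-term"`/`"C-term"`).
#' @param delta_mass Mass shift in Da, |delta| < 2000.
#' @param type `"fixed"` or `"variable"`.
#' @param name Short label used in modification strings.
#' @return A list of class `xl_modification`.
#' @examples
#' mod_carbamidomethyl()  # +57.02146 on C, fixed
#' mod_oxidation_m()      # +15.99491 on M, variable
#' @export
modification <- function(target, delta_mass, type = c("fixed", "variable"),
                         name = "mod") {
  type <- match.arg(type)
  stopifnot(abs(delta_mass) < 2000)
  structure(list(target = target, delta_mass = delta_mass,
                 type = type, name = name),
            class = "xl_modification")
}

#' @rdname modification
#' @export
mod_carbamidomethyl <- function() {
  modification("C", 57.02146, "fixed", "cam")
}

#' @rdname modification
#' @export
mod_oxidation_m <- function() {
  modification("M", 15.99491, "variable", "ox")
}
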