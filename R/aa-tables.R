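# Amino-acid constant tables shared across the package.

#' Canonical amino-acid alphabet
#'
#' The 20 one-letter codes accepted everywhere in qtykit. Non-canonical
#' characters (X, B, Z, U, ...) are rejected at parse time: the metric
#' functions require a closed alphabet to stay deterministic.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

# Average residue masses in Da (monomer minus one water), Expasy-compatible.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

# Mass of one water molecule (average), added once per chain.
WATER_AVG_MASS <- 18.01524

# Kyte-Doolittle hydropathy values.
AA_KYTE_DOOLITTLE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  E = -3.5, Q = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Three-letter -> one-letter residue codes (used when relabelling structures).
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- setNames(names(AA_THREE_TO_ONE), unname(AA_THREE_TO_ONE))

#' The QTY substitution mapping
#'
#' Named character vector giving the fixed hydrophobic-to-hydrophilic
#' replacement scheme: leucine to glutamine, isoleucine and valine to
#' threonine, phenylalanine to tyrosine. The mapping is applied only inside
#' annotated transmembrane spans and is not user-extensible.
#'
#' @format Named character vector (`c(L = "Q", I = "T", V = "T", F = "Y")`).
#' @export
QTY_MAPPING <- c(L = "Q", I = "T", V = "T", F = "Y")

#' Bjellqvist pKa table for isoelectric-point calculation
#'
#' Returns the ionizable-group model used by [isoelectric_point()]: the
#' Bjellqvist pKa set popularised by the Expasy Compute pI tool. The
#' N-terminal pKa is residue-specific (with a generic fallback of 7.5); the
#' C-terminus and the side chains of D, E, C, Y (acidic) and H, K, R (basic)
#' carry fixed values. Supply a modified copy to swap the model.
#'
#' @return A list with elements `n_term` (named numeric vector of
#'   residue-specific N-terminal pKa values), `n_term_default`, `c_term`,
#'   `acidic` and `basic` (named numeric vectors of side-chain pKa values).
#' @examples
#' bjellqvist_pka()$basic
#' @export
bjellqvist_pka <- function() {
  list(
    n_term = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
               V = 7.44, E = 7.70, G = 7.50),
    n_term_default = 7.50,
    c_term = 3.55,
    acidic = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
    basic  = c(H = 5.98, K = 10.00, R = 12.00)
  )
}

#' Van der Waals radius table for SASA
#'
#' Element radii (in Angstrom) used by [shrake_rupley_sasa()]. Unlisted
#' elements fall back to the carbon radius.
#'
#' @return Named numeric vector with a `default` entry.
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, default = 1.70)
}

#' Hydrophobic residue set
#'
#' Default residue set treated as hydrophobic by
#' [hydrophobic_surface_fraction()]: the Kyte-Doolittle-positive residues
#' plus A, P and W by convention. None of the QTY replacement residues
#' (Q, T, Y) is a member, so every QTY substitution moves surface area out
#' of the hydrophobic class.
#'
#' @format Character vector of one-letter codes.
#' @export
HYDROPHOBIC_SET <- c("A", "V", "L", "I", "P", "F", "M", "W")

# Internal: validate a residue string, returning it uppercased.
check_residues <- function(x, what = "sequence") {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad) > 0L) {
    stop(
      "non-canonical residue code(s) in ", what, ": ",
      paste(bad, collapse = ", "),
      " (only the 20 canonical one-letter codes are accepted)",
      call. = FALSE
    )
  }
  x
}
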