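#' Amino-acid constants
#'
#' Fixed internal amino-acid column order (alphabetical by one-letter code)
#' and the physicochemical lookup tables used by the property features.
#' All parsers permute external column orders into [AA_ORDER] so that
#' downstream feature code never depends on a file dialect.
#'
#' @name aa_tables
#' @keywords internal
NULL

#' Internal amino-acid order
#'
#' The 20 standard amino acids, alphabetical by one-letter code. Every
#' PSSM-derived matrix in the package has its columns in this order.
#'
#' @export
AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Ambiguity codes tolerated in sequences; they contribute zero to
# composition/property counts and their track rows are used as-is.
AA_AMBIGUOUS <- c("X", "B", "Z", "U")

#' Physicochemical property tables
#'
#' Per-amino-acid polarity class (non-polar, polar, acidic-polar,
#' basic-polar), charge class (positive, negative, neutral),
#' Kyte-Doolittle hydropathy and average residue mass in daltons.
#' Histidine is placed with the basic-polar / positively charged
#' residues, the textbook convention.
#'
#' @return A data.frame with one row per standard amino acid, in
#'   [AA_ORDER], and columns `aa`, `polarity`, `charge`, `hydropathy`,
#'   `mass`.
#' @examples
#' property_tables()["K", ]
#' @export
property_tables <- function() {
  polarity <- c(
    A = "nonpolar", C = "polar", D = "acidic", E = "acidic",
    F = "nonpolar", G = "nonpolar", H = "basic", I = "nonpolar",
    K = "basic", L = "nonpolar", M = "nonpolar", N = "polar",
    P = "nonpolar", Q = "polar", R = "basic", S = "polar",
    T = "polar", V = "nonpolar", W = "nonpolar", Y = "polar"
  )
  charge <- c(
    A = "neutral", C = "neutral", D = "negative", E = "negative",
    F = "neutral", G = "neutral", H = "positive", I = "neutral",
    K = "positive", L = "neutral", M = "neutral", N = "neutral",
    P = "neutral", Q = "neutral", R = "positive", S = "neutral",
    T = "neutral", V = "neutral", W = "neutral", Y = "neutral"
  )
  # Kyte & Doolittle hydropathy index
  hydropathy <- c(
    A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4,
    H = -3.2, I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5,
    P = -1.6, Q = -3.5, R = -4.5, S = -0.8, T = -0.7, V = 4.2,
    W = -0.9, Y = -1.3
  )
  # average residue (monomer minus water) masses, Da
  mass <- c(
    A = 71.08, C = 103.14, D = 115.09, E = 129.12, F = 147.18,
    G = 57.05, H = 137.14, I = 113.16, K = 128.17, L = 113.16,
    M = 131.19, N = 114.10, P = 97.12, Q = 128.13, R = 156.19,
    S = 87.08, T = 101.10, V = 99.13, W = 186.21, Y = 163.18
  )
  data.frame(
    aa = AA_ORDER,
    polarity = unname(polarity[AA_ORDER]),
    charge = unname(charge[AA_ORDER]),
    hydropathy = unname(hydropathy[AA_ORDER]),
    mass = unname(mass[AA_ORDER]),
    row.names = AA_ORDER,
    stringsAsFactors = FALSE
  )
}

POLARITY_CLASSES <- c("nonpolar", "polar", "acidic", "basic")
CHARGE_CLASSES <- c("positive", "negative", "neutral")
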