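#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids (one-letter codes)
#'
#' Alphabetically ordered one-letter codes used throughout the package.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# three-letter -> one-letter lookup for PDB residue names
AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

#' Physicochemical category of an amino acid
#'
#' Fixed six-way classification used for the category-change classifier
#' feature: aliphatic (A, V, L, I, M), aromatic (F, W, Y, H), polar
#' (S, T, N, Q, C), positively charged (K, R), negatively charged (D, E)
#' and special (G, P).
#'
#' @param aa Character vector of one-letter amino-acid codes.
#' @return Character vector of category names.
#' @export
#' @examples
#' aa_category(c("A", "Y", "K"))
aa_category <- function(aa) {
  cat_map <- c(
    A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
    M = "aliphatic",
    F = "aromatic", W = "aromatic", Y = "aromatic", H = "aromatic",
    S = "polar", T = "polar", N = "polar", Q = "polar", C = "polar",
    K = "positive", R = "positive",
    D = "negative", E = "negative",
    G = "special", P = "special"
  )
  out <- unname(cat_map[aa])
  if (anyNA(out)) stop("unknown amino acid(s): ",
                       paste(unique(aa[is.na(out)]), collapse = ", "))
  out
}

# Theoretical per-residue maximum accessible surface areas (A^2), used to
# normalize per-residue SASA and for the identity-swap dSASA feature
# (Tien et al. 2013, theoretical column).
AA_MAX_SASA <- c(
  A = 129, R = 274, N = 195, D = 193, C = 167,
  Q = 225, E = 223, G = 104, H = 224, I = 197,
  L = 201, K = 236, M = 224, F = 240, P = 159,
  S = 155, T = 172, W = 285, Y = 263, V = 174
)

#' Difference of tabulated maximum accessible surface areas
#'
#' Returns the difference in the theoretical per-amino-acid maximum
#' solvent-accessible surface area between a mutant and a reference identity
#' (mutant minus reference), the identity-swap surrogate for the structural
#' change in accessible area caused by a substitution.
#'
#' @param ref_aa,mut_aa One-letter amino-acid codes (vectorized).
#' @return Numeric vector of area differences in square Angstrom.
#' @export
#' @examples
#' max_sasa_delta("A", "W")
#' max_sasa_delta("A", "A")  # 0
max_sasa_delta <- function(ref_aa, mut_aa) {
  bad <- setdiff(unique(c(ref_aa, mut_aa)), names(AA_MAX_SASA))
  if (length(bad)) stop("unknown amino acid(s): ", paste(bad, collapse = ", "))
  unname(AA_MAX_SASA[mut_aa] - AA_MAX_SASA[ref_aa])
}

# --- internal helpers -------------------------------------------------------

# positions are handled as integers keyed by their character form
.pos_key <- function(positions) as.character(as.integer(positions))

# validate a genotype: named character vector, names = positions
.check_genotype <- function(genotype) {
  stopifnot(is.character(genotype), !is.null(names(genotype)))
  bad <- setdiff(unique(genotype), AA_ALPHABET)
  if (length(bad)) stop("genotype contains non-standard identities: ",
                        paste(bad, collapse = ", "))
  invisible(genotype)
}

# coerce a single genotype (named character) or a character matrix with
# position colnames into a one-row / n-row matrix
.as_genotype_matrix <- function(g) {
  if (is.matrix(g)) return(g)
  matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
}

# count mutations of each row of a genotype matrix relative to a reference
.n_mutations <- function(G, reference) {
  ref <- reference[colnames(G)]
  rowSums(G != matrix(ref, nrow(G), ncol(G), byrow = TRUE))
}
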