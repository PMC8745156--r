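# Amino-acid alphabets, physicochemical classes, radii and max-ASA tables.

#' Amino acid alphabets and physicochemical classes
#'
#' The 20 standard residues are partitioned into four physicochemical
#' classes: apolar (G, A, V, I, L, P, M), polar (S, T, C, N, Q, H),
#' aromatic (F, W, Y) and charged (D, E, K, R). Heatmap-style short labels
#' are `a`, `p`, `r` and `c` respectively.
#'
#' @format `aa_alphabet` is a character vector of the 20 one-letter codes;
#'   `residue_classes` is a named list of four character vectors that
#'   partition `aa_alphabet`.
#' @export
aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @rdname aa_alphabet
#' @export
residue_classes <- list(
  apolar   = c("G", "A", "V", "I", "L", "P", "M"),
  polar    = c("S", "T", "C", "N", "Q", "H"),
  aromatic = c("F", "W", "Y"),
  charged  = c("D", "E", "K", "R")
)

# short labels used in figures and matrix I/O
class_labels <- c(apolar = "a", polar = "p", aromatic = "r", charged = "c")

# one-letter <-> three-letter residue codes
aa_three <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")
aa_one <- setNames(names(aa_three), aa_three)

#' Default van der Waals radii (Angstrom)
#'
#' Heavy-atom element radii used by the surface-area computation:
#' C 1.76, N 1.65, O 1.40, S 1.85, plus P 1.90 and SE 1.90 for
#' completeness. Configurable through the `radii` arguments of
#' [read_structure()] and the generators.
#'
#' @format Named numeric vector, element symbol to radius in Angstrom.
#' @export
default_vdw_radii <- c(C = 1.76, N = 1.65, O = 1.40, S = 1.85,
                       P = 1.90, SE = 1.90)

#' Theoretical maximum residue accessibility (Angstrom^2)
#'
#' Gly-X-Gly theoretical maximum accessible surface areas (Tien et al.
#' 2013, theoretical set), used to normalize absolute residue ASA into
#' relative solvent accessibility (RSA, percent). Keyed by three-letter
#' residue name. A configuration item: any table with the same layout can
#' be passed to [relative_accessibility()].
#'
#' @format Named numeric vector, three-letter residue name to max ASA.
#' @export
max_acc_tien2013 <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

#' Physicochemical class of a residue
#'
#' @param aa Character vector of one-letter residue codes.
#' @return Character vector over `c("apolar", "polar", "aromatic",
#'   "charged")`.
#' @examples
#' residue_class(c("G", "Y", "D"))
#' @export
residue_class <- function(aa) {
  aa <- toupper(aa)
  bad <- setdiff(unique(aa), aa_alphabet)
  if (length(bad))
    stop("not standard amino acid code(s): ", paste(bad, collapse = ", "))
  lut <- unlist(lapply(names(residue_classes), function(cl)
    setNames(rep(cl, length(residue_classes[[cl]])), residue_classes[[cl]])))
  unname(lut[aa])
}

# the four classes must partition the alphabet; checked at load time
.onLoad <- function(libname, pkgname) {
  all20 <- sort(unlist(residue_classes, use.names = FALSE))
  stopifnot(identical(all20, sort(aa_alphabet)))
}
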