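#' The 20-letter amino-acid alphabet
#'
#' Standard one-letter codes in the fixed order used throughout the package
#' for node labels and one-hot positions: alphabetical
#' A, C, D, E, F, G, H, I, K, L, M, N, P, Q, R, S, T, V, W, Y.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Ten-group physicochemical classification (binary, multi-membership allowed:
# e.g. H is both Aromatic and Positive).
PC10_GROUPS <- list(
  Aromatic    = c("F", "Y", "W", "H"),
  Negative    = c("D", "E"),
  Positive    = c("K", "H", "R"),
  Polar       = c("N", "Q", "S", "D", "E", "C", "T", "K", "R", "H", "Y", "W"),
  Hydrophobic = c("A", "G", "C", "T", "I", "V", "L", "K", "H", "F", "Y", "W", "M"),
  Aliphatic   = c("I", "V", "L"),
  Tiny        = c("A", "S", "G", "C"),
  Charged     = c("K", "H", "R", "D", "E"),
  Small       = c("P", "N", "D", "T", "C", "A", "G", "S", "V"),
  Proline     = "P"
)

# Composition/Transition/Distribution (CTD) scheme: seven physicochemical
# properties, each splitting the 20 residues into three disjoint groups.
# "Normalized" is the normalized van der Waals volume.
CTD_GROUPS <- list(
  Hydrophobicity = list(
    g1 = c("A", "C", "F", "G", "H", "I", "L", "M", "N", "P", "Q", "S", "T", "V", "W", "Y"),
    g2 = c("D", "E"),
    g3 = c("K", "R")
  ),
  Normalized = list(
    g1 = c("C", "F", "I", "L", "M", "V", "W"),
    g2 = c("A", "G", "H", "P", "S", "T", "Y"),
    g3 = c("D", "E", "K", "N", "Q", "R")
  ),
  Polarity = list(
    g1 = c("A", "C", "D", "G", "P", "S", "T"),
    g2 = c("E", "I", "L", "N", "Q", "V"),
    g3 = c("F", "H", "K", "M", "R", "W", "Y")
  ),
  Polarizibility = list(
    g1 = c("C", "F", "I", "L", "M", "V", "W", "Y"),
    g2 = c("A", "G", "P", "S", "T"),
    g3 = c("D", "E", "H", "K", "N", "Q", "R")
  ),
  Charge = list(
    g1 = c("A", "D", "G", "S", "T"),
    g2 = c("C", "E", "I", "L", "N", "P", "Q", "V"),
    g3 = c("F", "H", "K", "M", "R", "W", "Y")
  ),
  SecondaryStructures = list(
    g1 = c("D", "G", "N", "P", "S"),
    g2 = c("A", "E", "H", "K", "L", "M", "Q", "R"),
    g3 = c("C", "F", "I", "T", "V", "W", "Y")
  ),
  SolventAccessibility = list(
    g1 = c("A", "C", "F", "G", "I", "L", "V", "W"),
    g2 = c("H", "M", "P", "S", "T", "Y"),
    g3 = c("D", "E", "K", "N", "R", "Q")
  )
)

#' Physicochemical group tables
#'
#' Accessors for the two binary physicochemical classifications backing
#' [pc10_encode()] and [ctd21_encode()]: a ten-property scheme where a residue
#' may belong to several groups, and the seven-property CTD scheme where each
#' property partitions the alphabet into exactly three groups.
#'
#' @return For `pc10_groups()`, a named list of 10 character vectors. For
#'   `ctd_groups()`, a named list of 7 lists, each with elements `g1`, `g2`,
#'   `g3`.
#' @export
pc10_groups <- function() PC10_GROUPS

#' @rdname pc10_groups
#' @export
ctd_groups <- function() CTD_GROUPS

check_residue <- function(residue) {
  if (!is.character(residue) || length(residue) != 1L || nchar(residue) != 1L) {
    stop("expected a single one-letter residue code", call. = FALSE)
  }
  residue <- toupper(residue)
  if (!residue %in% aa_alphabet()) {
    stop("unknown residue '", residue, "': not one of the 20 standard amino acids",
         call. = FALSE)
  }
  residue
}

#' One-hot residue encoding
#'
#' Encodes a residue as a 20-dimensional indicator vector with a single 1 at
#' the residue's rank in the fixed alphabet (see [aa_alphabet()]).
#'
#' @param residue Single one-letter amino-acid code.
#' @return Numeric vector of length 20.
#' @examples
#' onehot_encode("A")  # 1 in position 1
#' @export
onehot_encode <- function(residue) {
  residue <- check_residue(residue)
  v <- numeric(20L)
  v[match(residue, aa_alphabet())] <- 1
  names(v) <- aa_alphabet()
  v
}

#' Ten-property binary physicochemical encoding
#'
#' Encodes a residue as a 10-dimensional binary vector; bit j is 1 when the
#' residue belongs to property group j (Aromatic, Negative, Positive, Polar,
#' Hydrophobic, Aliphatic, Tiny, Charged, Small, Proline). Residues commonly
#' belong to several groups, so the vector may contain multiple 1s.
#'
#' @inheritParams onehot_encode
#' @return Numeric binary vector of length 10, named by property.
#' @export
pc10_encode <- function(residue) {
  residue <- check_residue(residue)
  v <- vapply(PC10_GROUPS, function(g) as.numeric(residue %in% g), numeric(1))
  v
}

#' CTD three-group physicochemical encoding
#'
#' Encodes a residue under the Composition/Transition/Distribution scheme:
#' for each of seven physicochemical properties (hydrophobicity, normalized
#' van der Waals volume, polarity, polarizibility, charge, secondary
#' structure, solvent accessibility) exactly one of three group slots is set
#' to 1, giving a 21-dimensional binary vector that always sums to 7.
#'
#' @inheritParams onehot_encode
#' @return Numeric binary vector of length 21, named `<property>.g<k>`.
#' @export
ctd21_encode <- function(residue) {
  residue <- check_residue(residue)
  v <- unlist(lapply(CTD_GROUPS, function(prop) {
    vapply(prop, function(g) as.numeric(residue %in% g), numeric(1))
  }))
  v
}

#' CTD group index per property
#'
#' For a residue, the group (1, 2 or 3) it falls in under each of the seven
#' CTD properties.
#'
#' @inheritParams onehot_encode
#' @return Integer vector of length 7, named by property.
#' @export
ctd_group_index <- function(residue) {
  residue <- check_residue(residue)
  vapply(CTD_GROUPS, function(prop) {
    which(vapply(prop, function(g) residue %in% g, logical(1)))[[1L]]
  }, integer(1))
}
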