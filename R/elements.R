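#' Amino-acid alphabet used throughout the package
#'
#' Class labels, dataset label vectors and prediction profiles all use the
#' fixed alphabetical three-letter order `ALA ... VAL` (20 classes, 0-based
#' labels 0-19 in stored datasets, 1-based columns in R matrices).
#'
#' @return Character vector of the 20 standard three-letter residue codes in
#'   alphabetical order.
#' @export
#' @examples
#' aa_alphabet()[1]   # "ALA"
aa_alphabet <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")
}

#' One-letter amino-acid codes in the same order as [aa_alphabet()]
#' @return Character vector of length 20.
#' @export
aa_alphabet1 <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# normalize a 1- or 3-letter code to a 1-based class index, NA if unknown
aa_index <- function(code) {
  code <- toupper(code)
  i <- match(code, aa_alphabet())
  j <- match(code, aa_alphabet1())
  ifelse(is.na(i), j, i)
}

# Bondi-style van der Waals radii (Angstrom); lookup is case-insensitive on
# standard element symbols
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  NA_ = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 2.00,
  MN = 2.00, CU = 1.40, SE = 1.90, B = 1.92
)

#' Van der Waals radius for an element symbol
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @param fallback Radius in Angstrom used for unrecognised elements.
#' @param on_unknown `"warn"` (default) to fall back with a warning, or
#'   `"error"` to stop.
#' @return Numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, fallback = 1.7, on_unknown = c("warn", "error")) {
  on_unknown <- match.arg(on_unknown)
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  r <- .vdw_radii[key]
  bad <- is.na(r)
  if (any(bad)) {
    if (on_unknown == "error") {
      stop("unknown element symbol(s): ", paste(unique(element[bad]), collapse = ", "))
    }
    warning("unknown element symbol(s) ", paste(unique(element[bad]), collapse = ", "),
            "; using fallback radius ", fallback, " A")
    r[bad] <- fallback
  }
  unname(r)
}

#' Map an element symbol to its voxel element channel
#'
#' Channels follow the fixed order C, H, O, N, S, P, X where X groups the
#' halogens F, Cl, Br and I. Elements outside this set (metals, Se, B, ...)
#' have no element channel and contribute only to the charge and SASA
#' channels of the voxel tensor.
#'
#' @param element Character vector of element symbols.
#' @return Integer vector of 1-based channel indices (1-7), `NA` where the
#'   element carries no element channel.
#' @export
#' @examples
#' element_channel(c("C", "P", "Cl", "Fe"))  # 1 6 7 NA
element_channel <- function(element) {
  key <- toupper(element)
  ch <- match(key, c("C", "H", "O", "N", "S", "P"))
  ch[key %in% c("F", "CL", "BR", "I")] <- 7L
  ch
}

#' Voxel channel names in storage order
#' @return Character vector of length 9.
#' @export
voxel_channels <- function() {
  c("C", "H", "O", "N", "S", "P", "X", "charge", "sasa")
}

.std_amino <- function() {
  c(aa_alphabet(), "MSE", "SEC", "PYL")
}

.std_nucleic <- function() {
  c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU", "I", "DI")
}

.ion_residues <- function() {
  c("NA", "K", "CL", "MG", "CA", "ZN", "FE", "MN", "CU", "NI", "CO",
    "CD", "HG", "BR", "IOD", "F", "LI", "RB", "CS", "SR", "BA", "AL")
}

# entity class from residue name + HETATM flag + atom count of the residue
classify_entity <- function(residue_name, is_hetatm, n_atoms_in_residue) {
  res <- toupper(residue_name)
  out <- rep("ligand", length(res))
  out[res %in% .std_amino()] <- "protein"
  out[res %in% .std_nucleic() & !is_hetatm] <- "nucleic"
  out[res %in% c("HOH", "WAT", "DOD")] <- "water"
  out[res %in% .ion_residues() & n_atoms_in_residue == 1L] <- "ion"
  out
}
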