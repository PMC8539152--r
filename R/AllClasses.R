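#' @import methods
NULL

SUPPORTED_ELEMENTS <- c("H", "B", "C", "N", "O", "P", "S", "Si",
                        "F", "Cl", "Br", "I")

## canonical neighbor ordering used throughout the group grammar;
## iodine is spelled "J" in rendered keys (see renderGroupKey)
ELEMENT_RANK <- c(H = 1, B = 2, C = 3, N = 4, O = 5, S = 6, P = 7,
                  Si = 8, F = 9, Cl = 10, Br = 11, I = 12)

#' MolecularGraph: atoms, typed bonds and optional 3D coordinates
#'
#' The central molecular data container. Atoms are rows of a data.frame with
#' columns \code{element}, \code{charge}, \code{x}, \code{y}, \code{z} (NA
#' when no geometry is stored) and the derived annotations \code{hyb}
#' (\code{"sp3"}, \code{"sp2"}, \code{"sp"}, \code{"aromatic"} or
#' \code{"none"}) and \code{aromatic}. Bonds are rows with columns
#' \code{a1}, \code{a2} and \code{order} (\code{"single"}, \code{"double"},
#' \code{"triple"}, \code{"aromatic"}). Hydrogens are explicit: every reader
#' materializes them from implicit valence before returning.
#'
#' @slot atoms data.frame of atoms.
#' @slot bonds data.frame of bonds.
#' @slot name character(1), free-text molecule name.
#' @slot has3d logical(1), TRUE when all atoms carry coordinates.
#' @exportClass MolecularGraph
setClass("MolecularGraph",
         representation(atoms = "data.frame", bonds = "data.frame",
                        name = "character", has3d = "logical"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  if (!all(c("element", "charge") %in% names(a)))
    msgs <- c(msgs, "atoms need 'element' and 'charge' columns")
  else {
    if (!all(a$element %in% SUPPORTED_ELEMENTS))
      msgs <- c(msgs, sprintf("unsupported element(s): %s",
                              paste(setdiff(a$element, SUPPORTED_ELEMENTS),
                                    collapse = ", ")))
    if (!all(a$charge %in% -1:1))
      msgs <- c(msgs, "formal charges must be -1, 0 or +1")
  }
  if (nrow(b) > 0) {
    if (!all(c(b$a1, b$a2) %in% seq_len(nrow(a))))
      msgs <- c(msgs, "bond endpoints out of range")
    if (!all(b$order %in% c("single", "double", "triple", "aromatic")))
      msgs <- c(msgs, "unknown bond order")
  }
  ## coordinates all present or all absent
  if (nrow(a) > 0) {
    miss <- is.na(a$x) | is.na(a$y) | is.na(a$z)
    if (any(miss) && !all(miss))
      msgs <- c(msgs, "coordinates must be present for all atoms or none")
    if (object@has3d && any(miss))
      msgs <- c(msgs, "has3d is TRUE but coordinates are missing")
  }
  if (length(msgs)) msgs else TRUE
})

#' Decomposition of a molecule into additive groups
#'
#' The occurrence vector of the additivity equation: one ordinary atom group
#' per backbone atom (an atom bound to at least two other atoms, hydrogens
#' counted) plus the special groups (H bridges, H-H contacts, ring-strain
#' angle classes). Atoms whose rendered key is not in the contribution table
#' are listed in \code{uncovered}.
#'
#' @slot ordinary named integer vector, key -> count, for atom groups.
#' @slot special named integer vector, key -> count, for special groups.
#' @slot uncovered integer vector of atom indices with no table row.
#' @slot name character(1), molecule name.
#' @exportClass Decomposition
setClass("Decomposition",
         representation(ordinary = "integer", special = "integer",
                        uncovered = "integer", name = "character"))

#' Table of fitted group contributions
#'
#' One row per group: the additive contribution in kJ/mol, the number of
#' occurrences and of distinct molecules supporting it in the training set,
#' and the validity flag (supported by at least \code{min_molecules}
#' independent molecules; predictions are restricted to valid groups).
#'
#' @slot data data.frame with columns \code{key}, \code{atom_type},
#'   \code{neighbors}, \code{contribution}, \code{occurrences},
#'   \code{molecules}, \code{valid}.
#' @slot min_molecules integer(1), validity threshold applied.
#' @slot checksum character(1), MD5 of the source file ("" for in-memory).
#' @exportClass ContributionTable
setClass("ContributionTable",
         representation(data = "data.frame", min_molecules = "integer",
                        checksum = "character"))

setValidity("ContributionTable", function(object) {
  d <- object@data
  need <- c("key", "atom_type", "neighbors", "contribution",
            "occurrences", "molecules", "valid")
  if (!all(need %in% names(d)))
    return(paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$key)) return("duplicate group keys")
  if (!identical(d$valid, d$molecules >= object@min_molecules))
    return("valid flag inconsistent with min_molecules")
  TRUE
})

#' Result of evaluating the additivity equation for one molecule
#'
#' @slot hc numeric(1), predicted standard heat of combustion, kJ/mol.
#' @slot hf numeric(1), heat of formation, kJ/mol (NA unless requested).
#' @slot terms data.frame with one row per group: key, count, contribution,
#'   product.
#' @slot computable logical(1), FALSE when blockers are present and strict
#'   evaluation was requested.
#' @slot blockers character vector of unknown or invalid group keys.
#' @slot name character(1).
#' @exportClass HcPrediction
setClass("HcPrediction",
         representation(hc = "numeric", hf = "numeric", terms = "data.frame",
                        computable = "logical", blockers = "character",
                        name = "character"))

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph '%s': %d atoms (%d heavy), %d bonds, %s\n",
              object@name, nrow(object@atoms),
              sum(object@atoms$element != "H"), nrow(object@bonds),
              if (object@has3d) "3D" else "topology only"))
  invisible(object)
})

setMethod("show", "Decomposition", function(object) {
  cat(sprintf("Decomposition '%s'\n", object@name))
  if (length(object@ordinary)) {
    cat("  atom groups:\n")
    for (k in names(object@ordinary))
      cat(sprintf("    %-28s %d\n", k, object@ordinary[[k]]))
  }
  if (length(object@special)) {
    cat("  special groups:\n")
    for (k in names(object@special))
      cat(sprintf("    %-28s %d\n", k, object@special[[k]]))
  }
  if (length(object@uncovered))
    cat("  uncovered atoms:", paste(object@uncovered, collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ContributionTable", function(object) {
  cat(sprintf("ContributionTable: %d groups, %d valid (min_molecules = %d)\n",
              nrow(object@data), sum(object@data$valid), object@min_molecules))
  invisible(object)
})

setMethod("show", "HcPrediction", function(object) {
  cat(sprintf("HcPrediction '%s': dHc = %.2f kJ/mol%s%s\n", object@name,
              object@hc,
              if (!is.na(object@hf)) sprintf(", dHf = %.2f kJ/mol", object@hf) else "",
              if (object@computable) "" else " [NOT COMPUTABLE]"))
  if (length(object@blockers))
    cat("  blockers:", paste(object@blockers, collapse = "; "), "\n")
  invisible(object)
})

## ---- accessors -------------------------------------------------------------

#' @describeIn MolecularGraph-class atom table accessor
#' @param x object
#' @export
atoms <- function(x) x@atoms

#' @describeIn MolecularGraph-class bond table accessor
#' @export
bonds <- function(x) x@bonds

#' Molecule name accessor
#' @param x a MolecularGraph, Decomposition or HcPrediction
#' @export
molName <- function(x) x@name

#' Number of atoms (hydrogens included)
#' @param x a MolecularGraph
#' @export
atomCount <- function(x) nrow(x@atoms)

#' Net formal charge of the molecule (sum over atoms)
#' @param x a MolecularGraph
#' @export
netCharge <- function(x) sum(x@atoms$charge)

#' Elemental formula as a named count vector
#' @param x a MolecularGraph
#' @export
elementCounts <- function(x) {
  tab <- table(factor(x@atoms$element, levels = SUPPORTED_ELEMENTS))
  cnt <- as.integer(tab)
  names(cnt) <- names(tab)
  cnt[cnt > 0]
}

#' Ordinary (atom) group counts of a decomposition
#' @param x a Decomposition
#' @export
ordinaryGroups <- function(x) x@ordinary

#' Special group counts of a decomposition
#' @param x a Decomposition
#' @export
specialGroups <- function(x) x@special

#' Atom indices not covered by any table row
#' @param x a Decomposition
#' @export
uncoveredAtoms <- function(x) x@uncovered

#' All group counts (ordinary + special) as one named vector
#' @param x a Decomposition
#' @export
groupCounts <- function(x) c(x@ordinary, x@special)

#' Predicted heat of combustion (kJ/mol)
#' @param x an HcPrediction
#' @export
hcValue <- function(x) x@hc

#' Predicted heat of formation (kJ/mol), NA unless computed
#' @param x an HcPrediction
#' @export
hfValue <- function(x) x@hf

#' Per-group terms of a prediction
#' @param x an HcPrediction
#' @export
predictionTerms <- function(x) x@terms

#' Is the prediction computable under the validity rule?
#' @param x an HcPrediction
#' @export
isComputable <- function(x) x@computable

#' Blocking (unknown or invalid) group keys of a prediction
#' @param x an HcPrediction
#' @export
blockers <- function(x) x@blockers

newMolecularGraph <- function(atoms, bonds, name = "", has3d = FALSE) {
  if (is.null(atoms$x)) atoms$x <- NA_real_
  if (is.null(atoms$y)) atoms$y <- NA_real_
  if (is.null(atoms$z)) atoms$z <- NA_real_
  if (is.null(atoms$hyb)) atoms$hyb <- NA_character_
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  rownames(atoms) <- NULL
  if (nrow(bonds)) rownames(bonds) <- NULL
  m <- new("MolecularGraph", atoms = atoms, bonds = bonds,
           name = as.character(name), has3d = isTRUE(has3d))
  perceiveHybridization(m)
}
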