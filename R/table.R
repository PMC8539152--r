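## Packaged, versioned contribution table (390 atom and special groups with
## their kJ/mol contributions, occurrence and molecule counts) plus the
## element combustion constants used for heat-of-formation conversion.

CONTRIB_N_GROUPS <- 390L
## MD5 of the packaged TSV, frozen at packaging time; loadContributionTable
## refuses silently corrupted copies.
CONTRIB_TABLE_MD5 <- "44bef3876dcb1ae87b2554c330a191fd"

#' Load the packaged group-contribution table
#'
#' Reads the packaged machine-readable contribution table (390 atom and
#' special groups: contribution in kJ/mol, number of occurrences and of
#' supporting molecules) and applies the validity rule: a group is valid
#' when supported by at least \code{min_molecules} independent molecules.
#' Predictions in strict mode are restricted to valid groups.
#'
#' @param path optional path to a TSV with columns \code{atom_type},
#'   \code{neighbors}, \code{contribution}, \code{occurrences},
#'   \code{molecules}; defaults to the packaged table (whose row count and
#'   checksum are verified).
#' @param min_molecules validity threshold, default 3.
#' @return a \linkS4class{ContributionTable}.
#' @examples
#' tab <- loadContributionTable()
#' contributionOf(tab, "C sp3", "H3C")
#' @export
loadContributionTable <- function(path = NULL, min_molecules = 3L) {
  packaged <- is.null(path)
  if (packaged)
    path <- system.file("extdata", "group_contributions.tsv",
                        package = "hcgroups", mustWork = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "",
                         colClasses = c(atom_type = "character",
                                        neighbors = "character"),
                         stringsAsFactors = FALSE, na.strings = NULL)
  d$neighbors[is.na(d$neighbors)] <- ""
  checksum <- unname(tools::md5sum(path))
  if (packaged) {
    if (nrow(d) != CONTRIB_N_GROUPS)
      stop("DataIntegrityError: expected ", CONTRIB_N_GROUPS,
           " packaged groups, found ", nrow(d))
    if (!grepl("^@", CONTRIB_TABLE_MD5) && !identical(checksum, CONTRIB_TABLE_MD5))
      stop("DataIntegrityError: packaged table checksum mismatch")
  }
  d$key <- renderGroupKey(d$atom_type, d$neighbors)
  d$valid <- d$molecules >= min_molecules
  d <- d[, c("key", "atom_type", "neighbors", "contribution",
             "occurrences", "molecules", "valid")]
  new("ContributionTable", data = d,
      min_molecules = as.integer(min_molecules), checksum = checksum)
}

#' Re-flag table validity against a different molecule threshold
#'
#' Returns a new table whose \code{valid} flags reflect
#' \code{min_molecules}; the input is never mutated.
#'
#' @param table a \linkS4class{ContributionTable}.
#' @param min_molecules minimum number of supporting molecules.
#' @return a new \linkS4class{ContributionTable}.
#' @export
validityFilter <- function(table, min_molecules = 3L) {
  d <- table@data
  d$valid <- d$molecules >= min_molecules
  new("ContributionTable", data = d,
      min_molecules = as.integer(min_molecules), checksum = table@checksum)
}

#' Look up one group contribution
#'
#' @param table a \linkS4class{ContributionTable}.
#' @param atom_type atom-type token (e.g. \code{"C sp3"}, \code{"Angle90"}).
#' @param neighbors neighbor descriptor (\code{""} for angle groups).
#' @return one-row data.frame (contribution, occurrences, molecules,
#'   valid), or NULL when the key is absent.
#' @export
contributionOf <- function(table, atom_type, neighbors = "") {
  key <- renderGroupKey(atom_type, neighbors)
  d <- table@data
  hit <- d[d$key == key, , drop = FALSE]
  if (!nrow(hit)) return(NULL)
  hit
}

#' Number of valid groups in a table
#' @param table a \linkS4class{ContributionTable}
#' @export
validGroupCount <- function(table) sum(table@data$valid)

#' Build a ContributionTable from keys and values (used by the trainer)
#'
#' @param keys character vector of group keys ("atom_type|neighbors").
#' @param contributions numeric vector, kJ/mol.
#' @param occurrences,molecules integer support counts (default 0).
#' @param min_molecules validity threshold.
#' @return a \linkS4class{ContributionTable}.
#' @export
makeContributionTable <- function(keys, contributions, occurrences = 0L,
                                  molecules = 0L, min_molecules = 3L) {
  parts <- strsplit(keys, GROUP_KEY_SEP, fixed = TRUE)
  d <- data.frame(
    key = keys,
    atom_type = vapply(parts, `[`, character(1), 1),
    neighbors = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                       character(1)),
    contribution = as.numeric(contributions),
    occurrences = as.integer(occurrences),
    molecules = as.integer(molecules),
    stringsAsFactors = FALSE)
  d$valid <- d$molecules >= min_molecules
  new("ContributionTable", data = d,
      min_molecules = as.integer(min_molecules), checksum = "")
}

#' Load the element combustion-enthalpy constants
#'
#' Per-atom standard combustion enthalpies of the elements (kJ/mol) under
#' a documented product convention (CO2(g), H2O(l), N2(g), SO2(g), ...),
#' used to convert a heat of combustion into a heat of formation by
#' Hess's law. The packaged defaults can be overridden by pointing
#' \code{path} at a YAML file of the same shape.
#'
#' @param path optional YAML path; default: packaged constants.
#' @return list with elements \code{elements} (named numeric vector) and
#'   \code{convention} (character).
#' @export
loadElementCombustion <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "element_combustion.yaml",
                        package = "hcgroups", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  vals <- unlist(y$elements)
  storage.mode(vals) <- "double"
  list(elements = vals, convention = as.character(y$convention))
}
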