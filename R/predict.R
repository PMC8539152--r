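## Evaluation of the additivity equation
##    dHc = sum_i a_i * A_i + sum_j b_j * B_j
## over a decomposition, plus the conversion to the heat of formation and
## the kcal -> kJ unit conversion.

KCAL_TO_KJ <- 4.1858

#' Convert kcal/mol to kJ/mol
#' @param x numeric, kcal/mol.
#' @return numeric, kJ/mol (x * 4.1858).
#' @export
kcalToKj <- function(x) x * KCAL_TO_KJ

#' Evaluate the additivity equation for a decomposition
#'
#' Sums count times contribution over all groups of the decomposition.
#' In strict mode the prediction is marked non-computable when any
#' required group is unknown to the table, not valid (supported by fewer
#' than the table's minimum number of independent molecules), or when the
#' decomposition left atoms uncovered; the offending keys are reported as
#' blockers. In lenient mode the sum is formed over the known groups
#' anyway and the blockers are still reported.
#'
#' @param decomp a \linkS4class{Decomposition}.
#' @param table a \linkS4class{ContributionTable}.
#' @param strict logical, default TRUE.
#' @return an \linkS4class{HcPrediction}.
#' @export
predictHc <- function(decomp, table, strict = TRUE) {
  counts <- groupCounts(decomp)
  d <- table@data
  idx <- match(names(counts), d$key)
  terms <- data.frame(
    key = if (length(counts)) names(counts) else character(),
    count = as.integer(counts),
    contribution = d$contribution[idx],
    stringsAsFactors = FALSE)
  terms$product <- terms$count * terms$contribution
  blockers <- character()
  if (any(is.na(idx)))
    blockers <- c(blockers, paste0("unknown: ", terms$key[is.na(idx)]))
  invalid <- !is.na(idx) & !d$valid[idx]
  if (any(invalid))
    blockers <- c(blockers, paste0("invalid: ", terms$key[invalid]))
  if (length(decomp@uncovered))
    blockers <- c(blockers, paste0("uncovered atom: ", decomp@uncovered))
  computable <- length(blockers) == 0 && length(counts) > 0
  hc <- sum(terms$product, na.rm = TRUE)
  if (strict && !computable) hc <- NA_real_
  new("HcPrediction", hc = hc, hf = NA_real_, terms = terms,
      computable = computable, blockers = blockers, name = decomp@name)
}

#' Heat of formation from a heat of combustion by Hess's law
#'
#' \code{hf = sum_e n_e * c_e - hc}, where \code{n_e} counts the atoms of
#' element e and \code{c_e} is the element's standard combustion enthalpy
#' under the packaged product convention.
#'
#' @param hc heat of combustion, kJ/mol.
#' @param formula named integer vector of element counts (see
#'   \code{\link{elementCounts}}).
#' @param constants result of \code{\link{loadElementCombustion}}.
#' @return heat of formation, kJ/mol.
#' @export
predictHf <- function(hc, formula, constants = loadElementCombustion()) {
  els <- names(formula)
  missing <- setdiff(els, names(constants$elements))
  if (length(missing))
    stop("ElementNotSupported: no combustion constant for ",
         paste(missing, collapse = ", "))
  sum(constants$elements[els] * as.numeric(formula)) - hc
}

#' Full structure-to-enthalpy prediction pipeline
#'
#' Convenience wrapper: normalize, decompose, evaluate the additivity
#' equation, and optionally convert to the heat of formation.
#'
#' @param mol a \linkS4class{MolecularGraph} (or SMILES string).
#' @param table a \linkS4class{ContributionTable}; default: packaged table.
#' @param strict passed to \code{\link{predictHc}}.
#' @param geometry_policy passed to \code{\link{decompose}}.
#' @param zwitterion_policy passed to \code{\link{normalizeConventions}}.
#' @param hf logical: also compute the heat of formation.
#' @param constants combustion constants for \code{hf = TRUE}.
#' @return an \linkS4class{HcPrediction}.
#' @examples
#' p <- predictMolecule("CC(=O)C")
#' round(hcValue(p), 1)   # -1791.0
#' @export
predictMolecule <- function(mol, table = loadContributionTable(),
                            strict = TRUE,
                            geometry_policy = c("topology_only", "use_3d"),
                            zwitterion_policy = c("as_drawn", "auto"),
                            hf = FALSE,
                            constants = NULL) {
  geometry_policy <- match.arg(geometry_policy)
  zwitterion_policy <- match.arg(zwitterion_policy)
  if (is.character(mol)) mol <- parseSmiles(mol, name = mol)
  mol <- normalizeConventions(mol, zwitterion_policy)
  dec <- decompose(mol, table, geometry_policy)
  pred <- predictHc(dec, table, strict = strict)
  if (hf && (pred@computable || !strict)) {
    if (is.null(constants)) constants <- loadElementCombustion()
    pred@hf <- predictHf(pred@hc, elementCounts(mol), constants)
  }
  pred
}
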