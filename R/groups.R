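## Group perception: every backbone atom (bound to at least two other
## atoms, hydrogens counted) is typed by element/charge/hybridization and
## described by its immediate neighbors in a fixed canonical spelling that
## matches the packaged contribution table character for character.

GROUP_KEY_SEP <- "|"

#' Render a group key from its atom-type and neighbor parts
#' @param atom_type atom-type token, e.g. \code{"C sp3"}.
#' @param neighbors neighbor descriptor, e.g. \code{"H2C2"} ("" for angle groups).
#' @return character key used for table lookup.
#' @export
renderGroupKey <- function(atom_type, neighbors) {
  paste(atom_type, neighbors, sep = GROUP_KEY_SEP)
}

chargeTag <- function(chg) {
  if (chg > 0) "(+)" else if (chg < 0) "(-)" else ""
}

#' Atom-type token of a backbone atom
#'
#' Combines element, central-charge marker and hybridization class:
#' \code{"C sp3"}, \code{"C(+) aromatic"}, \code{"N(+) sp2"} and so on.
#' Sulfur and phosphorus carry a valence class instead (\code{"S2"} for
#' divalent sulfur, \code{"S4"} for hypervalent; \code{"P3"}/\code{"P4"});
#' oxygen, silicon and boron carry no hybridization.
#'
#' @param mol a normalized \linkS4class{MolecularGraph}.
#' @param i atom index (must be a backbone atom).
#' @return character(1) atom-type token.
#' @export
classifyAtom <- function(mol, i) {
  a <- mol@atoms
  el <- a$element[i]; chg <- a$charge[i]; hyb <- a$hyb[i]
  switch(el,
    C = paste0("C", chargeTag(chg), " ", hyb),
    N = if (chg < 0) "N(-)" else paste0("N", chargeTag(chg), " ", hyb),
    O = "O",
    S = if (bondOrderSum(mol, i) <= 2.25) "S2" else "S4",
    P = if (bondOrderSum(mol, i) <= 3.25) "P3" else "P4",
    Si = "Si",
    B = paste0("B", chargeTag(chg)),
    stop("UnknownAtomType: element ", el, " cannot be a group center"))
}

#' Canonical neighbor descriptor of a backbone atom
#'
#' Hydrogen count first (\code{"H"}, \code{"H2"}, \code{"H3"}), then heavy
#' neighbors grouped by (element, bond marker) with multiplicity digits,
#' in the fixed element order H, B, C, N, O, S, P, Si, F, Cl, Br, J and
#' marker order plain, \code{"="}, \code{"#"}, \code{":"} within an
#' element (iodine is spelled \code{"J"}). A single \code{"(+)"} or
#' \code{"(-)"} suffix records a charged neighbor. For central atoms of
#' type neutral N sp3, O and S2 (all-single-bond centers) the
#' pi-membership of the neighbors is expressed as a trailing
#' \code{"(pi)"}, \code{"(2pi)"} or \code{"(3pi)"} count (a neighbor is a
#' pi member when it is aromatic, sp2 or sp) instead of per-neighbor
#' markers.
#'
#' @inheritParams classifyAtom
#' @return character(1) neighbor descriptor.
#' @export
encodeNeighbors <- function(mol, i) {
  a <- mol@atoms
  nb <- neighborsOf(mol, i)
  hn <- sum(a$element[nb] == "H")
  heavy <- nb[a$element[nb] != "H"]
  el <- a$element[i]; chg <- a$charge[i]
  pimode <- (el == "N" && chg == 0 && a$hyb[i] == "sp3") ||
            (el == "O" && chg == 0 && !a$aromatic[i]) ||
            (el == "S" && chg == 0 && bondOrderSum(mol, i) <= 2.25)
  marker_of <- c(single = "", double = "=", triple = "#", aromatic = ":")
  toks <- data.frame(elem = character(), marker = character(),
                     stringsAsFactors = FALSE)
  pos_suffix <- FALSE; neg_suffix <- FALSE
  npi <- 0L
  for (j in heavy) {
    kb <- bondBetween(mol, i, j)
    mk <- if (pimode) "" else marker_of[[mol@bonds$order[kb]]]
    elj <- a$element[j]
    if (elj == "I") elj <- "J"
    if (a$charge[j] > 0) pos_suffix <- TRUE
    if (a$charge[j] < 0) neg_suffix <- TRUE
    ## pi membership: unsaturated carbon and nitrogen neighbors only;
    ## formally hypervalent centers (sulfate S, phosphate P) do not count
    if (pimode && elj %in% c("C", "N") &&
        a$hyb[j] %in% c("sp", "sp2", "aromatic")) npi <- npi + 1L
    toks <- rbind(toks, data.frame(elem = elj, marker = mk,
                                   stringsAsFactors = FALSE))
  }
  out <- if (hn > 0) paste0("H", if (hn > 1) hn else "") else ""
  if (nrow(toks)) {
    rank_el <- ELEMENT_RANK[ifelse(toks$elem == "J", "I", toks$elem)]
    key <- paste(formatC(rank_el, width = 2, flag = "0"),
                 match(toks$marker, c("", "=", "#", ":")), sep = "-")
    tab <- table(key)
    ord <- sort(names(tab))
    for (g in ord) {
      first <- which(key == g)[1]
      cnt <- tab[[g]]
      out <- paste0(out, toks$marker[first], toks$elem[first],
                    if (cnt > 1) cnt else "")
    }
  }
  if (pos_suffix) out <- paste0(out, "(+)")
  if (neg_suffix) out <- paste0(out, "(-)")
  if (pimode && npi > 0)
    out <- paste0(out, "(", if (npi > 1) npi else "", "pi)")
  out
}

#' Count intramolecular hydrogen-bridge special groups ("H Acceptor")
#'
#' One count per acidic hydrogen (attached to O, N or S) that lies closer
#' than 1.75 Angstrom to a non-bonded acceptor atom (O, N or F).
#'
#' @param mol a MolecularGraph with 3D coordinates.
#' @return integer count.
#' @export
detectHbondGroups <- function(mol) {
  if (!mol@has3d) stop("GeometryRequired: H-bridge detection needs 3D coordinates")
  a <- mol@atoms
  adj <- adjacencyList(mol)
  count <- 0L
  for (h in which(a$element == "H")) {
    parent <- adj[[h]]
    if (!length(parent) || !a$element[parent[1]] %in% c("O", "N", "S")) next
    acceptors <- setdiff(which(a$element %in% c("O", "N", "F")), c(parent, h))
    for (acc in acceptors) {
      if (interatomicDistance(mol, h, acc) < 1.75) { count <- count + 1L; break }
    }
  }
  count
}

#' Count close intramolecular H-H contact special groups (".H" and "..H")
#'
#' Non-bonded hydrogen pairs, excluding geminal pairs (same heavy atom)
#' and vicinal pairs (attached to bonded heavy atoms): a distance below
#' 2.0 Angstrom counts as \code{".H"}, between 2.0 and 2.3 as \code{"..H"}.
#'
#' @param mol a MolecularGraph with 3D coordinates.
#' @return named integer vector \code{c(".H" = , "..H" = )}.
#' @export
detectHhContacts <- function(mol) {
  if (!mol@has3d) stop("GeometryRequired: H-H contact detection needs 3D coordinates")
  a <- mol@atoms
  adj <- adjacencyList(mol)
  hs <- which(a$element == "H")
  close1 <- 0L; close2 <- 0L
  if (length(hs) > 1) {
    for (p in seq_len(length(hs) - 1)) {
      for (q in seq(p + 1, length(hs))) {
        h1 <- hs[p]; h2 <- hs[q]
        p1 <- adj[[h1]]; p2 <- adj[[h2]]
        if (!length(p1) || !length(p2)) next
        p1 <- p1[1]; p2 <- p2[1]
        if (p1 == p2) next
        if (length(bondBetween(mol, p1, p2))) next
        d <- interatomicDistance(mol, h1, h2)
        if (d < 2.0) close1 <- close1 + 1L
        else if (d <= 2.3) close2 <- close2 + 1L
      }
    }
  }
  c(".H" = close1, "..H" = close2)
}

#' Count ring-strain angle special groups (Angle60 / Angle90 / Angle102)
#'
#' With 3D geometry each ring atom's intra-ring bond angle is binned:
#' below 74 degrees Angle60, 74-98 Angle90, 98-106 Angle102, above 106
#' nothing. Without geometry (\code{"topology_only"}) three-ring atoms are
#' assigned Angle60 and four-ring atoms Angle90; five-membered and larger
#' rings are not auto-assigned, because their strain class depends on the
#' actual conformation.
#'
#' @param mol a MolecularGraph.
#' @param geometry_policy \code{"use_3d"} or \code{"topology_only"}.
#' @return named integer vector over Angle60, Angle90, Angle102.
#' @export
detectAngleGroups <- function(mol, geometry_policy = c("topology_only", "use_3d")) {
  geometry_policy <- match.arg(geometry_policy)
  rings <- smallestRings(mol)
  out <- c(Angle60 = 0L, Angle90 = 0L, Angle102 = 0L)
  for (ring in rings) {
    n <- length(ring)
    if (geometry_policy == "use_3d") {
      if (!mol@has3d) stop("GeometryRequired: angle binning needs 3D coordinates")
      for (k in seq_len(n)) {
        left <- ring[if (k == 1) n else k - 1]
        right <- ring[if (k == n) 1 else k + 1]
        ang <- bondAngle(mol, left, ring[k], right)
        if (ang < 74) out["Angle60"] <- out["Angle60"] + 1L
        else if (ang < 98) out["Angle90"] <- out["Angle90"] + 1L
        else if (ang <= 106) out["Angle102"] <- out["Angle102"] + 1L
      }
    } else {
      if (n == 3) out["Angle60"] <- out["Angle60"] + 3L
      else if (n == 4) out["Angle90"] <- out["Angle90"] + 4L
    }
  }
  out
}

#' Decompose a molecule into its additive groups
#'
#' Assigns one ordinary atom group to every backbone atom and appends the
#' special groups (ring-strain angle classes always; H bridges and H-H
#' contacts when 3D geometry is used). Atoms whose rendered key has no row
#' in the contribution table are reported in \code{uncovered}, not treated
#' as fatal.
#'
#' @param mol a \linkS4class{MolecularGraph}; call
#'   \code{\link{normalizeConventions}} first.
#' @param table optional \linkS4class{ContributionTable} used to flag
#'   uncovered atoms (without it nothing is flagged).
#' @param geometry_policy \code{"topology_only"} (default) or
#'   \code{"use_3d"}; the latter requires coordinates and additionally
#'   detects H bridges and H-H contacts.
#' @return a \linkS4class{Decomposition}.
#' @examples
#' tab <- loadContributionTable()
#' dk <- parseSmiles("C1(=C)OC(=O)C1", "diketene")
#' decompose(normalizeConventions(dk), tab)
#' @export
decompose <- function(mol, table = NULL,
                      geometry_policy = c("topology_only", "use_3d")) {
  geometry_policy <- match.arg(geometry_policy)
  mol <- perceiveHybridization(mol)
  a <- mol@atoms
  deg <- vapply(seq_len(nrow(a)), function(i) degreeOf(mol, i), integer(1))
  backbone <- which(a$element != "H" & deg >= 2)
  keys <- vapply(backbone, function(i)
    renderGroupKey(classifyAtom(mol, i), encodeNeighbors(mol, i)), character(1))
  ordinary <- integer()
  uncovered <- integer()
  known <- if (!is.null(table)) table@data$key else NULL
  for (k in seq_along(backbone)) {
    key <- keys[k]
    if (!is.null(known) && !(key %in% known)) {
      uncovered <- c(uncovered, backbone[k])
    } else {
      ordinary[key] <- if (is.na(ordinary[key])) 1L else ordinary[key] + 1L
    }
  }
  special <- integer()
  ang <- detectAngleGroups(mol, geometry_policy)
  for (nm in names(ang))
    if (ang[[nm]] > 0) special[renderGroupKey(nm, "")] <- ang[[nm]]
  if (geometry_policy == "use_3d") {
    hb <- detectHbondGroups(mol)
    if (hb > 0) special[renderGroupKey("H", "H Acceptor")] <- hb
    hh <- detectHhContacts(mol)
    if (hh[[".H"]] > 0) special[renderGroupKey("H", ".H")] <- hh[[".H"]]
    if (hh[["..H"]] > 0) special[renderGroupKey("H", "..H")] <- hh[["..H"]]
  }
  new("Decomposition", ordinary = ordinary, special = special,
      uncovered = uncovered, name = mol@name)
}
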