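## Normalization to the database's structural conventions:
##  (a) six-membered aromatic rings carry six aromatic bonds (never the
##      alternating single/double style);
##  (b) five-membered heteroaromatics are stored in kekule form (their ring
##      atoms are typed sp2/sp3 with pi-environment counting, not aromatic);
##  (c) in amidinium, guanidinium and imidazolium fragments the positive
##      charge sits on the carbon between the nitrogens and the C-N bonds
##      of the fragment are aromatic;
##  (d) molecules with both a carboxylic acid and an aliphatic primary
##      amine or guanidine may be converted to the zwitterion.

#' Normalize a molecule to the structural conventions of the group grammar
#'
#' @param mol a \linkS4class{MolecularGraph}.
#' @param zwitterion_policy \code{"as_drawn"} keeps input charges;
#'   \code{"auto"} converts molecules containing both a carboxylic acid and
#'   an aliphatic primary amine or a guanidine into the zwitterion (the
#'   proton moves from O to N; anilines and secondary amines are never
#'   auto-converted).
#' @return the normalized molecule. The function is idempotent and
#'   conserves net charge.
#' @export
normalizeConventions <- function(mol, zwitterion_policy = c("as_drawn", "auto")) {
  zwitterion_policy <- match.arg(zwitterion_policy)
  mol <- perceiveHybridization(mol)
  rings <- smallestRings(mol)
  mol <- aromatizeSixRings(mol, rings)
  mol <- relocateAmidiniumCharge(mol, rings)
  mol <- kekulizeResidualAromatic(mol, rings)
  if (zwitterion_policy == "auto") {
    mol <- autoZwitterionize(mol)
    ## a protonated guanidine becomes an amidinium fragment
    mol <- relocateAmidiniumCharge(mol, smallestRings(mol))
    mol <- kekulizeResidualAromatic(mol, smallestRings(mol))
  }
  perceiveHybridization(mol)
}

## six-membered rings drawn kekule (alternating single/double, every atom
## C or N) are rewritten with six aromatic bonds; rings read in aromatic
## form already satisfy the convention
aromatizeSixRings <- function(mol, rings) {
  for (ring in rings) {
    if (length(ring) != 6) next
    el <- mol@atoms$element[ring]
    if (!all(el %in% c("C", "N"))) next
    kb <- ringBondIndices(mol, ring)
    ord <- mol@bonds$order[kb]
    if (all(ord == "aromatic")) next
    if (sum(ord == "double") == 3 && sum(ord == "single") == 3 &&
        isAlternating(mol, ring, kb)) {
      mol@bonds$order[kb] <- "aromatic"
    }
  }
  perceiveHybridization(mol)
}

ringBondIndices <- function(mol, ring) {
  n <- length(ring)
  vapply(seq_len(n), function(k)
    bondBetween(mol, ring[k], ring[if (k == n) 1 else k + 1])[1], integer(1))
}

isAlternating <- function(mol, ring, kb) {
  ord <- mol@bonds$order[kb]
  d <- ord == "double"
  all(d != c(d[-1], d[1]))
}

## positive charge moved from N to the carbon between the nitrogens; the
## fragment's C-N bonds become aromatic. Covers amidinium / guanidinium
## drawn as C=N(+), and imidazolium read as an aromatic 5-ring.
relocateAmidiniumCharge <- function(mol, rings) {
  a <- mol@atoms
  repeat {
    hit <- FALSE
    for (ci in which(a$element == "C")) {
      nb <- neighborsOf(mol, ci)
      nN <- nb[a$element[nb] == "N"]
      if (length(nN) < 2) next
      ## case 1: C=N(+) double bond with at least one further N neighbor
      cation <- NA_integer_
      for (j in nN) {
        kb <- bondBetween(mol, ci, j)
        if (mol@bonds$order[kb] == "double" && a$charge[j] == 1) cation <- j
      }
      ## case 2: aromatic five-ring C flanked by two aromatic N, one ring
      ## atom positively charged (imidazolium as parsed from SMILES)
      ring5 <- NULL
      if (is.na(cation)) {
        for (ring in rings) {
          if (length(ring) != 5 || !(ci %in% ring)) next
          kb <- ringBondIndices(mol, ring)
          if (!all(mol@bonds$order[kb] == "aromatic")) next
          flank <- intersect(nN, ring)
          if (length(flank) == 2 && any(a$charge[ring] == 1)) {
            cation <- ring[a$charge[ring] == 1][1]
            ring5 <- ring
            break
          }
        }
      }
      if (is.na(cation) || a$charge[ci] != 0) next
      ## move the charge and aromatize the N-C(+)-N fragment
      a$charge[cation] <- a$charge[cation] - 1L
      a$charge[ci] <- 1L
      targets <- if (is.null(ring5)) nN else intersect(nN, ring5)
      for (j in targets) {
        kb <- bondBetween(mol, ci, j)
        mol@bonds$order[kb] <- "aromatic"
      }
      ## an N that lost its proton count keeps its H atoms: charge moved,
      ## bonds unchanged (C=N(+)H2 -> C(+):NH2)
      mol@atoms <- a
      hit <- TRUE
      break
    }
    if (!hit) break
  }
  perceiveHybridization(mol)
}

neighborsOf <- function(mol, i) {
  b <- mol@bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

## kekulize aromatic bonds that are not part of an all-aromatic six-ring
## and not part of an amidinium fragment: perfect matching over the atoms
## that need one double bond; lone-pair donors (pyrrole N, furan O,
## thiophene S, anionic centers) need none
kekulizeResidualAromatic <- function(mol, rings) {
  b <- mol@bonds
  aromb <- which(b$order == "aromatic")
  if (!length(aromb)) return(mol)
  protected <- logical(nrow(b))
  for (ring in rings) {
    if (length(ring) != 6) next
    kb <- ringBondIndices(mol, ring)
    if (all(b$order[kb] == "aromatic")) protected[kb] <- TRUE
  }
  ## amidinium fragments: aromatic bonds touching a positively charged C
  a <- mol@atoms
  for (k in aromb) {
    ij <- c(b$a1[k], b$a2[k])
    if (any(a$element[ij] == "C" & a$charge[ij] == 1) &&
        any(a$element[ij] == "N"))
      protected[k] <- TRUE
  }
  free <- setdiff(aromb, which(protected))
  if (!length(free)) return(mol)
  verts <- unique(c(b$a1[free], b$a2[free]))
  needs <- vapply(verts, function(i) atomNeedsRingDouble(mol, i, protected),
                  logical(1))
  needy <- verts[needs]
  ## backtracking perfect matching on the needy vertices over free bonds
  edges <- lapply(free, function(k) c(b$a1[k], b$a2[k]))
  match_bonds <- kekuleMatch(needy, free, edges)
  if (is.null(match_bonds))
    stop("KekulizationError: cannot kekulize aromatic system (atoms ",
         paste(needy, collapse = ","), ")")
  b$order[free] <- "single"
  b$order[match_bonds] <- "double"
  mol@bonds <- b
  perceiveHybridization(mol)
}

atomNeedsRingDouble <- function(mol, i, protected) {
  a <- mol@atoms
  el <- a$element[i]; chg <- a$charge[i]
  kb <- bondsOf(mol, i)
  ## already pi-satisfied through an exocyclic double/triple bond or a
  ## protected aromatic bond
  if (any(mol@bonds$order[kb] %in% c("double", "triple"))) return(FALSE)
  if (any(protected[kb] & mol@bonds$order[kb] == "aromatic")) return(FALSE)
  conn <- length(kb)
  if (el == "C") return(chg == 0)          # C(+)/C(-) act as donors/acceptors
  if (el == "N") {
    if (chg < 0) return(FALSE)             # anionic N: lone-pair donor
    if (chg > 0) return(conn == 3)         # pyridinium-type N(+)
    return(conn == 2)                      # pyridine-type in a 5-ring
  }
  FALSE                                    # O, S, P donors
}

kekuleMatch <- function(needy, free_bonds, edges) {
  if (!length(needy)) return(integer())
  rec <- function(remaining, used_bonds) {
    if (!length(remaining)) return(used_bonds)
    v <- remaining[1]
    for (k in seq_along(free_bonds)) {
      e <- edges[[k]]
      if (!(v %in% e)) next
      w <- setdiff(e, v)
      if (!(w %in% remaining)) next
      res <- rec(setdiff(remaining, c(v, w)), c(used_bonds, free_bonds[k]))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  rec(needy, integer())
}

## move the acidic proton of a carboxylic acid onto an aliphatic primary
## amine or a guanidine imine nitrogen of the same component
autoZwitterionize <- function(mol) {
  a <- mol@atoms
  comp <- connectedComponents(mol)
  adj <- adjacencyList(mol)
  acidH <- NA_integer_; acidO <- NA_integer_
  for (o in which(a$element == "O" & a$charge == 0)) {
    nb <- adj[[o]]
    hs <- nb[a$element[nb] == "H"]
    heav <- nb[a$element[nb] != "H"]
    if (length(hs) != 1 || length(heav) != 1) next
    c1 <- heav
    if (a$element[c1] != "C") next
    kb <- bondsOf(mol, c1)
    dbl <- mol@bonds$order[kb] == "double"
    dblO <- FALSE
    for (k in kb[dbl]) {
      other <- setdiff(c(mol@bonds$a1[k], mol@bonds$a2[k]), c1)
      if (a$element[other] == "O") dblO <- TRUE
    }
    if (dblO) { acidH <- hs; acidO <- o; break }
  }
  if (is.na(acidH)) return(mol)
  baseN <- NA_integer_
  for (nn in which(a$element == "N" & a$charge == 0)) {
    if (comp[nn] != comp[acidO]) next
    nb <- adj[[nn]]
    heav <- nb[a$element[nb] != "H"]
    ## aliphatic primary amine: one heavy neighbor, sp3 non-aromatic C
    if (length(heav) == 1 && a$element[heav] == "C" &&
        !a$aromatic[heav] && a$hyb[heav] == "sp3" &&
        sum(a$element[nb] == "H") == 2) { baseN <- nn; break }
    ## guanidine imine N: =C with two further N neighbors
    kb <- bondsOf(mol, nn)
    for (k in kb[mol@bonds$order[kb] == "double"]) {
      cc <- setdiff(c(mol@bonds$a1[k], mol@bonds$a2[k]), nn)
      if (a$element[cc] == "C") {
        cnb <- adj[[cc]]
        if (sum(a$element[cnb] == "N") >= 3) { baseN <- nn; break }
      }
    }
    if (!is.na(baseN)) break
  }
  if (is.na(baseN)) return(mol)
  ## move the proton: rebond H from O to N, adjust formal charges
  kb <- bondBetween(mol, acidO, acidH)
  mol@bonds$a1[kb] <- baseN
  mol@bonds$a2[kb] <- acidH
  a$charge[acidO] <- -1L
  a$charge[baseN] <- 1L
  mol@atoms <- a
  perceiveHybridization(mol)
}
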