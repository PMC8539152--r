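## Shared graph helpers: adjacency, valence, hybridization, ring perception.

BOND_ORDER_NUM <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

## default valences used to materialize implicit hydrogens; charged variants
## are looked up as "<element><sign>" (N+ = 4 etc.). S and P may expand to
## the next allowed valence when drawn hypervalent.
DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = 3, O = 2, P = c(3, 5), S = c(2, 4, 6), Si = 4,
  F = 1, Cl = 1, Br = 1, I = 1, H = 1,
  `N+` = 4, `N-` = 2, `O+` = 3, `O-` = 1, `C+` = 3, `C-` = 3,
  `S+` = 3, `S-` = 1, `B-` = 4, `P+` = 4
)

adjacencyList <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- vector("list", n)
  b <- mol@bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], b$a2[k])
      adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], b$a1[k])
    }
  }
  adj
}

bondsOf <- function(mol, i) {
  b <- mol@bonds
  which(b$a1 == i | b$a2 == i)
}

bondBetween <- function(mol, i, j) {
  b <- mol@bonds
  which((b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i))
}

bondOrderSum <- function(mol, i) {
  kb <- bondsOf(mol, i)
  if (!length(kb)) return(0)
  sum(BOND_ORDER_NUM[mol@bonds$order[kb]])
}

degreeOf <- function(mol, i) length(bondsOf(mol, i))

#' Assign hybridization and aromatic flags from the bond table
#'
#' Any aromatic bond makes the atom aromatic; a triple bond or two double
#' bonds make it sp; one double bond sp2; otherwise sp3 (hydrogens and other
#' monovalent atoms are marked \code{"none"}).
#'
#' @param mol a MolecularGraph
#' @return the molecule with updated \code{hyb} and \code{aromatic} columns
#' @export
perceiveHybridization <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  hyb <- rep("sp3", n)
  arom <- rep(FALSE, n)
  ndouble <- integer(n); ntriple <- integer(n); naromb <- integer(n)
  b <- mol@bonds
  if (nrow(b)) {
    for (k in seq_len(nrow(b))) {
      ij <- c(b$a1[k], b$a2[k])
      switch(b$order[k],
             double   = ndouble[ij] <- ndouble[ij] + 1L,
             triple   = ntriple[ij] <- ntriple[ij] + 1L,
             aromatic = naromb[ij]  <- naromb[ij] + 1L)
    }
  }
  for (i in seq_len(n)) {
    if (naromb[i] > 0) { hyb[i] <- "aromatic"; arom[i] <- TRUE }
    else if (ntriple[i] > 0 || ndouble[i] >= 2) hyb[i] <- "sp"
    else if (ndouble[i] == 1) hyb[i] <- "sp2"
    else hyb[i] <- "sp3"
    if (a$element[i] == "H") hyb[i] <- "none"
  }
  a$hyb <- hyb
  a$aromatic <- arom
  mol@atoms <- a
  mol
}

## smallest ring through each bond (breadth-first search on the graph with
## the bond removed); the deduplicated collection approximates the smallest
## set of smallest rings and is the basis for aromaticity and ring strain
smallestRings <- function(mol, max_size = 8) {
  b <- mol@bonds
  if (!nrow(b)) return(list())
  adj <- adjacencyList(mol)
  rings <- list()
  seen <- character()
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    ## BFS from i to j avoiding the direct bond
    prev <- rep(NA_integer_, length(adj))
    dist <- rep(NA_integer_, length(adj))
    dist[i] <- 0L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(dist[j])) break
      for (w in adj[[v]]) {
        if (v == i && w == j) next
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          prev[w] <- v
          queue <- c(queue, w)
        }
      }
    }
    if (is.na(dist[j]) || dist[j] + 1L > max_size) next
    path <- j
    while (path[1] != i) path <- c(prev[path[1]], path)
    key <- paste(sort(path), collapse = "-")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1]] <- path }
  }
  rings
}

interatomicDistance <- function(mol, i, j) {
  a <- mol@atoms
  sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
}

bondAngle <- function(mol, left, center, right) {
  a <- mol@atoms
  v1 <- c(a$x[left] - a$x[center], a$y[left] - a$y[center], a$z[left] - a$z[center])
  v2 <- c(a$x[right] - a$x[center], a$y[right] - a$y[center], a$z[right] - a$z[center])
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

valenceTargets <- function(element, charge) {
  key <- if (charge > 0) paste0(element, "+") else if (charge < 0) paste0(element, "-") else element
  v <- DEFAULT_VALENCE[[key]]
  if (is.null(v)) v <- DEFAULT_VALENCE[[element]]
  if (is.null(v)) stop("no default valence for element ", element)
  v
}

## append explicit hydrogens so that each heavy atom reaches its default
## valence (the smallest allowed valence >= current bond-order sum)
addImplicitHydrogens <- function(atoms, bonds, explicitH = NULL) {
  n0 <- nrow(atoms)
  for (i in seq_len(n0)) {
    el <- atoms$element[i]
    if (el == "H") next
    kb <- which(bonds$a1 == i | bonds$a2 == i)
    bsum <- if (length(kb)) sum(BOND_ORDER_NUM[bonds$order[kb]]) else 0
    nh <- if (!is.null(explicitH) && !is.na(explicitH[i])) {
      explicitH[i]
    } else {
      targets <- valenceTargets(el, atoms$charge[i])
      tgt <- targets[targets >= ceiling(bsum)][1]
      if (is.na(tgt)) 0 else floor(tgt - bsum)
    }
    if (is.na(nh) || nh <= 0) next
    for (h in seq_len(nh)) {
      atoms <- rbind(atoms, data.frame(element = "H", charge = 0L,
                                       x = NA_real_, y = NA_real_, z = NA_real_,
                                       stringsAsFactors = FALSE))
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms),
                                       order = "single", stringsAsFactors = FALSE))
    }
  }
  list(atoms = atoms, bonds = bonds)
}

connectedComponents <- function(mol) {
  n <- nrow(mol@atoms)
  adj <- adjacencyList(mol)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (is.na(comp[w])) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}
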