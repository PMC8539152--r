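## SMILES reader (Daylight subset: organic subset + bracket atoms, ring
## closures, branches, charges, explicit H counts, aromatic lower-case,
## dot-separated components; no stereochemistry, no isotopes-as-semantics).

SMILES_ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
SMILES_AROMATIC <- c(b = "B", c = "C", n = "N", o = "O", p = "P", s = "S")

#' Parse a SMILES string into a MolecularGraph
#'
#' Supports the organic subset plus bracket atoms with charges and explicit
#' hydrogen counts, branches, ring-closure digits (including \code{\%nn}),
#' bond symbols \code{- = # :}, aromatic lower-case atoms and dot-separated
#' multi-component inputs (salts, ionic liquids). Hydrogens are made
#' explicit from standard valences (C4, N3 / N4+, O2, S2/4/6 as drawn,
#' P3/5, Si4, B3, halogen 1). Aromatic input bonds are kept as aromatic
#' bond order; \code{\link{normalizeConventions}} settles the final
#' aromatic/kekule representation.
#'
#' @param smiles character(1) SMILES.
#' @param name molecule name carried through downstream results.
#' @return a \linkS4class{MolecularGraph} with \code{has3d = FALSE}.
#' @examples
#' parseSmiles("OO", "hydrogen peroxide")
#' parseSmiles("CC(=O)C", "acetone")
#' @export
parseSmiles <- function(smiles, name = "") {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles))
    stop("ParseError: SMILES must be a non-empty string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- data.frame(element = character(), charge = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      stringsAsFactors = FALSE)
  explicitH <- integer()   # NA = derive from valence
  aromAtom <- logical()
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = character(),
                      stringsAsFactors = FALSE)
  stack <- integer()
  prev <- NA_integer_
  pending_bond <- NA_character_
  ringmap <- list()        # label -> c(atom, bond)
  i <- 1
  addAtom <- function(el, charge, hcount, arom) {
    atoms <<- rbind(atoms, data.frame(element = el, charge = as.integer(charge),
                                      x = NA_real_, y = NA_real_, z = NA_real_,
                                      stringsAsFactors = FALSE))
    explicitH <<- c(explicitH, hcount)
    aromAtom <<- c(aromAtom, arom)
    idx <- nrow(atoms)
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) ord <- if (arom && aromAtom[prev]) "aromatic" else "single"
      if (ord != "none")
        bonds <<- rbind(bonds, data.frame(a1 = prev, a2 = idx, order = ord,
                                          stringsAsFactors = FALSE))
    }
    pending_bond <<- NA_character_
    prev <<- idx
    idx
  }
  closeRing <- function(label) {
    ord <- pending_bond
    pending_bond <<- NA_character_
    if (is.null(ringmap[[label]])) {
      ringmap[[label]] <<- list(atom = prev, order = ord)
    } else {
      opener <- ringmap[[label]]
      ringmap[[label]] <<- NULL
      use <- if (!is.na(ord)) ord else if (!is.na(opener$order)) opener$order
             else if (aromAtom[opener$atom] && aromAtom[prev]) "aromatic" else "single"
      bonds <<- rbind(bonds, data.frame(a1 = opener$atom, a2 = prev, order = use,
                                        stringsAsFactors = FALSE))
    }
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1
      if (j > n) stop("ParseError: unclosed bracket atom")
      body <- paste(chars[(i + 1):(j - 1)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\++|-+)?$", body))[[1]]
      if (!length(m)) stop("ParseError: bad bracket atom [", body, "]")
      sym <- m[3]
      arom <- sym %in% names(SMILES_AROMATIC)
      el <- if (arom) SMILES_AROMATIC[[sym]] else sym
      if (!el %in% SUPPORTED_ELEMENTS)
        stop("UnsupportedElement: ", el)
      hc <- if (m[5] == "") 0L
            else if (m[5] == "H") 1L
            else as.integer(sub("H", "", m[5]))
      chg <- 0L
      if (m[6] != "") {
        cs <- m[6]
        chg <- if (cs %in% c("+", "-")) ifelse(cs == "+", 1L, -1L)
               else if (grepl("^\\++$", cs)) nchar(cs)
               else if (grepl("^-+$", cs)) -nchar(cs)
               else as.integer(paste0(substr(cs, 1, 1), sub("^[+-]", "", cs)))
      }
      addAtom(el, chg, hc, arom)
      i <- j + 1
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                             ":" = "aromatic", "/" = "single", "\\" = "single")
      i <- i + 1
    } else if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1
    } else if (ch == ")") {
      if (!length(stack)) stop("ParseError: unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_character_; i <- i + 1
    } else if (grepl("[0-9]", ch)) {
      closeRing(ch); i <- i + 1
    } else if (ch == "%") {
      if (i + 2 > n) stop("ParseError: bad %nn ring label")
      closeRing(paste0(chars[i + 1], chars[i + 2])); i <- i + 3
    } else {
      ## organic-subset atom, possibly two-letter (Cl, Br, Si not allowed bare)
      two <- if (i < n) paste0(ch, chars[i + 1]) else ""
      if (two %in% c("Cl", "Br")) {
        addAtom(two, 0L, NA_integer_, FALSE); i <- i + 2
      } else if (ch %in% SMILES_ORGANIC) {
        addAtom(ch, 0L, NA_integer_, FALSE); i <- i + 1
      } else if (ch %in% names(SMILES_AROMATIC)) {
        addAtom(SMILES_AROMATIC[[ch]], 0L, NA_integer_, TRUE); i <- i + 1
      } else if (ch %in% c("A", "D", "E", "G", "J", "L", "M", "Q", "R", "T",
                           "U", "V", "W", "X", "Z", "K")) {
        stop("UnsupportedElement: ", ch)
      } else {
        stop("ParseError: unexpected character '", ch, "' at position ", i)
      }
    }
  }
  if (length(ringmap)) stop("ParseError: unclosed ring bond(s)")
  if (length(stack)) stop("ParseError: unmatched '('")
  ## implicit hydrogens: aromatic organic-subset atoms get the standard
  ## aromatic count (aromatic C: 3 - heavy degree; aromatic N/O/S/P: 0)
  expl <- explicitH
  for (k in seq_len(nrow(atoms))) {
    if (is.na(expl[k]) && aromAtom[k]) {
      deg <- sum(bonds$a1 == k | bonds$a2 == k)
      expl[k] <- if (atoms$element[k] == "C") max(0L, 3L - deg) else 0L
    }
  }
  res <- addImplicitHydrogens(atoms, bonds, expl)
  newMolecularGraph(res$atoms, res$bonds, name = name, has3d = FALSE)
}

#' Write a molecule as a SMILES string
#'
#' A plain, non-canonical writer used for round-trip checks and annotated
#' output: hydrogens are folded back into implicit counts, charged atoms
#' and silicon are written as bracket atoms, aromatic bonds as lower-case
#' atoms. Components are dot-separated.
#'
#' @param mol a MolecularGraph
#' @return character(1) SMILES
#' @export
writeSmiles <- function(mol) {
  a <- mol@atoms
  heavy <- which(a$element != "H")
  if (!length(heavy)) return("[H][H]")
  adj <- adjacencyList(mol)
  nH <- vapply(seq_len(nrow(a)), function(i)
    sum(a$element[adj[[i]]] == "H"), integer(1))
  bsym <- c(single = "", double = "=", triple = "#", aromatic = ":")
  atomToken <- function(i) {
    el <- a$element[i]
    sym <- if (a$aromatic[i] && el %in% SMILES_AROMATIC) tolower(el) else el
    if (a$charge[i] != 0 || el == "Si") {
      chg <- if (a$charge[i] > 0) "+" else if (a$charge[i] < 0) "-" else ""
      h <- if (nH[i] > 0) paste0("H", if (nH[i] > 1) nH[i] else "") else ""
      paste0("[", sym, h, chg, "]")
    } else sym
  }
  comp <- connectedComponents(mol)
  parts <- character()
  for (cc in unique(comp[heavy])) {
    root <- heavy[comp[heavy] == cc][1]
    ## spanning tree (DFS) + back edges, then recursive emission
    vis <- rep(FALSE, nrow(a))
    parent <- rep(NA_integer_, nrow(a))
    stack2 <- root; vis[root] <- TRUE
    back <- list()
    while (length(stack2)) {
      v <- stack2[length(stack2)]; stack2 <- stack2[-length(stack2)]
      for (w in adj[[v]]) {
        if (a$element[w] == "H") next
        if (!vis[w]) {
          vis[w] <- TRUE; parent[w] <- v; stack2 <- c(stack2, w)
        } else if (!identical(parent[v], w)) {
          key <- paste(sort(c(v, w)), collapse = "-")
          back[[key]] <- c(v, w)
        }
      }
    }
    labels <- list()
    if (length(back))
      for (k in seq_along(back)) labels[[names(back)[k]]] <- k
    rec <- function(v) {
      s <- atomToken(v)
      for (key in names(back)) {
        e <- back[[key]]
        if (v %in% e) {
          kb <- bondBetween(mol, e[1], e[2])
          lab <- labels[[key]]
          s <- paste0(s, bsym[mol@bonds$order[kb]],
                      if (lab > 9) paste0("%", lab) else lab)
        }
      }
      kids <- adj[[v]][a$element[adj[[v]]] != "H"]
      kids <- kids[!is.na(parent[kids]) & parent[kids] == v]
      ss <- vapply(kids, function(w) {
        kb <- bondBetween(mol, v, w)
        paste0(bsym[mol@bonds$order[kb]], rec(w))
      }, character(1))
      if (length(ss) > 1)
        s <- paste0(s, paste0("(", ss[-length(ss)], ")", collapse = ""),
                    ss[length(ss)])
      else if (length(ss) == 1) s <- paste0(s, ss)
      s
    }
    parts <- c(parts, rec(root))
  }
  paste(parts, collapse = ".")
}
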