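## MDL MOL / SDF (V2000) reader and writer. Fixed-width connection tables,
## "M  CHG" property lines, multi-record SDF with data fields.

V2000_BOND_ORDER <- c("1" = "single", "2" = "double", "3" = "triple",
                      "4" = "aromatic")

parseMolBlockLines <- function(lines, name = NULL) {
  if (length(lines) < 4) stop("ParseError: MOL block too short")
  counts <- lines[4]
  if (grepl("V3000", counts)) stop("ParseError: V3000 connection tables are not supported")
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds))
    stop("ParseError: malformed counts line: ", counts)
  if (length(lines) < 4 + natoms + nbonds)
    stop("ParseError: truncated connection table")
  dim3d <- grepl("3D", substr(lines[2], 21, 22))
  at <- lines[5:(4 + natoms)]
  x <- as.numeric(substr(at, 1, 10))
  y <- as.numeric(substr(at, 11, 20))
  z <- as.numeric(substr(at, 21, 30))
  el <- trimws(substr(at, 32, 34))
  bad <- setdiff(el, SUPPORTED_ELEMENTS)
  if (length(bad)) stop("UnsupportedElement: ", paste(bad, collapse = ", "))
  ## old-style charge column (4 = +1, ... 0 = none, 5 = -1 variants)
  oldchg <- suppressWarnings(as.integer(substr(at, 37, 39)))
  charge <- integer(natoms)
  charge[!is.na(oldchg) & oldchg == 3] <- 1L
  charge[!is.na(oldchg) & oldchg == 5] <- -1L
  atoms <- data.frame(element = el, charge = charge, x = x, y = y, z = z,
                      stringsAsFactors = FALSE)
  bonds <- if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    ord <- trimws(substr(bl, 7, 9))
    if (!all(ord %in% names(V2000_BOND_ORDER)))
      stop("ParseError: unsupported bond order in MOL block")
    data.frame(a1 = as.integer(substr(bl, 1, 3)),
               a2 = as.integer(substr(bl, 4, 6)),
               order = unname(V2000_BOND_ORDER[ord]),
               stringsAsFactors = FALSE)
  } else data.frame(a1 = integer(), a2 = integer(), order = character(),
                    stringsAsFactors = FALSE)
  ## property block: M CHG overrides all charges
  prop <- lines[-seq_len(4 + natoms + nbonds)]
  chgl <- grep("^M  CHG", prop, value = TRUE)
  if (length(chgl)) {
    atoms$charge <- 0L
    for (l in chgl) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", l)), "\\s+")[[1]])
      npairs <- f[1]
      for (p in seq_len(npairs))
        atoms$charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  has3d <- dim3d || any(abs(z) > 1e-8)
  if (!has3d) atoms$x <- atoms$y <- atoms$z <- NA_real_
  res <- addImplicitHydrogens(atoms, bonds)
  if (has3d && nrow(res$atoms) > natoms) {
    ## implicit hydrogens added to a 3D record have no coordinates; place
    ## them on their parent so the coordinate invariant holds (flagged
    ## positions are never used for special-group geometry by themselves)
    extra <- seq(natoms + 1, nrow(res$atoms))
    for (i in extra) {
      parent <- res$bonds$a1[res$bonds$a2 == i]
      res$atoms$x[i] <- res$atoms$x[parent]
      res$atoms$y[i] <- res$atoms$y[parent]
      res$atoms$z[i] <- res$atoms$z[parent]
    }
  }
  nm <- if (!is.null(name)) name else trimws(lines[1])
  newMolecularGraph(res$atoms, res$bonds, name = nm, has3d = has3d)
}

#' Parse an MDL MOL (V2000) block
#'
#' @param text character: either a single string with embedded newlines or a
#'   vector of lines; exactly one connection table.
#' @param name optional molecule name overriding the header line.
#' @return a \linkS4class{MolecularGraph}; \code{has3d} is TRUE when the
#'   dimensionality flag says 3D or any z coordinate is non-zero.
#' @export
parseMolfile <- function(text, name = NULL) {
  lines <- if (length(text) == 1 && grepl("\n", text))
    strsplit(text, "\n", fixed = TRUE)[[1]] else text
  parseMolBlockLines(lines, name = name)
}

#' Read a (possibly multi-record) SDF file or string
#'
#' @param con file path or character with embedded newlines.
#' @return list of \linkS4class{MolecularGraph} in file order.
#' @export
readSdf <- function(con) {
  lines <- if (length(con) == 1 && file.exists(con)) readLines(con, warn = FALSE)
           else if (length(con) == 1 && grepl("\n", con)) strsplit(con, "\n", fixed = TRUE)[[1]]
           else con
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  out <- list()
  for (r in recs) {
    r <- r[r != "$$$$"]
    ## drop data fields ("> <tag>" blocks) after M  END
    mend <- grep("^M  END", r)
    if (length(mend)) r <- r[seq_len(mend[1])]
    if (!any(nzchar(trimws(r)))) next
    out[[length(out) + 1]] <- parseMolBlockLines(r)
  }
  out
}

molToMolBlock <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  x <- ifelse(is.na(a$x), 0, a$x); y <- ifelse(is.na(a$y), 0, a$y)
  z <- ifelse(is.na(a$z), 0, a$z)
  hdr <- c(mol@name, "  hcgroups", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                   nrow(a), nrow(b)))
  atl <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                 x, y, z, a$element)
  num <- c(single = 1, double = 2, triple = 3, aromatic = 4)
  btl <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2,
                              num[b$order]) else character()
  chg <- which(a$charge != 0)
  chgl <- if (length(chg)) {
    vapply(split(chg, ceiling(seq_along(chg) / 8)), function(idx)
      paste0("M  CHG", sprintf("%3d", length(idx)),
             paste0(sprintf("%4d%4d", idx, a$charge[idx]), collapse = "")),
      character(1))
  } else character()
  c(hdr, atl, btl, chgl, "M  END")
}

#' Write molecules to an SDF file with optional data fields
#'
#' @param mols a MolecularGraph or list of them.
#' @param file output path (or "" for a character return).
#' @param fields optional list (one element per molecule) of named
#'   vectors written as SDF data fields, e.g. computed properties.
#' @return invisibly, the lines written.
#' @export
writeSdf <- function(mols, file = "", fields = NULL) {
  if (is(mols, "MolecularGraph")) mols <- list(mols)
  out <- character()
  for (i in seq_along(mols)) {
    out <- c(out, molToMolBlock(mols[[i]]))
    fl <- if (!is.null(fields) && length(fields) >= i) fields[[i]] else NULL
    if (length(fl))
      for (nm in names(fl))
        out <- c(out, paste0(">  <", nm, ">"), as.character(fl[[nm]]), "")
    out <- c(out, "$$$$")
  }
  if (nzchar(file)) writeLines(out, file)
  invisible(out)
}
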