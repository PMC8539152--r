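## shared test helpers: the packaged table, a rounded pipeline shortcut,
## an atom-permutation utility and a parameterized H-H contact fixture

ctab <- loadContributionTable()

hcRounded <- function(x, ...) round(hcValue(predictMolecule(x, ctab, ...)), 1)

## apply a random atom permutation to a molecule (same graph, new indices)
permuteAtoms <- function(mol, perm = sample(atomCount(mol))) {
  a <- atoms(mol)[perm, ]          # new atom k is old atom perm[k]
  b <- bonds(mol)
  newpos <- integer(length(perm)); newpos[perm] <- seq_along(perm)
  b$a1 <- newpos[b$a1]
  b$a2 <- newpos[b$a2]
  hcgroups:::newMolecularGraph(a, b, name = molName(mol), has3d = mol@has3d)
}

## propane-like scaffold with one hydrogen on each terminal carbon placed
## at an exact mutual distance d; all other hydrogens far away
hhContactFixture <- function(d) {
  atoms <- data.frame(element = c("C", "C", "C", "H", "H"),
                      charge = 0L,
                      x = c(0, 1.5, 3.0, 0, d),
                      y = c(0, 0, 0, 1.09, 1.09),
                      z = 0, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = c(1, 2, 1, 3), a2 = c(2, 3, 4, 5),
                      order = "single", stringsAsFactors = FALSE)
  res <- hcgroups:::addImplicitHydrogens(atoms, bonds)
  a <- res$atoms
  extra <- which(is.na(a$x))
  for (k in seq_along(extra)) {
    parent <- res$bonds$a1[res$bonds$a2 == extra[k]]
    a$x[extra[k]] <- a$x[parent]
    a$y[extra[k]] <- a$y[parent] - 0.6
    a$z[extra[k]] <- c(2, -2, 3, -3, 4, -4, 5)[k] * 2
  }
  res$atoms <- a
  hcgroups:::newMolecularGraph(res$atoms, res$bonds,
                               name = sprintf("hh_%.2f", d), has3d = TRUE)
}

groupMultiset <- function(decomp) {
  g <- groupCounts(decomp)
  g[order(names(g))]
}
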