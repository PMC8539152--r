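# hcgroups

Atom-group additivity for the standard heats of combustion and formation
of organic molecules, in R.

## The problem

The standard heat of combustion ΔH°c (and, through Hess's law, the heat of
formation ΔH°f) of an organic compound can be estimated to within a few
kJ/mol by breaking the molecule into *atom groups* — each "backbone" atom
(an atom bound to at least two other atoms, hydrogens counted) characterized
by its element, formal charge and hybridization together with an encoded
description of its immediate neighbors — and summing fitted per-group
increments:

    ΔH°c = Σ_i a_i · A_i  +  Σ_j b_j · B_j

where `A_i` counts the occurrences of atom group *i*, `B_j` counts the
*special groups* (intramolecular hydrogen bridges, close H–H contacts and
small-ring bond-angle strain classes Angle60/Angle90/Angle102), and `a_i`,
`b_j` are contributions in kJ/mol fitted by least squares over thousands of
compounds with measured combustion enthalpies. The method is general: it
covers neutral organics, salts and ionic liquids over H, B, C, N, O, P, S,
Si and the halogens.

`hcgroups` implements the whole method:

* **Structure input** — a SMILES reader (Daylight subset) and an MDL
  MOL/SDF V2000 reader/writer, with explicit-hydrogen materialization.
* **Convention normalization** — six-membered aromatic rings are stored
  with six aromatic bonds; five-ring heteroaromatics are kekulized; in
  amidinium/guanidinium/imidazolium fragments the positive charge is moved
  onto the carbon between the nitrogens; amino acids can be
  auto-zwitterionized.
* **Group perception** — canonical atom-type and neighbor-descriptor
  rendering (`classifyAtom()`, `encodeNeighbors()`, `decompose()`),
  matching the packaged table's spelling character for character, plus the
  geometric special-group detectors.
* **A packaged contribution table** — 390 groups with contributions,
  occurrence and molecule counts, checksummed, with the validity rule
  (a group must be supported by at least three independent molecules).
* **Prediction** — `predictHc()` / `predictMolecule()` evaluate the sum
  (strict mode refuses molecules containing unknown or invalid groups),
  `predictHf()` converts to heats of formation with documented element
  combustion constants.
* **Refitting machinery** — design-matrix construction, a Gauss–Seidel
  solver for the normal equations, 10-fold cross-validation and the
  3×S outlier-rejection loop (`fitContributions()`), plus seeded synthetic
  data generators so every stage is testable.

## Worked example

Diketene (4-methylene-2-oxetanone) decomposes into five atom groups plus
the four-membered-ring strain group with multiplicity 4:

```r
library(hcgroups)
tab <- loadContributionTable()
p <- predictMolecule("C1(=C)OC(=O)C1", tab, hf = TRUE)
p
#> HcPrediction 'C1(=C)OC(=O)C1': dHc = -1903.19 kJ/mol, dHf = -242.51 kJ/mol
predictionTerms(p)
#>         key count contribution product
#>  C sp2|C=CO     1      -470.12 -470.12
#>  C sp2|H2=C     1      -703.30 -703.30
#>   O|C2(2pi)     1       278.25  278.25
#>  C sp2|CO=O     1      -256.51 -256.51
#>  C sp3|H2C2     1      -653.47 -653.47
#>    Angle90|     4       -24.51  -98.04
```

The predicted ΔH°c of −1903.2 kJ/mol compares with the experimental
−1913.4 kJ/mol. Each row is one group: for example `C sp2|CO=O` is the
lactone carbonyl carbon (an sp2 carbon bonded to one carbon, one
single-bonded oxygen and one double-bonded oxygen), and `O|C2(2pi)` is the
ring oxygen with two π-system neighbors. Rounding to 0.1 kJ/mol matches
the reference tables; the same pipeline reproduces, e.g., glycine
(−1038.1 neutral / −980.8 zwitterionic), acetone −1791.0 and its enol
−1798.0, phenol −3055.4, and 1-butyl-3-methylimidazolium chloride −5206.6.

A command-line front end with `predict`, `decompose`, `fit`, `crossval`
and `simulate` subcommands is installed under
`system.file("scripts", "hcgroups-cli", package = "hcgroups")`.

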