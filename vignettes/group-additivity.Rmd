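---
title: "Atom-group additivity for combustion enthalpies: model, conventions and fitting"
author: "hcgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-group additivity for combustion enthalpies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcgroups)
```

## The model

The standard heat of combustion of an organic molecule is modeled as a
sum of additive increments,

$$\Delta H^\circ_c \;=\; \sum_i a_i A_i \;+\; \sum_j b_j B_j,$$

where $A_i$ counts how often *atom group* $i$ occurs in the molecule,
$B_j$ counts the *special groups*, and the $a_i, b_j$ (kJ/mol) are
contributions fitted by least squares against measured combustion
enthalpies. An atom group is one **backbone atom** — an atom bound to at
least two other atoms, hydrogens counted — characterized by its element,
formal charge and hybridization, together with a canonical text encoding
of its immediate neighbors. Terminal atoms (carbonyl oxygens, halogens,
the hydrogens of a methylene group) never form groups of their own; they
appear only inside the neighbor descriptors of their backbone partners.
Special groups capture what the first coordination sphere cannot:
intramolecular hydrogen bridges, close H–H contacts, and the bond-angle
strain of small rings.

The additivity assumption means the model sees no conformational
preferences, no long-range electrostatics and no phase corrections: the
target quantity is the standard-condition value as tabulated in
combustion calorimetry compilations, and a multi-component system (a
salt, an ionic liquid) is simply the sum of its components.

## The group grammar

`classifyAtom()` renders the atom-type token:

* carbon and nitrogen carry a hybridization word — `C sp3`, `C sp2`,
  `C sp`, `C aromatic`, `N sp3`, … — derived purely from the bond table
  (any aromatic bond ⇒ aromatic; a triple bond or two double bonds ⇒ sp;
  one double bond ⇒ sp2; otherwise sp3);
* a central formal charge is attached to the element symbol
  (`N(+) sp3`, `C(+) aromatic`, `B(-)`); anionic nitrogen is spelled
  plainly `N(-)`;
* sulfur and phosphorus carry a valence class instead: `S2` for
  divalent sulfur, `S4` for anything hypervalent, `P3`/`P4` likewise;
* oxygen, silicon and boron carry no hybridization.

`encodeNeighbors()` renders the neighbor descriptor:

* the hydrogen count comes first (`H`, `H2`, `H3`);
* heavy neighbors are grouped by (element, bond marker) with
  multiplicity digits, in the fixed element order
  H, B, C, N, O, S, P, Si, F, Cl, Br, J and marker order
  plain < `=` < `#` < `:` within an element (iodine is spelled `J` in
  descriptors, while the molecule model uses the standard `I`);
* a single `(+)` or `(-)` suffix is appended when any neighbor carries
  that charge — the suffix records *presence*, not multiplicity, so the
  nitrate nitrogen renders `O2=O(-)` and both sulfate and hydrogensulfate
  sulfur render `O2=O2(-)`;
* for central atoms of type neutral `N sp3`, `O` and `S2` — all-single-bond
  centers — the π environment of the neighbors is expressed as a trailing
  `(pi)`, `(2pi)` or `(3pi)` count instead of per-neighbor markers. A
  neighbor is a π member when it is an unsaturated (sp, sp2 or aromatic)
  **carbon or nitrogen**. This is the single riskiest convention in the
  grammar and it is guarded by a fixture suite: the phenol hydroxyl renders
  `HC(pi)`, the lactone ring oxygen `C2(2pi)`, an ester oxygen `C2(pi)`, a
  dialkyl ether `C2` — and the hydrogensulfate O–H renders plain `HS`,
  which is why formally hypervalent sulfur and phosphorus neighbors are
  excluded from the π count.

A group key is the atom-type token joined to the descriptor
(`"C sp2|CO=O"`); lookup against the packaged table is exact string
matching, which is also why the canonical ordering above is frozen.

## Structural conventions

`normalizeConventions()` rewrites every input to the conventions the
contribution table was fitted under:

1. **Six-membered aromatic rings carry six aromatic bonds.** Kekulé input
   (alternating single/double, all ring atoms C or N) is rewritten;
   cross-conjugated rings such as quinones are left alone.
2. **Five-membered heteroaromatics are kekulized.** Thiophene, furan,
   pyrrole and their fused relatives are stored with localized double
   bonds; their ring atoms are typed sp2/sp3 and the heteroatom sees its
   π neighbors through the `(pi)` count (`S2|C2(2pi)`, `O|C2(2pi)`,
   `N sp3|HC2(2pi)`). In a fused system such as indole the benzene ring
   keeps its six aromatic bonds — including the shared bond — and only
   the pure five-ring bonds are kekulized. The kekulization itself is a
   small backtracking perfect matching over the atoms that still need one
   double bond, with lone-pair donors (pyrrole-type N, O, S, anionic
   centers) needing none.
3. **Amidinium, guanidinium and imidazolium fragments put the positive
   charge on the carbon between the nitrogens**, and that carbon's C–N
   bonds become aromatic. An imidazolium ring read from aromatic SMILES
   therefore ends up with exactly two aromatic bonds (N1:C2:N3), a C4=C5
   double bond and single N–C bonds — its N1 renders
   `N aromatic|C2:C(+)` and its C2 `C(+) aromatic|H:N2`. Pyrazolium has
   no carbon between its adjacent nitrogens; such rings are kekulized as
   drawn.
4. **Zwitterion policy.** Under `zwitterion_policy = "auto"` a molecule
   containing both a carboxylic acid and an aliphatic **primary** amine
   or a guanidine has the acidic proton moved from O to N (glycine
   becomes H3N⁺–CH2–COO⁻). The scope is deliberately narrow: anilines
   (the amine conjugated to the ring, hence weakly basic) and secondary
   amines such as sarcosine are never auto-converted, so both prototropic
   forms of those compounds remain individually computable. The default
   is `"as_drawn"` — the honest choice for amphoteric molecules beyond
   those two named cases.

Normalization is idempotent and conserves net charge (a proton moves, it
never appears or disappears); both properties are tested.

## Special groups and geometry policies

The thresholds are packaged in `special_groups.tsv`:

| group | meaning | window |
|---|---|---|
| `H Acceptor` | acidic H (on O, N, S) to a non-bonded O/N/F acceptor | d < 1.75 Å |
| `.H` | non-bonded H–H contact | d < 2.0 Å |
| `..H` | non-bonded H–H contact | 2.0 ≤ d ≤ 2.3 Å |
| `Angle60` | ring-atom bond angle | < 74° |
| `Angle90` | ring-atom bond angle | 74–98° |
| `Angle102` | ring-atom bond angle | 98–106° |

H–H contacts exclude geminal pairs (same heavy atom) and pairs on bonded
heavy atoms; whether 1,3-pairs were excluded in the original fit is not
documented, and excluding them is this package's recorded assumption.
Ring membership uses the smallest ring through each bond (a
smallest-set-of-smallest-rings approximation); a fused-ring atom can
collect at most one angle group per ring it closes.

Two geometry policies exist. `use_3d` is authoritative: it requires
coordinates (consumed, never generated — conformer generation is out of
scope) and evaluates all three detector families. `topology_only` is a
documented approximation: three-ring atoms get `Angle60`, four-ring atoms
`Angle90`, and five-membered rings get **nothing**, because their strain
class depends on the actual pucker — a planar pentagon sits at 108°
(no group) while typical envelope conformations put two to five atoms
into the 98–106° bin. H bridges and H–H contacts are likewise undetectable
without geometry.

## The contribution table and the validity rule

The packaged table has 390 rows — atom groups plus the six special
groups — each with its contribution, its number of occurrences and the
number of distinct supporting molecules in the original fit. It is stored
as plain TSV with a frozen MD5 checksum that `loadContributionTable()`
verifies; a transcription audit in the test suite checks that the six
groups of the worked example sum to the printed total exactly.

A group is **valid** when supported by at least `min_molecules = 3`
independent molecules; strict prediction refuses molecules containing
invalid or unknown groups (lenient mode sums anyway and reports the
blockers). One bookkeeping discrepancy is worth recording: counting the
packaged rows with ≥ 3 supporting molecules gives 274 valid groups
(268 excluding the special groups), whereas the source compilation's own
summary row states 267. No threshold reading reproduces 267 from the
printed rows, so the packaged table is kept verbatim and the package
reports what the rows actually contain.

## Heats of formation

`predictHf()` applies Hess's law, `ΔH°f = Σ_e n_e c_e − ΔH°c`, with
per-atom element combustion enthalpies under a documented product
convention (CO2(g), H2O(l), N2(g), SO2(g), H3PO4 for phosphorus,
SiO2(quartz), B2O3, HX(g) for halogens with water-corrected constants so
the identity holds when one H pairs with each halogen). The constant set
is external to the fitted contributions; the packaged defaults are
assembled from CODATA-consistent formation enthalpies and can be
overridden by a user YAML of the same shape. Consequently the package's
own checks on ΔH°f are derivational (a Hess-cycle hand example and exact
round trips), not comparisons against tabulated formation data.

## Refitting: design matrix, Gauss–Seidel, cross-validation, outliers

`buildDesignSystem()` turns records (group-count vectors plus measured
values) into an M×N occurrence matrix; records with uncovered atoms are
excluded with a message, unused vocabulary columns are dropped with a
warning.

"Normalizing" the rectangular system is read as forming the normal
equations $X^TX\,b = X^Ty$, which `gaussSeidelSolve()` balances by
coordinate-wise sweeps in fixed column order, starting from zero, until
the largest coordinate update falls below `tol` (default 1e-6 kJ/mol,
sweep limit 10 000). A direct `qr.solve` of the same normal equations
serves as the independent oracle in the tests: on well-conditioned
random designs the two agree to better than 1e-6 kJ/mol. Degeneracies
fail loudly — all-zero columns are removed with a warning, perfectly
collinear columns raise a non-identifiability error, and a sweep budget
overrun raises a convergence error carrying the last iterate.

`crossValidate()` shuffles the records into k folds (default 10) by a
recorded seed, as equal as possible, so that every record is tested
exactly once; test records whose groups never occur in the training part
are *not evaluable* and get NA. `fitContributions()` runs the full loop:
solve, cross-validate, compute the cross-validated standard error
S (RMS, n denominator), discard records whose cross-validated residual
exceeds `outlier_k × S` (default 3), and repeat to a fixed point
(`single_pass = TRUE` gives the one-shot variant; the loop is monotone —
the survivor set never grows — and a safety bound caps the rounds).
Rejection is suppressed when S falls below 10×`tol`, so a noise-free
dataset is never decimated over rounding-level residuals.

Two statistics conventions are emitted side by side because the original
convention is not stated: `sigma` uses the n−p denominator for the
resubstitution fit, `sigma_n` the plain RMS; cross-validated errors use
the RMS form. The accuracy statistics (R², σ, mean deviation) are
computed only over compounds whose groups are all valid under the
survivor counts, which is why the evaluated compound count is smaller
than the fitted one — the same shrinkage the reference statistics show.

## Synthetic data: what it emulates and what it does not

`genDesign()` draws sparse non-negative occurrence matrices (Zipf-profiled
Poisson counts, patched so no row or column is empty), plants uniform
contributions in a realistic range (−2000 to −100 kJ/mol), adds Gaussian
noise (default 5 kJ/mol, the order of the reference cross-validated
error), and optionally perturbs a fraction of records into gross
outliers (default scenario: 5% at 10σ). Everything is deterministic
under the spec's seed. These designs bypass chemistry entirely — by
construction, so that solver and cross-validation properties are tested
independently of any perception bug. What passing those tests shows is
that the *fitting machinery* is correct; it says nothing about whether
real combustion data satisfy additivity, and the synthetic noise is
homoscedastic where calorimetric errors are not. The chemical side is
covered separately by `fixtureMolecules()`: structures whose
decompositions and predicted values are pinned against the reference
tables, including both prototropic forms of the amino-acid fixtures and
a constructed 3D pair that switches an H bridge on and off across the
1.75 Å threshold.

Test problem sizes are deliberately desk-scale: random solver designs of
10–60 records over 3–15 groups (100 systems for the oracle comparison),
60-record/8-group designs with 20 replicates for the outlier-recovery
study, and the 28-compound ionic-liquid suite for the end-to-end
deterministic check.

## Known limitations

* **Conformation-dependent special groups need the original geometries.**
  The reference calculated values for several ionic liquids include H–H
  contact and five-ring `Angle102` terms that come from the curated 3D
  conformations behind the original fit (e.g. the tetramethylguanidinium
  value sits 5.2 kJ/mol — four `..H` contacts — below the exact
  topological sum). Those conformations are not distributed, and this
  package does not generate conformers, so its topology-only predictions
  for that suite deviate slightly more from experiment (mean absolute
  percentage deviation ≈ 0.29% over the 28 compounds, vs 0.23% for the
  reference calculated column, which the summary-statistics code does
  reproduce from the printed values).
* Prediction quality is bounded by table coverage: a molecule containing
  any group outside the 390 (or any invalid group, in strict mode) is
  refused rather than extrapolated; methane itself is uncovered (its
  carbon would render the unknown key `C sp3|H4`).
* The global reference statistics (σ = 18.12, S = 19.16 kJ/mol over ~4900
  compounds) require the full training compilation, which is not shipped;
  the fitting machinery is therefore validated by property-based tests
  with planted ground truth instead.
* The SMILES writer is non-canonical (round-trip tests compare multisets,
  not strings), stereochemistry is ignored (no group depends on it), and
  aromaticity perception targets the conventions above rather than any
  general aromaticity model.
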