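Package: hcgroups
Title: Atom-Group Additivity for Standard Heats of Combustion and Formation
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Predicts standard heats of combustion and formation of organic
    molecules by atom-group additivity. Molecules read from SMILES or MDL
    MOL/SDF (V2000) are normalized to fixed structural conventions
    (aromatic-bond six-rings, amidinium charge on carbon, optional
    zwitterionization of amino acids), decomposed into backbone atom groups
    characterized by their immediate neighbor atoms plus geometry-derived
    special groups (intramolecular hydrogen bridges, close H-H contacts,
    small-ring bond-angle strain), and scored against a packaged table of
    390 fitted group contributions. The fitting machinery used to derive
    such contributions is included: design-matrix construction, a
    Gauss-Seidel solver for the normal equations, k-fold cross-validation
    and iterative outlier rejection, together with synthetic-data
    generators that make every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, tools, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
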