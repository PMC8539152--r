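# Standard molar combustion enthalpies of the elements, kJ/mol per atom,
# at 298.15 K / 1 bar, used to convert a heat of combustion into a heat of
# formation by Hess's law:  dHf = sum(n_e * c_e) - dHc.
# Product convention (documented per element, overridable by the user):
#   C  -> CO2(g)                    H -> 1/2 H2O(l)
#   N  -> 1/2 N2(g)                 O -> (no products; reference O2)
#   S  -> SO2(g)                    P -> H3PO4(aq), water-corrected
#   Si -> SiO2(quartz)              B -> 1/2 B2O3(cr)
#   F  -> HF(g),  Cl -> HCl(g),  Br -> HBr(g),  I -> HI(g); the halogen
#   constants are water-corrected so that dHf = sum(n_e c_e) - dHc holds
#   when one H per halogen ends up as HX instead of H2O.
# Values assembled from CODATA-consistent standard enthalpies of formation.
convention: "CO2(g), H2O(l), N2(g), SO2(g), H3PO4(aq), SiO2(quartz), B2O3(cr), HX(g)"
elements:
  "C": -393.51
  "H": -142.915
  "N": 0.0
  "O": 0.0
  "S": -296.81
  "P": -855.65
  "Si": -910.70
  "B": -636.75
  "F": -130.39
  "Cl": 50.61
  "Br": 106.63
  "I": 169.40
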