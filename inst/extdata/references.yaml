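# Default reference values for the scored properties of caffeic acid.
#
# Energetic references: the gas-phase experimental bond dissociation
# enthalpy at the catechol C4 hydroxyl averages 80.0 kcal/mol and the
# experimental proton affinity is 323.3 kcal/mol; the remaining energetic
# entries are the high-level double-hybrid (B2PLYP-D3BJ/aug-cc-pVTZ scale)
# values implied by the quoted offsets from those experiments. Vertical
# ionization potential / electron affinity references come from the same
# high-level calculation (7.16 eV / 0.67 eV).
#
# Geometry references (O-H bond lengths, intramolecular hydrogen-bond
# length) are SYNTHETIC: representative catechol-scale values chosen for the
# packaged generator and scoring demonstrations, not taken from the
# benchmark's own dataset (which is not distributed).
references:
  - property: oh_c3
    value: 0.966
    units: angstrom
    provenance: high_level_theory
    synthetic: true
  - property: oh_c4
    value: 0.966
    units: angstrom
    provenance: high_level_theory
    synthetic: true
  - property: hbond
    value: 2.13
    units: angstrom
    provenance: high_level_theory
    synthetic: true
  - property: bde_c3
    value: 92.6
    units: kcal/mol
    provenance: high_level_theory
  - property: bde_c4
    value: 80.1
    units: kcal/mol
    provenance: high_level_theory
  - property: aip
    value: 184.1
    units: kcal/mol
    provenance: high_level_theory
  - property: aea
    value: -12.8
    units: kcal/mol
    provenance: high_level_theory
  - property: pa_c3
    value: 340.3
    units: kcal/mol
    provenance: high_level_theory
  - property: pa_c4
    value: 320.4
    units: kcal/mol
    provenance: high_level_theory
  - property: vip
    value: 7.16
    units: eV
    provenance: high_level_theory
  - property: vea
    value: 0.67
    units: eV
    provenance: high_level_theory
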