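seed: 42.0
binding:
  titration_csv: demo_titration.csv
  ligand_unit: uM
  protein_total: 1.0
  fix_I0: no
peaks:
  kind: emission
  reference_csv: demo_emission_free.csv
  treated_csv: demo_emission_bound.csv
fret:
  donor_csv: demo_donor_emission.csv
  acceptor_csv: demo_acceptor_absorption.csv
  F: 31.0
  F0: 100.0
  convention: standard_A6
kinetics:
  value_kind: concentration
  epsilon_mM: 27.9
  baseline_csv: demo_release_baseline.csv
  treated:
  - label: '1:22'
    csv: demo_release_1to22.csv
  - label: '1:44'
    csv: demo_release_1to44.csv
  - label: 1:66
    csv: demo_release_1to66.csv
calibration:
  rel_tol: 0.05
  reference_csv: demo_calibration_reference.csv
  others:
  - label: with protein
    csv: demo_calibration_protein.csv
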