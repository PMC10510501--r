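# Property-gate thresholds.  Boundary semantics: ro3 molar mass is a strict
# "<"; every other bound is inclusive.  All values configurable.
ro5:
  max_molar_mass: 500
  max_logp: 5
  max_n_hbd: 5
  max_n_hba: 10
ro3:
  max_molar_mass: 300      # strict <
  max_logp: 3
  max_n_hbd: 3
  max_n_hba: 3
  max_n_rotb: 3
  max_psa: 60
lead_like:
  min_molar_mass: 200
  max_molar_mass: 450
  min_logp: -3.5
  max_logp: 4.5
  max_n_rings: 4
  max_n_rotb: 10
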