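# Physical and critical properties of aripiprazole (form II).
# Melting point from DSC; boiling/critical properties from group-contribution
# estimates; sublimation pressures from a corresponding-states method.
name: aripiprazole
formula: C23H27Cl2N3O2
cas: 129722-12-9
molar_mass: 448.39        # g/mol
melting_T: 415.11         # K
boiling_T: 744.93         # K
critical_T: 981.18        # K
critical_P: 6.07          # bar
acentric_factor: 0.3189
molar_volume: 552.8       # cm^3/mol (solid)
sublimation_P:            # bar, by temperature (K)
  "308.15": 2.28e-06
  "318.15": 6.90e-06
  "328.15": 1.97e-05
  "338.15": 5.33e-05
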