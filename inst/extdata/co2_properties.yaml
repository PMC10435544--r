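# Carbon dioxide solvent properties. The critical mass density is the
# standard literature value; the molar critical density follows from it
# (467.6 / 44.01 * 1000 = 10625 mol/m^3) and enters the expanded-liquid
# (modified Wilson) model.
name: carbon dioxide
formula: CO2
cas: 124-38-9
molar_mass: 44.01             # g/mol
critical_T: 304.18            # K
critical_P: 73.8              # bar
acentric_factor: 0.225
critical_mass_density: 467.6  # kg/m^3
critical_molar_density: 10625 # mol/m^3
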