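# Bilinear cohesive-zone parameters for the lamellar interface of the
# human aortic media, calibrated against peel, direct-tension and shear
# experiments. Units: tractions kPa, fracture energies mN/mm (= N/m),
# stiffnesses mN/mm^3.
mode_I:
  T_C_kPa: 131
  G_C_mN_per_mm: 49
  K_mN_per_mm3: 1638
mode_II:
  T_C_kPa: 97
  G_C_mN_per_mm: 200
  K_mN_per_mm3: 35000
mode_III:
  T_C_kPa: 120
  G_C_mN_per_mm: 240
  K_mN_per_mm3: 35000
alpha: 1
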