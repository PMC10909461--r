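# HGO parameters for the human thoracic aortic wall (biaxial testing).
# Units: kPa for stresses, 1/kPa for D; theta in degrees from the
# circumferential direction.
media:
  C10_kPa: 23.0097
  k1_kPa: 127.0692
  k2: 4.4952
  kappa: 0.3201
  theta_deg: 0.0008
  D_per_kPa: 1.0e-6
adventitia:
  C10_kPa: 8.2649
  k1_kPa: 71.2311
  k2: 1.6901
  kappa: 0.3013
  theta_deg: 0.001
  D_per_kPa: 1.0e-6
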