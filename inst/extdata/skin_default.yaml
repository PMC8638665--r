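# Synthetic 5-layer skin optical preset for 200-400 nm photon transport.
# These are NOT measured tissue data: they are an explicit, documented
# stand-in with epidermis-like UV magnitudes (strong protein/nucleic-acid
# absorption below ~240 nm decaying double-exponentially, a weak
# melanin-like power-law term, power-law scattering, g = 0.9, matched
# internal refractive indices). All coefficients in mm^-1, thicknesses in
# um. Edit and reload with make_skin_preset(path).
name: default
ambient_n: 1.0
wl_range_nm:
- 200.0
- 400.0
markers:
  top_of_epidermis: 20.0
  mid_epidermis: 60.0
  basal_layer: 100.0
layers:
- name: stratum_corneum
  thickness_um: 20.0
  refractive_index: 1.38
  g: 0.9
  mua_const: 0.0
  mua_a1: 300.0
  mua_w1: 15.0
  mua_a2: 25.0
  mua_w2: 80.0
  mua_mel: 0.5
  mus_const: 0.0
  mus_400: 50.0
  mus_b: 1.5
- name: living_epidermis
  thickness_um: 80.0
  refractive_index: 1.38
  g: 0.9
  mua_const: 0.0
  mua_a1: 250.0
  mua_w1: 15.0
  mua_a2: 20.0
  mua_w2: 80.0
  mua_mel: 1.0
  mus_const: 0.0
  mus_400: 40.0
  mus_b: 1.5
- name: papillary_dermis
  thickness_um: 150.0
  refractive_index: 1.38
  g: 0.9
  mua_const: 0.0
  mua_a1: 150.0
  mua_w1: 15.0
  mua_a2: 15.0
  mua_w2: 90.0
  mua_mel: 0.0
  mus_const: 0.0
  mus_400: 30.0
  mus_b: 1.5
- name: reticular_dermis
  thickness_um: 1000.0
  refractive_index: 1.38
  g: 0.9
  mua_const: 0.0
  mua_a1: 120.0
  mua_w1: 15.0
  mua_a2: 10.0
  mua_w2: 100.0
  mua_mel: 0.0
  mus_const: 0.0
  mus_400: 25.0
  mus_b: 1.5
- name: subcutis
  thickness_um: 1750.0
  refractive_index: 1.38
  g: 0.9
  mua_const: 0.0
  mua_a1: 80.0
  mua_w1: 15.0
  mua_a2: 8.0
  mua_w2: 100.0
  mua_mel: 0.0
  mus_const: 0.0
  mus_400: 15.0
  mus_b: 1.5
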