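# Two identical Schnakenberg layers with equal exchange rates; the surface
# inhibitor diffusion d_vS is the bifurcation parameter.
preset: fig2a
eta: 0.5
overrides:
  d_vS: 20
analysis:
  q_max: 300
simulation:
  N_x: 128
  dt: 0.05
  t_final: 1500
  init_noise: 0.01
seed: 1
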