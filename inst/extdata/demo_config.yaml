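# Demo run: four small phantom brains (two living/advective, two
# sacrificed/diffusive) plus two synthetic lymph-node images per group.
seed: 42
threshold: auto
sample_n: all
phantom:
  shape: [10, 48, 48]
  in_plane_um: 10.4
  axial_um: 70
  misalign_sigma_px: 2
  misalign_sigma_deg: 1
  noise_sigma: 0.02
brains:
  - {id: L30_a, group: L30, mode: advective, seed: 11}
  - {id: L30_b, group: L30, mode: advective, seed: 12}
  - {id: S30_a, group: S30, mode: diffusive, seed: 21}
  - {id: S30_b, group: S30, mode: diffusive, seed: 22}
lymphnode:
  images:
    - {id: LN_L90_1, group: L90, node_class: DCLN-left, n_tracer: 5, n_autofluor: 20, seed: 31}
    - {id: LN_L90_2, group: L90, node_class: DCLN-right, n_tracer: 4, n_autofluor: 20, seed: 32}
    - {id: LN_S90_1, group: S90, node_class: DCLN-left, n_tracer: 0, n_autofluor: 20, seed: 33}
    - {id: LN_S90_2, group: S90, node_class: DCLN-right, n_tracer: 0, n_autofluor: 20, seed: 34}
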