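# Bundled example data

- `jeholosaurus_zspacing.csv` — transcription of the published per-side
  Z-spacing values for the six *Jeholosaurus* specimens (tooth positions;
  empty cells omitted).
- `vonebner_increments_synthetic.csv` — SYNTHETIC daily von Ebner
  increment-width series standing in for unavailable raw thin-section
  measurements: lognormal widths rescaled so that each tooth's couplet
  count and mean width equal the published formation times and DDARs
  (rM8 46 d / 11.7178 µm, lPM4 33 d / 13.7688 µm, rPM5 25 d / 12.7401 µm).
- `ornithischia_topology_synthetic.nwk`, `ornithischia_ages_synthetic.csv`,
  `replacement_states_synthetic.csv` — a SYNTHETIC ornithischian stand-in
  dataset (real genus names; illustrative first/last appearance dates in Ma
  and tooth-replacement-pattern state codings) for demonstrating
  time-calibration and ancestral-state reconstruction. Not a reconstruction
  of any published character matrix.
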