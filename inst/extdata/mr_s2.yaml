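# Two designable sites, distance-weighted fixed-point (MR) energies, p = 5.
# B = 0.95 keeps states within 5% of the attainable minimum (M = 2).
model: MR
structure:
  sites: 2
  interactions:
    - [1, 2]
  d_inv:
    1-2: 1.0
table: mr_table.csv
threshold:
  B: 0.95
p: 5
iterations: auto
backend: shortcut
shots: 8192
seed: 11
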