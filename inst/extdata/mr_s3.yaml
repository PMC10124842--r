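# Three designable sites, complete graph, MR energies, p = 5.
# Asymmetric distance reciprocals (sum 1.6 before grid quantization).
model: MR
structure:
  sites: 3
  interactions:
    - [1, 2]
    - [1, 3]
    - [2, 3]
  d_inv:
    1-2: 1.0
    1-3: 0.35
    2-3: 0.25
table: mr_table.csv
threshold:
  B: 0.70
p: 5
iterations: auto
backend: shortcut
shots: 8192
seed: 11
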