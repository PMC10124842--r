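# Three designable sites on a triangle (all three contacts), SP energies.
# The formula threshold e_min*i + 1 = -11 is unattainable on this table
# (no sequence scores -4 on all three pairs); -8 keeps the four
# hydrophobic-core sequences (H1-H1-H1 and the three H1-H1-H2 placements).
model: SP
structure:
  sites: 3
  interactions:
    - [1, 2]
    - [1, 3]
    - [2, 3]
table: sp_table.csv
threshold:
  e_th: -8
iterations: auto
backend: gate
shots: 8192
seed: 11
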