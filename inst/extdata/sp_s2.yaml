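# Two designable sites, one contact, integer (SP) energies.
# E_th = -3 marks only the Pos-Neg / Neg-Pos salt bridge (M = 2).
model: SP
structure:
  sites: 2
  interactions:
    - [1, 2]
table: sp_table.csv
threshold:
  e_th: -3
iterations: auto
backend: gate
shots: 8192
seed: 11
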