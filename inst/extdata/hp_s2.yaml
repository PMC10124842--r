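# Two-site hydrophobic-polar model (the 7-qubit device-scale circuit).
# E_th = 0 marks the single H-H contact.
model: HP
structure:
  sites: 2
  interactions:
    - [1, 2]
table: hp_table.csv
threshold:
  e_th: 0
iterations: auto
backend: gate
shots: 8192
seed: 11
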