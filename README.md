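# qgdesign — Grover search circuits for protein sequence design

`qgdesign` builds and simulates gate-based quantum circuits that solve small
protein sequence design problems with Grover's algorithm, for researchers who
want a fully verifiable, desk-scale model of how amplitude amplification
applies to combinatorial design.

## The problem and the method

A design instance has `s` designable sites, each filled by one of `A` residue
types, so there are `N = A^s` candidate sequences. A sequence `k` is scored by
a pairwise contact energy model over the structure's interacting site pairs:

- **SP** (simplified): integer energies, `E_tot(k) = Σ_{a>b} E_{a,b}(k)`;
- **MR** (more realistic): fixed-point energies weighted by precomputed
  distance reciprocals, `E_tot(k) = Σ_{a>b} E_{a,b}(k) · d⁻¹_{a,b}`, on a
  two's-complement grid with `p` fraction bits (`p = 5` gives 0.03125);
- **HP**: the two-letter hydrophobic/polar variant of SP, small enough for
  a 7-qubit circuit.

The *answer states* are the sequences with `E_tot` strictly below a threshold
`E_th` (SP/HP default `E_min·i + 1`; MR uses a fraction `B·E_min·Σd⁻¹`).
Grover's algorithm finds them in `O(√(N/M))` oracle queries instead of the
classical `O(N)`: each residue is encoded on `g = ⌈log₂ A⌉` qubits, `H^{⊗n}`
(`n = g·s`) prepares the uniform superposition, and each iteration applies

1. the **oracle**: controlled constant loads write the table entries into a
   value register, Cuccaro-style ripple-carry adders (`2m+1` qubits) sum them
   (the MR model first multiplies by `d⁻¹` with a shift-and-add multiplier,
   within a `16m+1`-qubit work budget), the threshold is subtracted, a `Z` on
   the sign bit flips the phase of answers, and everything is uncomputed;
2. the **diffuser**: inversion about the mean on the sequence register.

After `R_max = argmax_R sin²((2R+1)·arcsin√(M/N))` iterations the answer
states carry essentially all the probability. Every circuit is built from
self-inverse gates `{H, X, CX, CCX, MCX, Z, MCZ}`; because the oracle is
classical-reversible it is verified *exhaustively* against the brute-force
energy model with a basis-state evaluator whose cost is independent of the
qubit count — this is how the 100+-qubit fixed-point oracles (up to the
234-qubit three-site MR circuit at `p = 10`) are validated.

## Worked example

```r
library(qgdesign)

prob <- design_problem("SP", structure = protein_structure(2), e_th = -3)
prob
#> <design_problem: SP model, s = 2, A = 8, n = 6 (N = 64 states), E_th = -3>

run_grover(prob, R = "auto", backend = "gate")
#> <grover_result: SP model, N = 64, M = 2, R = 4, E_th = -3, gate backend>
#>   success probability (total over 2 marked states): 0.9992
#>  sequence bitstring energy  probability marked
#>   Pos-Neg    100101     -4 4.995912e-01   TRUE
#>   Neg-Pos    101100     -4 4.995912e-01   TRUE
#>   Pol1-H1    010000      0 1.318846e-05  FALSE
#>   Pol1-H2    010001      0 1.318846e-05  FALSE
#>   Pol2-H1    011000      0 1.318846e-05  FALSE

qubit_budget(prob)
#> <resource_report: SP model, s = 2>
#>   n = 6   N = 64   m = 4   work qubits = 9   total q = 15
#>   A = 8 (g = 3), i = 1, W = 1, p = 0, E in [-4, 1]
```

Of the 64 candidate dipeptides, only the two salt-bridge orderings Pos-Neg and
Neg-Pos score below the threshold (`E = -4 < -3`); after the optimal four
iterations each is measured with probability ~0.4996, while at `R = 1` the two
together reach only ~26%. The full 15-qubit circuit (6 sequence + 9 work
qubits) was simulated gate by gate, and the work register is checked to be
exactly `|0⟩` before it is discarded.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/qgd.R run --config sp_s2.yaml --backend gate
Rscript inst/cli/qgd.R brute-force --config mr_s3.yaml
Rscript inst/cli/qgd.R resources --config mr_s2.yaml
Rscript inst/cli/qgd.R sweep --config sp_s3.yaml --max-iterations 8
```

Packaged configurations: `sp_s2.yaml`, `sp_s3.yaml`, `mr_s2.yaml`,
`mr_s3.yaml`, `hp_s2.yaml`, with their energy tables in CSV next to them.
Custom tables and structures are plain CSV/YAML files.

## Scope

The package targets ideal (noise-free) simulation: device noise models,
transpilation to hardware-native gate sets and coupling maps, and
matrix-product-state backends are out of scope. Depth figures after
multi-controlled-gate decomposition depend on the chosen convention;
`decompose_circuit()` documents one reasonable choice.
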