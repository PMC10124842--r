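---
title: "Grover circuits for pairwise-energy protein design: models, arithmetic and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grover circuits for pairwise-energy protein design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgdesign)
```

## The design problem

Protein sequence design asks which residues, placed at `s` designable sites of
a fixed backbone, minimize the structure's energy. With `A` residue types
there are `A^s` candidate sequences, so exhaustive search is exponential in
`s`. `qgdesign` treats the problem the way lattice-model studies do: residues
are featureless beads, the structure is reduced to its set of interacting site
pairs, and the energy of a sequence is a sum of precomputed pairwise contact
energies. Three model families are supported.

* **SP** — integer contact energies from a symmetric `A x A` table,
  `E_tot(k) = sum over interacting pairs of E[a,b](k)`. The packaged 8-residue
  table (two hydrophobic types, two polar types, one positive, one negative,
  two neutral fillers) has a unique minimum of -4 for the Pos/Neg salt bridge
  and a maximum of +1 for like-charge repulsion.
* **MR** — each pair's energy is weighted by a precomputed distance
  reciprocal, `E_tot(k) = sum of E[a,b](k) * d_inv[a,b]`, on a fixed-point
  grid. Since `E * d_inv` has the form of a scaled Coulomb term, any
  precomputed pairwise potential can be fed in through the table. The MR model
  requires the complete interaction graph: every pair of sites interacts,
  with nearer pairs contributing more.
* **HP** — the two-letter hydrophobic/polar reduction with a single
  favourable H-H contact (-2); its two-site instance fits a 7-qubit circuit.

A sequence is an *answer* when its total energy is **strictly below** a
threshold `E_th`. For SP/HP the default `E_th = E_min * i + 1` is the lowest
integer threshold that still admits the minimum-energy sequences. For MR the
threshold is a fraction of the attainable minimum, `E_th = B * E_min *
sum(d_inv)` with `B` in (0, 1], floored onto the energy grid (flooring is
deliberate: rounding the threshold up could silently admit states sitting on
the grid boundary). Strict comparison is what makes the default SP threshold
select exactly the minimum-energy set: -4 < -3 but -3 is not.

```{r answers}
prob <- design_problem("SP", structure = protein_structure(2), e_th = -3)
enumerate_answer_states(prob)
```

## Grover search over sequences

Each residue is encoded on `g = ceiling(log2(A))` qubits (canonical codes in
table order, so the first residue is the all-zero code), and a sequence is the
concatenation of its site codes, site 1 leftmost — `n = g * s` qubits
spanning `N = 2^n` basis states. `H` on every sequence qubit prepares the
uniform superposition; one Grover iteration is the phase oracle followed by
the diffuser (inversion about the mean), and after `R` iterations the total
probability of `M` marked states follows `sin^2((2R + 1) * asin(sqrt(M/N)))`.
`optimal_iterations()` returns the maximizing `R >= 1` (ties toward smaller
`R`), which never exceeds `ceiling(pi/4 * sqrt(N/M))` and grows as
`sqrt(N/M)` — the quadratic advantage over a classical scan.

When `A < 2^g` some binary codes name no residue. Those states still live in
the superposition; the convention here is that any pair involving an invalid
code contributes zero energy, in both the circuit (no load fires) and the
classical reference, so the two semantics never diverge. All packaged
instances use `A = 2^g`.

## The adder-only oracle

On a basis state `|k>|0...0>` the oracle computes `E_tot(k) - E_th` in an
`m`-qubit two's-complement accumulator, applies `Z` to the sign bit (so
exactly the strictly-negative results, i.e. answers, acquire phase -1), and
uncomputes every arithmetic step so the work register returns to `|0>`:

1. **Constant loads** — for every residue pair with a nonzero entry, a
   multi-controlled X pattern keyed on the pair's `2g`-bit code writes the
   entry into the value register. Loads are self-inverse, which is also how
   they are removed again.
2. **Ripple-carry adders** — the Cuccaro-style MAJ/UMA construction adds the
   value register into the accumulator in place with one carry ancilla:
   `2m + 1` qubits, `{X, CX, CCX}` only. The subtractor is the adder
   conjugated by bitwise complement (`b - a = ~(~b + a)`).
3. **Multiplier (MR only)** — a shift-and-add multiplier forms the exact
   `2m`-bit signed product of the loaded energy and the `d_inv` constant from
   sign-extended partial products, then rounds it to `p` fraction bits into an
   `m`-bit output. Rounding is half-away-from-zero, implemented reversibly
   with two flag qubits (`f` = OR of the dropped bits below the halfway bit,
   `g = f OR NOT sign`); it matches `quantize()` bit for bit, so gate-level
   and classical energies are identical, not merely close. The
   ancilla-plus-output footprint is `5m + 3` qubits; resource reports quote
   the published `16m + 1` budget, which it respects with room to spare.

The register width comes from the qubit budget,
`m = ceiling(log2((|Emax| + |Emin|) * W * 2)) + p`, with interaction weight
`W = i` (SP/HP) or `W = sum(d_inv)` (MR). The literal complete-graph pair
count is available via `qubit_budget(..., eq3_literal = TRUE)`, but the
attainable-energy weight is the default because it is what the published
per-circuit budgets are consistent with. `oracle_format()` additionally
widens `m` if a user-chosen threshold pushes any intermediate value (raw table
entries, per-pair products, partial sums, or the threshold-subtracted total)
out of range, so in-circuit arithmetic can never wrap silently.

```{r budget}
qubit_budget(prob)
```

## Numerical and degenerate-input choices

* **Fixed-point grid.** MR tables must be exactly representable at the
  instance's `p` (default 5, precision 0.03125; the high-precision variant
  uses `p = 10`). Distance reciprocals are quantized onto the same grid at
  problem construction, so circuit constants and the classical reference use
  identical numbers. The classical MR energy quantizes each pairwise product
  before summing — the same order of operations as the circuit.
* **Ties.** Product rounding breaks ties away from zero everywhere.
  `optimal_iterations()` breaks ties toward smaller `R`.
* **Degenerate instances.** `M = 0` (empty answer set) makes Grover undefined
  and `M = N` makes it pointless; `run_grover()` refuses both unless
  `allow_degenerate = TRUE`. `R = 0` is permitted as a baseline (bare uniform
  superposition).
* **Bit order.** Qubit 0 is the leftmost character of every bitstring and the
  most significant bit of a basis-state index, uniformly across encoding,
  registers and serialization.

## Three backends and the verification strategy

`run_grover()` exposes three interchangeable backends. The `gate` backend
simulates the assembled circuit amplitude by amplitude (dense statevector,
capped at 24 qubits = 256 MiB of amplitudes) and asserts the work register is
exactly `|0>` before discarding it — the usual "work qubits are not measured"
assumption becomes a checked invariant. The `shortcut` backend replaces the
oracle by the diagonal phase computed from brute force, on `n` qubits only.
The `analytic` backend evaluates the closed form. All three agree to 1e-9 on
the packaged instances, which is itself one of the test suite's properties.

Oracles too wide for a statevector (the fixed-point MR circuits: 81 qubits at
`p = 5`, well beyond the cap even at reduced precision) are still verified
*exhaustively*: since the oracle is built from classical reversible gates plus
`Z`-type phases, a basis-state evaluator propagates each `|k>|0>` through the
gate list at a cost independent of width, and the resulting phase pattern is
compared against the brute-force answer set — for the packaged instances and
for randomized fixtures drawn by `generate_fixture()` under fixed seeds.

Problem sizes were chosen so the full suite stays interactive: exhaustive
arithmetic checks up to `m = 6` (adders) and `m = 5` (multiplier), gate-level
Grover runs at 15 and 20 qubits, shortcut-mode sweeps up to `N = 262144`
(the six-site SP hairpin), and 100+ random oracle fixtures.

## What the synthetic fixtures do and do not show

`generate_fixture()` draws symmetric random tables (integer, or on the MR
grid) over small alphabets, pins one pair to the range minimum so the default
threshold always yields a nonempty answer set, and samples random interaction
graphs. This exercises the full code-path space of the oracle builder —
arbitrary patterns of loads, negative and positive entries, partial graphs,
random `d_inv` weights — which is what the constructions must be correct
against. It does **not** emulate real proteins: there are no rotamers, no
backbone geometry, no force-field energies, and residues are interchangeable
beads. Passing fixtures therefore certify the circuit constructions and the
search dynamics, not the biological fidelity of any particular energy table;
realistic use means supplying your own precomputed table via CSV.

## Known limitations

* Ideal, noise-free simulation only: no device noise channels, no
  transpilation to native gate sets or coupling maps, no matrix-product-state
  backend. Published figures tied to those (hardware success probabilities,
  transpiled depths) are intentionally out of scope.
* `decompose_circuit()` lowers `MCX`/`MCZ` with one specific Toffoli-ladder
  convention; depth after decomposition is convention-dependent and no
  specific decomposed-depth figure is asserted.
* `asymptotic_costs()` evaluates leading-order gate-count expressions with
  unit constants and is labelled an estimate; only the `sqrt(N)`-versus-`N`
  scaling (and the resulting eventual crossover) is meaningful, not the exact
  crossover point.
* Register widths are capped at 30 bits of scaled integer — generous for
  contact-style tables, but this is not a general-purpose fixed-point
  library.
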