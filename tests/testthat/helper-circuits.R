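# Shared helpers: bit plumbing and the oracle-versus-brute-force harness.

int_bits <- function(k, m) as.integer(intToBits(k))[m:1]   # MSB first
bits_int <- function(bits) sum(bits * 2^((length(bits) - 1):0))

# All basis inputs |k>|0...0> for a problem's oracle.
oracle_inputs <- function(problem, circuit) {
  t(vapply(0:(problem$N - 1),
           function(k) c(int_bits(k, problem$n), rep(0L, circuit$width - problem$n)),
           integer(circuit$width)))
}

# Evaluate an oracle on every basis state; returns the marked k's plus the
# uncomputation / sequence-preservation checks.
oracle_exhaustive <- function(problem, fmt = NULL) {
  orc <- build_oracle(problem, fmt)
  inputs <- oracle_inputs(problem, orc)
  res <- evaluate_basis(orc, inputs)
  list(marked = sort(which(res$phase == -1L) - 1L),
       work_clean = all(res$bits[, (problem$n + 1):orc$width] == 0L),
       seq_preserved = all(res$bits[, 1:problem$n] == inputs[, 1:problem$n]),
       width = orc$width)
}

sp2_problem <- function(e_th = -3) {
  design_problem("SP", structure = protein_structure(2), e_th = e_th)
}

mr2_problem <- function(B = 0.95, p = 5) {
  design_problem("MR", table = default_energy_table("MR"),
                 structure = protein_structure(2, d_inv = 1.0), p = p, B = B)
}

hp2_problem <- function(e_th = 0) {
  design_problem("HP", structure = protein_structure(2), e_th = e_th)
}

sp3_problem <- function(e_th = -8) {
  design_problem("SP", structure = protein_structure(3), e_th = e_th)
}
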