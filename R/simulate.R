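# Evaluation backends: dense statevector simulation for small widths, and
# classical reversible basis-state propagation (cost independent of width) for
# the oracle's X/CX/CCX/MCX/Z/MCZ subset.

#' Propagate a basis state through a classical-reversible circuit
#'
#' Circuits built from `{X, CX, CCX, MCX, Z, MCZ}` map basis states to basis
#' states up to a sign; this backend propagates the bits classically and tracks
#' the accumulated phase, at a cost linear in the gate count and independent of
#' the qubit count. It is how wide oracles (e.g. the 100+ qubit fixed-point
#' models) are verified exhaustively.
#'
#' @param circuit A `quantum_circuit` without `H` gates.
#' @param input A bitstring of length `width`, or a matrix of 0/1 integers with
#'   one basis state per row.
#' @return For a single input, a list with `bits` (bitstring) and `phase`
#'   (+1 or -1); for a matrix, a list with a `bits` matrix and a `phase` vector.
#' @examples
#' qc <- quantum_circuit(2, list(gate_x(0)))
#' evaluate_basis(qc, "00")   # "10", phase +1
#' @export
evaluate_basis <- function(circuit, input) {
  single <- is.character(input) && length(input) == 1L
  if (single) input <- matrix(bitstring_to_bits(input), nrow = 1)
  if (!is.matrix(input)) stop("'input' must be a bitstring or a 0/1 matrix")
  if (ncol(input) != circuit$width)
    stop("input width does not match the circuit width")
  cc <- compile_circuit(circuit)
  res <- cpp_evaluate_basis_batch(input, cc$kind, cc$controls, cc$target)
  if (single)
    list(bits = bits_to_bitstring(res$bits[1, ]), phase = res$phase[1])
  else
    res
}

#' Run a circuit on the dense statevector simulator
#'
#' Exact complex amplitudes for circuits up to `cap` qubits (default 24, i.e.
#' 256 MiB of amplitudes). Supports the full gate alphabet including `H`.
#'
#' @param circuit A `quantum_circuit`.
#' @param initial Initial basis state as a bitstring (default all zeros).
#' @param cap Maximum width accepted.
#' @return Complex amplitude vector of length `2^width`, indexed so that the
#'   bitstring with qubit 0 leftmost is the binary expansion of `index - 1`.
#' @examples
#' psi <- run_statevector(quantum_circuit(1, list(gate_h(0))))
#' abs(psi)^2    # 0.5, 0.5
#' @export
run_statevector <- function(circuit, initial = NULL, cap = 24L) {
  q <- circuit$width
  if (q > cap)
    stop(sprintf("circuit width %d exceeds the statevector cap of %d qubits", q, cap))
  dim <- 2^q
  psi <- complex(real = numeric(dim))
  if (is.null(initial)) {
    psi[1] <- 1 + 0i
  } else {
    bits <- bitstring_to_bits(initial)
    if (length(bits) != q) stop("initial state width does not match the circuit")
    psi[sum(bits * 2^((q - 1):0)) + 1] <- 1 + 0i
  }
  cc <- compile_circuit(circuit)
  psi <- cpp_run_statevector(psi, q, cc$kind, cc$controls, cc$target)
  nrm <- sum(abs(psi)^2)
  if (abs(nrm - 1) > 1e-9)
    stop(sprintf("statevector norm drifted to %.12f", nrm))
  psi
}

#' Sample measurement counts from a probability vector
#'
#' Multinomial sampling of `shots` measurements, reproducible under `seed`.
#' The caller's RNG state is preserved.
#'
#' @param probabilities Probability vector (must be non-negative, sum 1).
#' @param shots Number of samples, e.g. the 8192 shots used for the packaged
#'   demonstrations.
#' @param seed Integer seed.
#' @return Integer vector of counts, same length and names as `probabilities`.
#' @export
sample_counts <- function(probabilities, shots, seed) {
  if (any(probabilities < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probabilities) - 1) > 1e-9) stop("probabilities must sum to 1")
  counts <- with_preserved_seed(seed,
    rmultinom(1, size = shots, prob = probabilities)[, 1])
  names(counts) <- names(probabilities)
  counts
}
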