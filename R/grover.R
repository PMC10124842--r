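# Full Grover pipeline: initialization, model-specific phase oracles built
# from the reversible arithmetic fragments, the diffuser, iteration
# scheduling, and three interchangeable execution backends.

#' Uniform-superposition initialization
#'
#' `H` on each of the `n` sequence qubits, creating the uniform superposition
#' over all `N = 2^n` candidate sequences from `|0...0>`.
#'
#' @param n Number of sequence qubits.
#' @return A `quantum_circuit` of width `n`.
#' @export
build_initialization <- function(n) {
  quantum_circuit(n, lapply(seq_len(n) - 1L, gate_h))
}

#' Grover diffuser (inversion about the mean)
#'
#' The standard construction `H^n X^n (n-controlled Z) X^n H^n` acting on the
#' sequence register only. Applied to states marked with a negative amplitude
#' by the oracle, it amplifies their probability at the expense of the rest.
#'
#' @param n Number of sequence qubits.
#' @return A `quantum_circuit` of width `n`.
#' @export
build_diffuser <- function(n) {
  hs <- lapply(seq_len(n) - 1L, gate_h)
  xs <- lapply(seq_len(n) - 1L, gate_x)
  mcz <- gate_z(n - 1L, controls = if (n > 1L) 0:(n - 2L) else integer(0))
  quantum_circuit(n, c(hs, xs, list(mcz), xs, hs))
}

# Smallest m >= lower that represents every value in 'vals' at p fraction bits.
min_width_for <- function(vals, p, lower = 1L) {
  z <- round(vals * 2^p)
  m <- max(lower, p + 1L)
  while (any(z < -2^(m - 1) | z > 2^(m - 1) - 1)) m <- m + 1L
  as.integer(m)
}

# Per-interaction energy contributions (already distance-weighted and
# quantized for MR), one numeric vector of the nonzero entries per pair.
pair_contributions <- function(problem) {
  A <- problem$alphabet$A
  vals <- problem$table$values
  lapply(seq_len(problem$structure$i), function(r) {
    e <- as.numeric(vals)
    if (problem$model == "MR")
      e <- quantize(e * problem$structure$d_inv[r], problem$p)
    e
  })
}

#' Fixed-point format used by a problem's oracle
#'
#' Starts from the register width of [qubit_budget()] and widens it if an
#' explicit user threshold pushes any intermediate value (partial energy sums,
#' the threshold itself, or the threshold-subtracted total) out of range, so
#' the in-circuit arithmetic can never wrap.
#'
#' @param problem A [design_problem()].
#' @return A [fixed_point_format()].
#' @export
oracle_format <- function(problem) {
  m0 <- qubit_budget(problem)$m
  contrib <- pair_contributions(problem)
  lo <- cumsum(vapply(contrib, min, numeric(1)))
  hi <- cumsum(vapply(contrib, max, numeric(1)))
  e_th <- threshold_energy(problem)
  vals <- c(unlist(contrib), lo, hi, e_th,
            lo[length(lo)] - e_th, hi[length(hi)] - e_th)
  if (problem$model == "MR")   # raw table entries and d^-1 live in registers too
    vals <- c(vals, as.numeric(problem$table$values), problem$structure$d_inv)
  fixed_point_format(min_width_for(vals, problem$p, lower = m0), problem$p)
}

seq_qubits_for_site <- function(problem, site) {
  (site - 1L) * problem$g + seq_len(problem$g) - 1L
}

# Controlled loads writing E(r_a, r_b) into 'reg' for every residue pair with
# a nonzero (weighted, quantized) energy, keyed on the pair's binary code.
energy_load_gates <- function(problem, fmt, pair_row, reg, weight = 1) {
  A <- problem$alphabet$A
  u <- problem$structure$pairs[pair_row, 1]
  v <- problem$structure$pairs[pair_row, 2]
  controls <- c(seq_qubits_for_site(problem, u), seq_qubits_for_site(problem, v))
  gates <- list()
  for (ia in seq_len(A)) {
    for (ib in seq_len(A)) {
      e <- problem$table$values[ia, ib]
      if (problem$model == "MR") e <- quantize(e * weight, problem$p)
      if (e == 0) next
      pattern <- paste0(residue_code(problem$alphabet, ia),
                        residue_code(problem$alphabet, ib))
      gates <- c(gates, constant_load_gates(e, fmt, reg, controls, pattern))
    }
  }
  gates
}

oracle_sp_gates <- function(problem, fmt, regs) {
  compute <- list()
  for (r in seq_len(problem$structure$i)) {
    loads <- energy_load_gates(problem, fmt, r, regs$val)
    compute <- c(compute, loads, adder_gates(regs$val, regs$acc, regs$carry),
                 rev(loads))
  }
  e_th <- threshold_energy(problem)
  thr <- constant_load_gates(e_th, fmt, regs$val)
  compute <- c(compute, thr, subtractor_gates(regs$val, regs$acc, regs$carry))
  compute
}

oracle_mr_gates <- function(problem, fmt, regs) {
  compute <- list()
  for (r in seq_len(problem$structure$i)) {
    dinv <- problem$structure$d_inv[r]
    b_load <- constant_load_gates(dinv, fmt, regs$b)
    a_loads <- energy_load_gates(problem, fmt, r, regs$a)
    mult <- multiplier_gates(fmt, regs$a, regs$b, regs$out, regs$prod,
                             regs$temp, regs$carry, regs$f, regs$g)
    compute <- c(compute, b_load, a_loads, mult,
                 adder_gates(regs$out, regs$acc, regs$carry),
                 rev(mult), rev(a_loads), rev(b_load))
  }
  e_th <- threshold_energy(problem)
  thr <- constant_load_gates(e_th, fmt, regs$a)
  compute <- c(compute, thr, subtractor_gates(regs$a, regs$acc, regs$carry))
  compute
}

#' Build the phase oracle for a design problem
#'
#' On a basis state `|k>|0...0>` the oracle computes the sequence's total
#' energy into an accumulator with controlled constant loads and ripple-carry
#' adders (the MR model additionally multiplies each entry by its distance
#' reciprocal with the in-circuit multiplier), subtracts the threshold, applies
#' a `Z` to the sign bit of the two's-complement difference (so exactly the
#' states with `E_tot < E_th` acquire a `-1` phase), and then uncomputes every
#' arithmetic step. Net effect: `(-1)^f(k) |k>|0...0>` with all work qubits
#' restored to zero.
#'
#' SP/HP oracles use `2m + 1` work qubits (value, accumulator, carry); MR
#' oracles use `8m + 3` (accumulator plus the multiplier block), inside the
#' `16m + 1` budget quoted by the resource reports.
#'
#' @param problem A [design_problem()].
#' @param fmt Fixed-point format; defaults to [oracle_format()].
#' @return A `quantum_circuit` over `n + work` qubits with a `seq` register
#'   first; attribute `work_qubits` records the work-register width.
#' @export
build_oracle <- function(problem, fmt = NULL) {
  if (is.null(fmt)) fmt <- oracle_format(problem)
  m <- fmt$m
  n <- problem$n
  if (problem$model == "MR") {
    regs <- std_registers(seq = n, acc = m, a = m, b = m, out = m,
                          prod = 2L * m, temp = 2L * m, carry = 1L,
                          f = 1L, g = 1L)
    compute <- oracle_mr_gates(problem, fmt, regs)
  } else {
    regs <- std_registers(seq = n, acc = m, val = m, carry = 1L)
    compute <- oracle_sp_gates(problem, fmt, regs)
  }
  gates <- c(compute, list(gate_z(regs$acc[1])), rev(compute))
  width <- max(unlist(regs)) + 1L
  qc <- quantum_circuit(width, gates, registers = regs, validate = FALSE)
  attr(qc, "work_qubits") <- width - n
  attr(qc, "fmt") <- fmt
  qc
}

#' Assemble the full Grover circuit
#'
#' Initialization on the sequence register followed by `R` repetitions of the
#' oracle and the diffuser.
#'
#' @param problem A [design_problem()].
#' @param R Number of Grover iterations (>= 0).
#' @param fmt Optional fixed-point format override.
#' @return A `quantum_circuit` over the oracle's full width.
#' @export
build_grover_circuit <- function(problem, R, fmt = NULL) {
  oracle <- build_oracle(problem, fmt)
  n <- problem$n
  init <- build_initialization(n)
  diff <- build_diffuser(n)
  gates <- init$gates
  for (r in seq_len(R)) gates <- c(gates, oracle$gates, diff$gates)
  qc <- quantum_circuit(oracle$width, gates, oracle$registers, validate = FALSE)
  attr(qc, "work_qubits") <- attr(oracle, "work_qubits")
  qc
}

#' Closed-form Grover success probability
#'
#' `sin^2((2R+1) * asin(sqrt(M/N)))`: the total probability of the `M` marked
#' states after `R` oracle + diffuser iterations of a uniform search over `N`
#' states.
#'
#' @param N Total number of states.
#' @param M Number of marked states (`0 <= M <= N`).
#' @param R Iteration count (vectorized).
#' @return Success probabilities in `[0, 1]`.
#' @examples
#' success_probability(64, 2, 1)   # ~0.258
#' success_probability(64, 2, 4)   # ~0.999
#' @export
success_probability <- function(N, M, R) {
  if (M > N) stop("M cannot exceed N")
  if (M < 0 || N < 1) stop("invalid (N, M)")
  theta <- asin(sqrt(M / N))
  sin((2 * R + 1) * theta)^2
}

#' Iteration count maximizing the success probability
#'
#' The `R >= 1` maximizing [success_probability()] (ties broken toward smaller
#' `R`); always at most `ceiling((pi/4) * sqrt(N/M))`.
#'
#' @param N Total number of states.
#' @param M Number of marked states (`1 <= M < N`).
#' @return Integer `R_max`.
#' @examples
#' optimal_iterations(64, 2)   # 4
#' optimal_iterations(64, 5)   # 2
#' @export
optimal_iterations <- function(N, M) {
  if (M < 1) stop("M must be at least 1")
  if (M >= N) stop("M must be smaller than N")
  theta <- asin(sqrt(M / N))
  cont <- (pi / (2 * theta) - 1) / 2
  cands <- sort(unique(pmax(1, c(floor(cont), ceiling(cont)))))
  cands[which.max(success_probability(N, M, cands))]
}

#' Run Grover's algorithm on a design problem
#'
#' The marked set is first determined by brute force ([enumerate_answer_states()]),
#' both as a degeneracy guard (Grover is undefined for `M = 0` and pointless
#' for `M = N`) and to resolve `R = "auto"` via [optimal_iterations()]. Three
#' backends then produce the per-state probabilities:
#'
#' * `"gate"` — full statevector simulation of the assembled circuit
#'   (initialization + R x (oracle + diffuser)). The work register is asserted
#'   to be exactly `|0>` before it is marginalized out, turning the usual
#'   "work qubits are discarded unmeasured" assumption into a checked invariant.
#'   Requires total width within the statevector cap.
#' * `"shortcut"` — n-qubit statevector with the oracle replaced by the
#'   diagonal +/-1 phase from the brute-force answer set.
#' * `"analytic"` — closed-form probabilities (uniform within the marked and
#'   unmarked classes).
#'
#' All three agree to numerical precision.
#'
#' @param problem A [design_problem()].
#' @param R Iteration count, or `"auto"` for `R_max`.
#' @param backend `"shortcut"`, `"gate"` or `"analytic"`.
#' @param shots If non-NULL, also sample measurement counts (requires `seed`).
#' @param seed Seed for sampling.
#' @param allow_degenerate Proceed even when `M = 0` or `M = N`.
#' @param cap Statevector width cap for gate mode.
#' @param keep_states Attach the full per-state table (default for `N <= 65536`).
#' @return An object of class `grover_result`: per-state probabilities, the
#'   marked set, `M`, `R`, the success probability (total marked mass), the
#'   backend used, and optionally counts and the per-state table.
#' @export
run_grover <- function(problem, R = "auto",
                       backend = c("shortcut", "gate", "analytic"),
                       shots = NULL, seed = NULL, allow_degenerate = FALSE,
                       cap = 24L, keep_states = NULL) {
  backend <- match.arg(backend)
  answers <- enumerate_answer_states(problem)
  M <- attr(answers, "M")
  N <- problem$N
  e_th <- attr(answers, "e_th")
  if ((M == 0L || M == N) && !allow_degenerate)
    stop(sprintf(paste0("degenerate instance: M = %d of N = %d states are marked ",
                        "(set allow_degenerate = TRUE to run anyway)"), M, N))
  if (identical(R, "auto")) {
    if (M == 0L || M == N)
      stop("R = \"auto\" needs 1 <= M < N")
    R <- optimal_iterations(N, M)
  }
  R <- as.integer(R)
  if (R < 0L) stop("R must be >= 0")
  marked_k <- answers$k

  if (backend == "gate") {
    qc <- build_grover_circuit(problem, R)
    if (qc$width > cap)
      stop(sprintf(paste0("gate mode needs %d qubits, above the statevector cap ",
                          "of %d; use the shortcut or analytic backend"),
                   qc$width, cap))
    psi <- run_statevector(qc, cap = cap)
    w <- qc$width - problem$n
    amp <- matrix(psi, nrow = 2^w)
    work_mass <- if (nrow(amp) > 1) sum(abs(amp[-1, ])^2) else 0
    if (work_mass > 1e-12)
      stop(sprintf("work qubits failed to uncompute (stray mass %.3e)", work_mass))
    probs <- abs(amp[1, ])^2
  } else if (backend == "shortcut") {
    phase <- rep(1, N)
    phase[marked_k + 1L] <- -1
    psi <- rep(1 / sqrt(N), N)
    for (r in seq_len(R)) {
      psi <- phase * psi
      psi <- 2 * mean(psi) - psi
    }
    probs <- psi^2
  } else {
    p_tot <- success_probability(N, M, R)
    probs <- rep(if (N > M) (1 - p_tot) / (N - M) else 0, N)
    if (M > 0) probs[marked_k + 1L] <- p_tot / M
  }

  success <- sum(probs[marked_k + 1L])
  if (is.null(keep_states)) keep_states <- N <= 65536
  per_state <- NULL
  if (keep_states) {
    energies <- state_energies(problem)
    ks <- 0:(N - 1)
    bitstrings <- vapply(ks, int_to_bitstring, character(1), m = problem$n)
    seqs <- vapply(bitstrings, function(b)
      paste(decode_sequence(b, problem), collapse = "-"), character(1),
      USE.NAMES = FALSE)
    per_state <- data.frame(k = ks, bitstring = bitstrings, sequence = seqs,
                            energy = energies, probability = probs,
                            marked = ks %in% marked_k,
                            stringsAsFactors = FALSE)
  }
  counts <- NULL
  if (!is.null(shots)) {
    if (is.null(seed)) stop("sampling requires a 'seed'")
    nm <- if (!is.null(per_state)) per_state$bitstring else NULL
    counts <- sample_counts(setNames(probs, nm), shots, seed)
  }
  structure(list(model = problem$model, s = problem$s, n = problem$n,
                 N = N, M = M, R = R, e_th = e_th, backend = backend,
                 probabilities = probs, marked = marked_k,
                 success_probability = success,
                 per_state = per_state, counts = counts),
            class = "grover_result")
}

#' @export
print.grover_result <- function(x, ...) {
  cat(sprintf("<grover_result: %s model, N = %d, M = %d, R = %d, E_th = %g, %s backend>\n",
              x$model, x$N, x$M, x$R, x$e_th, x$backend))
  cat(sprintf("  success probability (total over %d marked states): %.4f\n",
              x$M, x$success_probability))
  if (!is.null(x$per_state)) {
    top <- x$per_state[order(-x$per_state$probability), ]
    print(head(top[, c("sequence", "bitstring", "energy", "probability", "marked")],
               min(5, nrow(top))), row.names = FALSE)
  }
  invisible(x)
}

#' Success probability as a function of the iteration count
#'
#' Runs [run_grover()] once per requested `R` and tabulates the total marked
#' probability; the curve rises as `sin^2((2R+1) theta)` to its maximum at
#' `R_max` and falls beyond it.
#'
#' @param problem A [design_problem()].
#' @param R_values Integer vector of iteration counts (>= 0).
#' @param backend Backend passed to [run_grover()].
#' @return A data frame with columns `R` and `success_probability`.
#' @export
sweep_iterations <- function(problem, R_values, backend = "shortcut") {
  if (any(R_values < 0)) stop("iteration counts must be >= 0")
  succ <- vapply(R_values, function(r)
    run_grover(problem, R = r, backend = backend,
               keep_states = FALSE)$success_probability, numeric(1))
  data.frame(R = as.integer(R_values), success_probability = succ)
}
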