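# Reversible fixed-point arithmetic fragments the oracle is built from.
# All builders emit only {X, CX, CCX, MCX}, so every fragment is verifiable by
# the basis-state evaluator at any register width. Register index vectors are
# most-significant bit first (matching bitstrings); helper functions below
# take LSB-first views internally.

# Ripple-carry addition b := a + b (mod 2^m) after Cuccaro et al.'s
# MAJ/UMA construction; 'carry' is a single clean ancilla, restored to 0.
adder_gates <- function(a, b, carry) {
  m <- length(a)
  al <- rev(a); bl <- rev(b)               # LSB first
  x <- c(carry, al[-m])                    # carry partner at each position
  gates <- vector("list", 6L * m)
  k <- 0L
  for (j in seq_len(m)) {                  # MAJ ladder
    gates[[k + 1L]] <- gate_x(bl[j], al[j])
    gates[[k + 2L]] <- gate_x(x[j], al[j])
    gates[[k + 3L]] <- gate_x(al[j], c(x[j], bl[j]))
    k <- k + 3L
  }
  for (j in rev(seq_len(m))) {             # UMA ladder (2-CNOT form)
    gates[[k + 1L]] <- gate_x(al[j], c(x[j], bl[j]))
    gates[[k + 2L]] <- gate_x(x[j], al[j])
    gates[[k + 3L]] <- gate_x(bl[j], x[j])
    k <- k + 3L
  }
  gates
}

# b := b - a (mod 2^m): the adder conjugated by bitwise complement of b,
# since b - a = ~(~b + a) in two's complement.
subtractor_gates <- function(a, b, carry) {
  conj <- lapply(b, gate_x)
  c(conj, adder_gates(a, b, carry), conj)
}

# Write a constant's bit pattern into an all-zero register, optionally
# controlled on 'controls' matching the given 0/1 'pattern' (zero-pattern
# controls are X-conjugated). Self-inverse.
constant_load_gates <- function(value, fmt, target, controls = integer(0),
                                pattern = NULL) {
  bits <- bitstring_to_bits(fp_encode(value, fmt))
  set <- which(bits == 1L)
  pre <- list()
  if (!is.null(pattern) && length(controls)) {
    pat <- if (is.character(pattern)) bitstring_to_bits(pattern) else pattern
    if (length(pat) != length(controls))
      stop("control pattern length must match the number of controls")
    pre <- lapply(controls[pat == 0L], gate_x)
  }
  core <- lapply(target[set], gate_x, controls = controls)
  c(pre, core, rev(pre))
}

# |a>|b>|0...> -> |a>|b>|round_p(a*b)>|0...>: shift-and-add over sign-extended
# partial products into a 2m-bit product register, then reversible rounding
# (half away from zero) of the low p bits into the m-bit output. 'prod' and
# 'temp' are 2m-bit ancilla registers, 'f'/'g' single-qubit rounding flags;
# all ancillas are restored to 0.
multiplier_gates <- function(fmt, a, b, out, prod, temp, carry, f, g) {
  m <- fmt$m; p <- fmt$p
  al <- rev(a); bl <- rev(b); pl <- rev(prod); tl <- rev(temp); ol <- rev(out)

  shift_add <- list()
  for (j in 0:(m - 1L)) {
    ctrl <- bl[j + 1L]
    copies <- lapply(0:(m - 1L), function(i) gate_x(tl[j + i + 1L], c(ctrl, al[i + 1L])))
    if (j + m < 2L * m)
      copies <- c(copies, lapply((j + m):(2L * m - 1L),
                                 function(k2) gate_x(tl[k2 + 1L], c(ctrl, al[m]))))
    adds <- if (j < m - 1L) adder_gates(temp, prod, carry)
            else subtractor_gates(temp, prod, carry)   # sign bit of b weighs -2^(m-1)
    shift_add <- c(shift_add, copies, adds, rev(copies))
  }

  round_gates <- list()
  if (p > 0L) {
    s_bit <- pl[2L * m]                       # product sign
    f_gates <- list()
    if (p >= 2L) {                            # f := OR of dropped bits 0..p-2
      low <- pl[seq_len(p - 1L)]
      lowx <- lapply(low, gate_x)
      f_gates <- c(list(gate_x(f)), lowx, list(gate_x(f, low)), lowx)
    }
    # g := f OR NOT sign  (round up at the halfway bit unless negative-and-exact-half)
    g_gates <- list(gate_x(f), gate_x(g, c(f, s_bit)), gate_x(f), gate_x(g))
    copy_gates <- lapply(seq_len(m), function(i) gate_x(ol[i], pl[p + i]))
    inc_flag <- gate_x(tl[1L], c(pl[p], g))   # +1 iff halfway bit set and g
    inc_add <- adder_gates(temp[(m + 1L):(2L * m)], out, carry)
    round_gates <- c(f_gates, g_gates, copy_gates,
                     list(inc_flag), inc_add, list(inc_flag),
                     rev(g_gates), rev(f_gates))
  } else {
    round_gates <- lapply(seq_len(m), function(i) gate_x(ol[i], pl[i]))
  }

  c(shift_add, round_gates, rev(shift_add))
}

std_registers <- function(...) {
  spec <- list(...)
  at <- 0L
  regs <- list()
  for (nm in names(spec)) {
    regs[[nm]] <- at + seq_len(spec[[nm]]) - 1L
    at <- at + spec[[nm]]
  }
  regs
}

#' Build a ripple-carry adder circuit
#'
#' An in-place Cuccaro-style ripple-carry adder mapping basis states
#' `|a>|b>|0>` to `|a>|a+b mod 2^m>|0>` (two's-complement wraparound) over
#' exactly `2m + 1` qubits: registers `a` (qubits 0..m-1, MSB first), `b`
#' (m..2m-1) and one carry ancilla (2m), built from `{X, CX, CCX}` only.
#'
#' @param fmt A [fixed_point_format()] (only `m` matters for the adder).
#' @return A `quantum_circuit` with registers `a`, `b`, `carry`.
#' @examples
#' qc <- build_adder(fixed_point_format(4))
#' evaluate_basis(qc, paste0(fp_encode(-4, fixed_point_format(4)),
#'                           fp_encode(3, fixed_point_format(4)), "0"))
#' @export
build_adder <- function(fmt) {
  m <- fmt$m
  regs <- std_registers(a = m, b = m, carry = 1L)
  quantum_circuit(2L * m + 1L, adder_gates(regs$a, regs$b, regs$carry),
                  registers = regs, validate = FALSE)
}

#' Build a ripple-carry subtractor circuit
#'
#' Maps `|a>|b>|0>` to `|a>|b-a mod 2^m>|0>`, realized as the adder conjugated
#' by bitwise complement of `b`; same `2m + 1` qubit layout as [build_adder()].
#'
#' @param fmt A [fixed_point_format()].
#' @return A `quantum_circuit` with registers `a`, `b`, `carry`.
#' @export
build_subtractor <- function(fmt) {
  m <- fmt$m
  regs <- std_registers(a = m, b = m, carry = 1L)
  quantum_circuit(2L * m + 1L, subtractor_gates(regs$a, regs$b, regs$carry),
                  registers = regs, validate = FALSE)
}

#' Build a fixed-point multiplier circuit
#'
#' Shift-and-add multiplication of two signed fixed-point registers:
#' `|a>|b>|0...0>` maps to `|a>|b>|round(a*b)>|0...0>`, where the product is
#' quantized to `p` fraction bits with the same round-half-away-from-zero rule
#' as [quantize()], so gate-level and classical energies agree bit-exactly.
#' Layout: `a` (m), `b` (m), `out` (m), then ancillas `prod` (2m), `temp` (2m),
#' `carry`, `f`, `g` — all ancillas restored to 0 on every basis input. The
#' ancilla-plus-output footprint is `5m + 3`, within the `16m + 1` work-qubit
#' budget the resource reports quote.
#'
#' If the true rounded product overflows `m` bits the output wraps; widths are
#' chosen upstream so that in-range problems never overflow, and the classical
#' evaluator raises on out-of-range values during verification.
#'
#' @param fmt A [fixed_point_format()].
#' @return A `quantum_circuit` with registers `a`, `b`, `out`, `prod`, `temp`,
#'   `carry`, `f`, `g`.
#' @export
build_multiplier <- function(fmt) {
  m <- fmt$m
  regs <- std_registers(a = m, b = m, out = m, prod = 2L * m, temp = 2L * m,
                        carry = 1L, f = 1L, g = 1L)
  gates <- multiplier_gates(fmt, regs$a, regs$b, regs$out, regs$prod,
                            regs$temp, regs$carry, regs$f, regs$g)
  quantum_circuit(7L * m + 3L, gates, registers = regs, validate = FALSE)
}

#' Build a controlled constant loader
#'
#' Writes the two's-complement bit pattern of `constant` into an all-zero
#' target register with multi-controlled X gates, firing only when the control
#' qubits match `pattern` (zero-pattern controls are conjugated by X). This is
#' how classically pre-computed energy-table entries enter the oracle: one
#' loader per residue-pair code with a nonzero entry. Self-inverse, so applying
#' it twice restores the register.
#'
#' @param constant The fixed-point value to load.
#' @param fmt A [fixed_point_format()].
#' @param controls Integer vector of control qubit indices (may be empty).
#' @param pattern Bitstring (or 0/1 vector) the controls must match; defaults
#'   to all ones.
#' @param width Total circuit width (default: just past the target register).
#' @param target Target register indices (default: the `m` qubits after the
#'   controls).
#' @return A `quantum_circuit`.
#' @export
build_constant_load <- function(constant, fmt, controls = integer(0),
                                pattern = NULL, width = NULL, target = NULL) {
  if (is.null(target))
    target <- (if (length(controls)) max(controls) + 1L else 0L) + seq_len(fmt$m) - 1L
  if (is.null(width)) width <- max(c(controls, target)) + 1L
  gates <- constant_load_gates(constant, fmt, target, controls, pattern)
  quantum_circuit(width, gates, registers = list(target = target),
                  validate = FALSE)
}
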