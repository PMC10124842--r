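# Gate-level intermediate representation.
#
# A gate is a list(kind, target, controls). The gate alphabet is
# {H, X, CX, CCX, MCX, Z, MCZ}; every member is self-inverse, so the inverse of
# a circuit is its gate list reversed. Qubit 0 is the LEFTMOST character of a
# bitstring (most significant bit of a basis-state index) everywhere.

#' Construct a single gate
#'
#' `gate_x()`, `gate_z()` and `gate_h()` are convenience constructors that pick
#' the conventional kind name from the number of controls (`X`/`CX`/`CCX`/`MCX`
#' and `Z`/`MCZ`).
#'
#' @param kind Gate kind, one of `"H"`, `"X"`, `"CX"`, `"CCX"`, `"MCX"`, `"Z"`, `"MCZ"`.
#' @param target Target qubit index (0-based).
#' @param controls Integer vector of control qubit indices (0-based).
#' @return An object of class `qgate`.
#' @export
gate <- function(kind, target, controls = integer(0)) {
  structure(list(kind = kind, target = as.integer(target),
                 controls = as.integer(controls)),
            class = "qgate")
}

#' @rdname gate
#' @export
gate_x <- function(target, controls = integer(0)) {
  nc <- length(controls)
  kind <- if (nc == 0L) "X" else if (nc == 1L) "CX" else if (nc == 2L) "CCX" else "MCX"
  gate(kind, target, controls)
}

#' @rdname gate
#' @export
gate_z <- function(target, controls = integer(0)) {
  gate(if (length(controls)) "MCZ" else "Z", target, controls)
}

#' @rdname gate
#' @export
gate_h <- function(target) gate("H", target)

#' @export
print.qgate <- function(x, ...) {
  cat(format_gate(x), "\n")
  invisible(x)
}

format_gate <- function(g) {
  if (length(g$controls))
    sprintf("%s %s -> %d", g$kind, paste(g$controls, collapse = " "), g$target)
  else
    sprintf("%s -> %d", g$kind, g$target)
}

#' Construct a quantum circuit
#'
#' A circuit is an ordered gate list over `width` qubits plus an optional named
#' register map (named integer vectors of qubit indices, most significant bit
#' first within each value register).
#'
#' @param width Number of qubits.
#' @param gates List of gates (see [gate()]).
#' @param registers Named list of 0-based qubit index vectors.
#' @param validate Check gate indices against the width (disable for large
#'   internally-built circuits).
#' @return An object of class `quantum_circuit`.
#' @export
quantum_circuit <- function(width, gates = list(), registers = list(),
                            validate = TRUE) {
  width <- as.integer(width)
  if (is.na(width) || width < 1L) stop("'width' must be a positive integer")
  if (validate && length(gates)) {
    for (g in gates) {
      qs <- c(g$target, g$controls)
      if (anyDuplicated(qs)) stop("controls and target of a gate must be disjoint")
      if (any(qs < 0L | qs >= width)) stop("gate qubit index out of range")
    }
  }
  if (length(registers)) {
    all_idx <- unlist(registers, use.names = FALSE)
    if (anyDuplicated(all_idx)) stop("register ranges must be disjoint")
    if (any(all_idx < 0L | all_idx >= width)) stop("register index out of range")
  }
  structure(list(width = width, gates = gates, registers = registers),
            class = "quantum_circuit")
}

#' @export
print.quantum_circuit <- function(x, n = 8, ...) {
  cat(sprintf("<quantum_circuit: %d qubits, %d gates, depth %d>\n",
              x$width, length(x$gates), circuit_depth(x)))
  if (length(x$registers)) {
    regs <- vapply(names(x$registers), function(nm) {
      idx <- x$registers[[nm]]
      sprintf("%s[%d]", nm, length(idx))
    }, character(1))
    cat("  registers:", paste(regs, collapse = " "), "\n")
  }
  shown <- head(x$gates, n)
  for (g in shown) cat(" ", format_gate(g), "\n")
  if (length(x$gates) > n) cat(sprintf("  ... %d more gates\n", length(x$gates) - n))
  invisible(x)
}

#' Concatenate circuits
#'
#' Gate lists are appended; the result's width is the larger of the two.
#' Registers of the first circuit are kept.
#'
#' @param a,b `quantum_circuit` objects.
#' @return A `quantum_circuit`.
#' @export
append_circuit <- function(a, b) {
  quantum_circuit(max(a$width, b$width), c(a$gates, b$gates),
                  registers = if (length(a$registers)) a$registers else b$registers,
                  validate = FALSE)
}

#' Invert a circuit
#'
#' Every gate in the IR is self-inverse, so the inverse circuit is the reversed
#' gate list.
#'
#' @param circuit A `quantum_circuit`.
#' @return A `quantum_circuit` implementing the inverse unitary.
#' @export
inverse_circuit <- function(circuit) {
  quantum_circuit(circuit$width, rev(circuit$gates), circuit$registers,
                  validate = FALSE)
}

# Lower the gate list to parallel vectors for the C++ kernels.
# kind codes: 0 = H, 1 = X-type, 2 = Z-type.
compile_circuit <- function(circuit) {
  ng <- length(circuit$gates)
  kind <- integer(ng)
  target <- integer(ng)
  controls <- vector("list", ng)
  for (i in seq_len(ng)) {
    g <- circuit$gates[[i]]
    kind[i] <- switch(g$kind, H = 0L, X = 1L, CX = 1L, CCX = 1L, MCX = 1L,
                      Z = 2L, MCZ = 2L,
                      stop(sprintf("unknown gate kind '%s'", g$kind)))
    target[i] <- g$target
    controls[[i]] <- g$controls
  }
  list(kind = kind, controls = controls, target = target)
}

#' Circuit depth
#'
#' The number of gates on the longest path through the circuit: gates acting on
#' disjoint qubits may run in parallel, so each gate sits one level above the
#' deepest frontier among the qubits it touches.
#'
#' @param circuit A `quantum_circuit`.
#' @return Integer depth (0 for an empty circuit).
#' @examples
#' qc <- quantum_circuit(2, list(gate_h(0), gate_x(1), gate_x(1, 0)))
#' circuit_depth(qc)   # 2
#' @export
circuit_depth <- function(circuit) {
  level <- integer(circuit$width)
  for (g in circuit$gates) {
    qs <- c(g$target, g$controls) + 1L
    lv <- max(level[qs]) + 1L
    level[qs] <- lv
  }
  if (circuit$width) max(level) else 0L
}

#' Tally gates by kind
#'
#' @param circuit A `quantum_circuit`.
#' @return Named integer vector of counts per gate kind; `sum()` of it equals
#'   the number of gates.
#' @export
count_gates <- function(circuit) {
  kinds <- c("H", "X", "CX", "CCX", "MCX", "Z", "MCZ")
  counts <- setNames(integer(length(kinds)), kinds)
  for (g in circuit$gates) counts[g$kind] <- counts[g$kind] + 1L
  counts
}

#' Serialize a circuit to newline-delimited text
#'
#' One gate per line, e.g. `"CCX 3 5 -> 9"`; the first line records the width.
#' [read_circuit()] inverts it.
#'
#' @param circuit A `quantum_circuit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_circuit <- function(circuit, path) {
  lines <- c(sprintf("width %d", circuit$width),
             vapply(circuit$gates, format_gate, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_circuit
#' @export
read_circuit <- function(path) {
  lines <- readLines(path)
  if (!grepl("^width [0-9]+$", lines[1])) stop("missing width header line")
  width <- as.integer(sub("^width ", "", lines[1]))
  gates <- lapply(lines[-1], function(ln) {
    parts <- strsplit(ln, " -> ", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop(sprintf("malformed gate line: '%s'", ln))
    lhs <- strsplit(trimws(parts[1]), " +")[[1]]
    gate(lhs[1], as.integer(parts[2]),
         controls = if (length(lhs) > 1) as.integer(lhs[-1]) else integer(0))
  })
  quantum_circuit(width, gates)
}

#' Decompose multi-controlled gates into the {H, X, CX, CCX} set
#'
#' Replaces every `MCX`/`MCZ` with a Toffoli ladder over freshly appended clean
#' ancilla qubits (`k` controls use `k - 2` ancillas and `2k - 3` Toffolis; an
#' `MCZ` is an `MCX` conjugated by `H` on its target). This is one reasonable
#' decomposition among many; depth figures quoted after decomposition depend on
#' the chosen convention.
#'
#' @param circuit A `quantum_circuit`.
#' @return A `quantum_circuit` over `width + ancillas` qubits whose action on
#'   the original qubits (with ancillas at 0) is identical.
#' @export
decompose_circuit <- function(circuit) {
  need <- 0L
  for (g in circuit$gates)
    if (g$kind %in% c("MCX", "MCZ"))
      need <- max(need, length(g$controls) - 1L)
  anc <- circuit$width + seq_len(need) - 1L
  out <- vector("list", 0L)
  for (g in circuit$gates) {
    if (!(g$kind %in% c("MCX", "MCZ"))) {
      out <- c(out, list(g))
      next
    }
    ctl <- g$controls
    k <- length(ctl)
    if (k <= 2L) {
      core <- if (g$kind == "MCZ") list(gate_z(g$target, ctl)) else list(gate_x(g$target, ctl))
      out <- c(out, core)
      next
    }
    ladder <- list(gate_x(anc[1], ctl[1:2]))
    for (j in seq_len(k - 2L)[-1])
      ladder <- c(ladder, list(gate_x(anc[j], c(ctl[j + 1L], anc[j - 1L]))))
    top <- c(ctl[k], anc[k - 2L])
    core <- if (g$kind == "MCZ")
      list(gate_h(g$target), gate_x(g$target, top), gate_h(g$target))
    else
      list(gate_x(g$target, top))
    out <- c(out, ladder, core, rev(ladder))
  }
  quantum_circuit(circuit$width + need, out, circuit$registers, validate = FALSE)
}
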