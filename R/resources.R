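# Qubit budgets and gate-count estimates.

#' Qubit budget of a design problem
#'
#' Sequence register: `n = g * s`. Value register width:
#' `m = ceiling(log2((|Emax| + |Emin|) * W * 2)) + p`, where the interaction
#' weight `W` is the interaction count `i` for the unweighted SP/HP models and
#' the attainable-energy bound `sum(d_inv)` for the distance-weighted MR model
#' (`eq3_literal = TRUE` instead uses the complete-graph pair count for MR).
#' Work qubits: `2m + 1` for SP/HP (value + accumulator + carry) and `16m + 1`
#' for MR (the multiplier block budget); total `q = n + work`.
#'
#' @param problem A [design_problem()].
#' @param e_span Override for `|Emax| + |Emin|` (some published budgets assume
#'   a wider span than a given table's).
#' @param weight Override for the interaction weight `W`.
#' @param eq3_literal Use `W = s(s-1)/2` for MR instead of `sum(d_inv)`.
#' @return An object of class `resource_report` with fields `model`, `s`, `A`,
#'   `g`, `n`, `N`, `i`, `W`, `p`, `e_min`, `e_max`, `m`, `work_qubits`,
#'   `total_qubits`.
#' @examples
#' qubit_budget(design_problem("SP", structure = protein_structure(2)))  # q = 15
#' @export
qubit_budget <- function(problem, e_span = NULL, weight = NULL,
                         eq3_literal = FALSE) {
  st <- problem$structure
  if (is.null(e_span))
    e_span <- abs(problem$table$e_max) + abs(problem$table$e_min)
  if (e_span <= 0) stop("the energy table must contain a nonzero entry")
  if (is.null(weight)) {
    weight <- if (problem$model == "MR") {
      if (eq3_literal) st$s * (st$s - 1) / 2 else sum(st$d_inv)
    } else {
      st$i
    }
  }
  m <- as.integer(ceiling(log2(e_span * weight * 2)) + problem$p)
  work <- if (problem$model == "MR") 16L * m + 1L else 2L * m + 1L
  structure(list(model = problem$model, s = st$s, A = problem$alphabet$A,
                 g = problem$g, n = problem$n, N = problem$N,
                 i = st$i, W = weight, p = problem$p,
                 e_min = problem$table$e_min, e_max = problem$table$e_max,
                 m = m, work_qubits = work, total_qubits = problem$n + work),
            class = "resource_report")
}

#' @export
print.resource_report <- function(x, ...) {
  cat(sprintf("<resource_report: %s model, s = %d>\n", x$model, x$s))
  cat(sprintf("  n = %d   N = %d   m = %d   work qubits = %d   total q = %d\n",
              x$n, x$N, x$m, x$work_qubits, x$total_qubits))
  cat(sprintf("  A = %d (g = %d), i = %d, W = %g, p = %d, E in [%g, %g]\n",
              x$A, x$g, x$i, x$W, x$p, x$e_min, x$e_max))
  invisible(x)
}

#' Leading-order gate-count estimates, quantum vs classical
#'
#' Evaluates with unit constants the leading-order expressions for the total
#' gate count of the quantum search,
#' `log2(N) + sqrt(N) * (log2(log2(N)) * ((log2 N)^2 + log2 N + 1) + log2 N)`,
#' and of an equivalent classical scan,
#' `N * log2(log2(N)) * (log2 N + 1)`. Both are ESTIMATES: the absolute
#' constants (and hence the exact crossover point) depend on conventions the
#' expressions do not fix, so only the scaling — `sqrt(N)` versus `N` — should
#' be read from them.
#'
#' @param N Number of states (>= 4), vectorized.
#' @return A data frame with columns `N`, `quantum_estimate`,
#'   `classical_estimate` and a `label` attribute marking the values as
#'   convention-dependent estimates.
#' @export
asymptotic_costs <- function(N) {
  if (any(N < 4)) stop("N must be at least 4")
  lg <- log2(N)
  quantum <- lg + sqrt(N) * (log2(lg) * (lg^2 + lg + 1) + lg)
  classical <- N * log2(lg) * (lg + 1)
  out <- data.frame(N = N, quantum_estimate = quantum,
                    classical_estimate = classical)
  attr(out, "label") <- "ESTIMATE: unit constants; only the scaling is meaningful"
  out
}
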