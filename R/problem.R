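# Design-problem definitions and the classical reference semantics every
# quantum construction is verified against.

#' Residue alphabet
#'
#' An ordered set of residue labels. Each residue is encoded on `g =
#' ceiling(log2(A))` qubits; the canonical code assigns consecutive binary
#' codes in table order (first label = all-zero code).
#'
#' @param names Character vector of unique residue labels (at least 2).
#' @return An object of class `residue_alphabet` with fields `names`, `A`, `g`.
#' @examples
#' residue_alphabet(c("H", "P"))
#' @export
residue_alphabet <- function(names) {
  names <- as.character(names)
  if (length(names) < 2L) stop("an alphabet needs at least 2 residues")
  if (anyDuplicated(names)) stop("residue labels must be unique")
  A <- length(names)
  structure(list(names = names, A = A, g = as.integer(ceiling(log2(A)))),
            class = "residue_alphabet")
}

#' @export
print.residue_alphabet <- function(x, ...) {
  cat(sprintf("<residue_alphabet: A = %d (%s), g = %d bits/residue>\n",
              x$A, paste(x$names, collapse = ","), x$g))
  invisible(x)
}

residue_code <- function(alphabet, idx) int_to_bitstring(idx - 1L, alphabet$g)

#' Pairwise residue energy table
#'
#' A symmetric A-by-A matrix of dimensionless contact energies. The extremes
#' `e_min`/`e_max` are always recomputed from the entries.
#'
#' @param values Square numeric matrix with identical row and column names
#'   (the residue labels).
#' @return An object of class `energy_table`.
#' @export
energy_table <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("energy table must be square")
  labels <- rownames(values)
  if (is.null(labels) || is.null(colnames(values)))
    stop("energy table needs residue labels as row and column names")
  if (!identical(labels, colnames(values)))
    stop("row and column labels of the energy table must match")
  if (!isTRUE(all.equal(values, t(values), tolerance = 0)))
    stop("energy table must be symmetric: values[a,b] must equal values[b,a]")
  structure(list(values = values, labels = labels,
                 e_min = min(values), e_max = max(values)),
            class = "energy_table")
}

#' @export
print.energy_table <- function(x, ...) {
  cat(sprintf("<energy_table: %d residues, e_min = %g, e_max = %g>\n",
              length(x$labels), x$e_min, x$e_max))
  print(x$values)
  invisible(x)
}

#' Read / write an energy table as CSV
#'
#' First row and column hold the residue labels; the body is the symmetric
#' matrix (decimal entries allowed for the fixed-point MR model).
#'
#' @param path CSV file path.
#' @return [read_energy_table()] returns an `energy_table`;
#'   [write_energy_table()] returns `path` invisibly.
#' @export
read_energy_table <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  colnames(m) <- colnames(df)
  energy_table(m)
}

#' @rdname read_energy_table
#' @param table An `energy_table`.
#' @export
write_energy_table <- function(table, path) {
  write.csv(table$values, path, quote = FALSE)
  invisible(path)
}

#' Packaged default energy tables
#'
#' Returns the packaged 8-residue tables (two hydrophobic types H1/H2, two
#' polar types Pol1/Pol2, charged Pos/Neg, and two neutral fillers X1/X2) for
#' the integer `"SP"` and fixed-point `"MR"` models, or the two-letter
#' hydrophobic-polar table for `"HP"`. The SP table has a unique minimum of -4
#' at the Pos/Neg salt bridge and a maximum of +1 for like-charge repulsion;
#' the HP table scores the single H-H contact at -2.
#'
#' @param model `"SP"`, `"MR"` or `"HP"`.
#' @return An `energy_table`.
#' @export
default_energy_table <- function(model = c("SP", "MR", "HP")) {
  model <- match.arg(model)
  file <- switch(model, SP = "sp_table.csv", MR = "mr_table.csv", HP = "hp_table.csv")
  read_energy_table(system.file("extdata", file, package = "qgdesign", mustWork = TRUE))
}

#' Designable-site structure
#'
#' `s` designable sites plus the set of interacting site pairs. The
#' distance-weighted MR model additionally needs a positive distance reciprocal
#' for every interacting pair and requires the complete interaction graph.
#'
#' @param sites Number of designable sites (>= 2).
#' @param interactions List (or 2-column matrix) of unordered site pairs,
#'   1-based. Defaults to all pairs.
#' @param d_inv Optional numeric vector of distance reciprocals, one per
#'   interaction pair (in the same order), all > 0.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(sites, interactions = NULL, d_inv = NULL) {
  s <- as.integer(sites)
  if (is.na(s) || s < 2L) stop("'sites' must be an integer >= 2")
  all_pairs <- t(utils::combn(s, 2))
  if (is.null(interactions)) {
    pairs <- all_pairs
  } else {
    if (is.list(interactions)) interactions <- do.call(rbind, interactions)
    pairs <- matrix(as.integer(interactions), ncol = 2)
    pairs <- t(apply(pairs, 1, sort))
    if (any(pairs[, 1] < 1L | pairs[, 2] > s)) stop("interaction site index out of range")
    if (any(pairs[, 1] == pairs[, 2])) stop("a site cannot interact with itself")
    if (anyDuplicated(pairs)) stop("duplicate interaction pair")
  }
  if (nrow(pairs) < 1L) stop("at least one interaction is required")
  if (!is.null(d_inv)) {
    d_inv <- as.numeric(d_inv)
    if (length(d_inv) != nrow(pairs))
      stop("'d_inv' must provide one distance reciprocal per interaction pair")
    if (any(d_inv <= 0)) stop("distance reciprocals must be > 0")
  }
  structure(list(s = s, pairs = pairs, i = nrow(pairs), d_inv = d_inv),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure: s = %d sites, i = %d interactions%s>\n",
              x$s, x$i, if (is.null(x$d_inv)) "" else ", distance-weighted"))
  invisible(x)
}

#' Define a protein design problem
#'
#' Binds a model kind, an energy table, a structure and a threshold into one
#' validated instance. Sequences over the alphabet are scored by the total
#' pairwise energy; the design goal is the set of sequences scoring strictly
#' below the threshold.
#'
#' Model kinds: `"SP"` (integer energies, unweighted interactions), `"MR"`
#' (fixed-point energies weighted by per-pair distance reciprocals; requires
#' the complete interaction graph), `"HP"` (two-letter hydrophobic-polar
#' variant of SP). SP/HP fix `p = 0`; MR defaults to `p = 5` (precision
#' 1/32 = 0.03125). MR distance reciprocals are quantized onto the `2^-p` grid
#' so the classical reference and the in-circuit constants agree exactly.
#'
#' The threshold is either an explicit energy `e_th` (SP/HP; default
#' `e_min * i + 1`, the lowest threshold that still admits the minimum-energy
#' sequences) or a fraction `B` in (0, 1] of the attainable minimum (MR; the
#' threshold is then `B * e_min * sum(d_inv)`, floored onto the energy grid).
#'
#' @param model `"SP"`, `"MR"` or `"HP"`.
#' @param table An [energy_table()]; defaults to the packaged table for the model.
#' @param structure A [protein_structure()].
#' @param p Fraction bits; only settable for MR.
#' @param e_th Explicit integer threshold (SP/HP only).
#' @param B Threshold fraction in (0, 1] (MR only; default 0.95).
#' @return An object of class `design_problem` with derived fields `alphabet`,
#'   `g`, `n = g*s` and `N = 2^n`.
#' @examples
#' prob <- design_problem("SP", structure = protein_structure(2), e_th = -3)
#' prob$N   # 64 sequence states
#' @export
design_problem <- function(model = c("SP", "MR", "HP"), table = NULL,
                           structure = NULL, p = NULL, e_th = NULL, B = NULL) {
  model <- match.arg(model)
  if (is.null(table)) table <- default_energy_table(model)
  if (is.null(structure)) stop("a 'structure' is required")
  alphabet <- residue_alphabet(table$labels)

  if (model %in% c("SP", "HP")) {
    if (!is.null(p) && p != 0L) stop("SP/HP models use integer energies (p = 0)")
    p <- 0L
    if (!is.null(B)) stop("'B' thresholds apply to the MR model only; use 'e_th'")
    if (!is.null(structure$d_inv))
      stop("distance reciprocals are not part of the SP/HP models")
    if (any(table$values != round(table$values)))
      stop("SP/HP energy tables must be integer-valued")
    if (!is.null(e_th) && e_th != round(e_th))
      stop("SP/HP thresholds must be integers")
  } else {
    if (is.null(p)) p <- 5L
    p <- as.integer(p)
    if (p < 1L) stop("the MR model needs at least 1 fraction bit")
    if (!is.null(e_th)) stop("MR thresholds are set via the fraction 'B'")
    if (is.null(B)) B <- 0.95
    if (B <= 0 || B > 1) stop("'B' must lie in (0, 1]")
    if (structure$i != structure$s * (structure$s - 1) / 2)
      stop("the MR model requires the complete interaction graph")
    if (is.null(structure$d_inv))
      stop("the MR model requires a distance reciprocal for every pair")
    grid <- quantize(structure$d_inv, p)
    if (any(grid <= 0))
      stop("a distance reciprocal quantizes to 0 at this precision; increase 'p'")
    structure$d_inv <- grid
    off <- abs(table$values * 2^p - round(table$values * 2^p)) > 1e-9
    if (any(off))
      stop(sprintf("energy table entries not representable with %d fraction bits", p))
  }

  prob <- structure(list(model = model, alphabet = alphabet, table = table,
                         structure = structure, p = as.integer(p),
                         e_th = e_th, B = B,
                         g = alphabet$g, s = structure$s,
                         n = alphabet$g * structure$s),
                    class = "design_problem")
  prob$N <- 2^prob$n
  prob
}

#' @export
print.design_problem <- function(x, ...) {
  thr <- if (x$model == "MR") sprintf("B = %g (E_th = %g)", x$B, threshold_energy(x))
         else sprintf("E_th = %g", threshold_energy(x))
  cat(sprintf("<design_problem: %s model, s = %d, A = %d, n = %d (N = %d states), %s>\n",
              x$model, x$s, x$alphabet$A, x$n, x$N, thr))
  invisible(x)
}

#' Encode a residue sequence as a bitstring
#'
#' Concatenates the per-site `g`-bit canonical codes, site 1 leftmost, most
#' significant bit first. [decode_sequence()] inverts it; codes beyond the
#' alphabet (possible when A is not a power of two) decode to `NA`.
#'
#' @param seq Character vector of `s` residue labels.
#' @param problem A [design_problem()].
#' @return A bitstring of length `n = g*s`.
#' @examples
#' prob <- design_problem("SP", structure = protein_structure(2))
#' encode_sequence(c("Pos", "Neg"), prob)   # "100101"
#' @export
encode_sequence <- function(seq, problem) {
  if (length(seq) != problem$s)
    stop(sprintf("expected %d residues, got %d", problem$s, length(seq)))
  idx <- match(seq, problem$alphabet$names)
  if (anyNA(idx))
    stop(sprintf("unknown residue label(s): %s",
                 paste(unique(seq[is.na(idx)]), collapse = ", ")))
  paste(vapply(idx, function(i) residue_code(problem$alphabet, i), character(1)),
        collapse = "")
}

#' @rdname encode_sequence
#' @param bits A bitstring of length `n`.
#' @export
decode_sequence <- function(bits, problem) {
  if (nchar(bits) != problem$n) stop("bitstring length does not match n = g*s")
  g <- problem$g
  idx <- vapply(seq_len(problem$s), function(site) {
    strtoi(substr(bits, (site - 1L) * g + 1L, site * g), base = 2) + 1L
  }, integer(1))
  labels <- problem$alphabet$names[idx]
  labels[idx > problem$alphabet$A] <- NA_character_
  labels
}

# Residue indices (1-based) for every state k = 0..N-1, one column per site.
# Vectorized; indices may exceed A when the alphabet is not a power of two.
state_residue_indices <- function(problem) {
  k <- 0:(problem$N - 1)
  g <- problem$g
  sapply(seq_len(problem$s), function(site) {
    shift <- g * (problem$s - site)
    (k %/% 2^shift) %% 2^g + 1L
  })
}

# Pair energy with the "invalid code scores zero" convention.
pair_energy <- function(problem, ia, ib) {
  A <- problem$alphabet$A
  e <- numeric(length(ia))
  ok <- ia <= A & ib <= A
  e[ok] <- problem$table$values[cbind(ia[ok], ib[ok])]
  e
}

#' Total energy of a sequence
#'
#' `total_energy_sp()` is the unweighted sum of table entries over the
#' structure's interaction pairs (SP and HP models). `total_energy_mr()` weights
#' each pair by its distance reciprocal and quantizes each product to `p`
#' fraction bits (ties away from zero) before summing — exactly what the
#' in-circuit multiplier computes. `total_energy()` dispatches on the model.
#'
#' @param seq Character vector of `s` residue labels.
#' @param problem A [design_problem()].
#' @return The total energy (integer for SP/HP; on the `2^-p` grid for MR).
#' @export
total_energy <- function(seq, problem) {
  if (problem$model == "MR") total_energy_mr(seq, problem)
  else total_energy_sp(seq, problem)
}

#' @rdname total_energy
#' @export
total_energy_sp <- function(seq, problem) {
  if (!problem$model %in% c("SP", "HP"))
    stop("total_energy_sp applies to the SP and HP models")
  idx <- match(seq, problem$alphabet$names)
  if (anyNA(idx)) stop("unknown residue label")
  pr <- problem$structure$pairs
  sum(pair_energy(problem, idx[pr[, 1]], idx[pr[, 2]]))
}

#' @rdname total_energy
#' @export
total_energy_mr <- function(seq, problem) {
  if (problem$model != "MR") stop("total_energy_mr applies to the MR model")
  idx <- match(seq, problem$alphabet$names)
  if (anyNA(idx)) stop("unknown residue label")
  pr <- problem$structure$pairs
  e <- pair_energy(problem, idx[pr[, 1]], idx[pr[, 2]])
  sum(quantize(e * problem$structure$d_inv, problem$p))
}

#' Threshold energy of a design problem
#'
#' SP/HP: the explicit `e_th` if given, otherwise `e_min * i + 1` — the lowest
#' threshold that still marks the minimum-energy sequences. MR: `B * e_min *
#' sum(d_inv)`, floored onto the `2^-p` grid so the grid boundary never admits
#' extra states.
#'
#' @param problem A [design_problem()].
#' @return The threshold energy.
#' @export
threshold_energy <- function(problem) {
  if (problem$model == "MR") {
    quantize_floor(problem$B * problem$table$e_min * sum(problem$structure$d_inv),
                   problem$p)
  } else {
    if (!is.null(problem$e_th)) problem$e_th
    else problem$table$e_min * problem$structure$i + 1
  }
}

# Vector of total energies for all N states, vectorized over states.
state_energies <- function(problem) {
  idx <- state_residue_indices(problem)
  pr <- problem$structure$pairs
  e <- numeric(problem$N)
  for (r in seq_len(nrow(pr))) {
    ep <- pair_energy(problem, idx[, pr[r, 1]], idx[, pr[r, 2]])
    if (problem$model == "MR")
      ep <- quantize(ep * problem$structure$d_inv[r], problem$p)
    e <- e + ep
  }
  e
}

#' Enumerate the answer states by brute force
#'
#' Classically evaluates every one of the `N = 2^n` states and returns those
#' with total energy strictly below the threshold. This is the reference
#' semantics (`f(k) = 1`) that the quantum oracle is verified against, and the
#' source of `M` for iteration scheduling.
#'
#' @param problem A [design_problem()].
#' @param e_th Optional threshold override.
#' @param limit Refuse enumeration beyond this many states (default `2^24`).
#' @return A data frame of answer states with columns `k`, `bitstring`,
#'   `sequence` and `energy`, plus attributes `M`, `N` and `e_th`.
#' @examples
#' prob <- design_problem("SP", structure = protein_structure(2), e_th = -3)
#' enumerate_answer_states(prob)   # Pos-Neg and Neg-Pos
#' @export
enumerate_answer_states <- function(problem, e_th = NULL, limit = 2^24) {
  if (problem$N > limit)
    stop(sprintf("N = %g exceeds the brute-force limit of %g states", problem$N, limit))
  if (is.null(e_th)) e_th <- threshold_energy(problem)
  energies <- state_energies(problem)
  ans_k <- which(energies < e_th) - 1L
  g <- problem$g
  labels <- vapply(ans_k, function(k) {
    bits <- int_to_bitstring(k, problem$n)
    paste(decode_sequence(bits, problem), collapse = "-")
  }, character(1))
  out <- data.frame(
    k = ans_k,
    bitstring = vapply(ans_k, int_to_bitstring, character(1), m = problem$n),
    sequence = labels,
    energy = energies[ans_k + 1L],
    stringsAsFactors = FALSE)
  attr(out, "M") <- nrow(out)
  attr(out, "N") <- problem$N
  attr(out, "e_th") <- e_th
  out
}
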