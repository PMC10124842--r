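# Configuration files, random fixtures and result output.

resolve_path <- function(path, base_dir) {
  if (file.exists(path)) return(path)
  cand <- file.path(base_dir, path)
  if (file.exists(cand)) return(cand)
  cand <- system.file("extdata", path, package = "qgdesign")
  if (nzchar(cand) && file.exists(cand)) return(cand)
  stop(sprintf("cannot find file '%s'", path))
}

#' Parse a YAML run configuration
#'
#' Reads a run configuration (model, structure, energy-table CSV path,
#' threshold, precision, iteration count, backend, shots, seed), validates it
#' into a [design_problem()], and returns both. Table paths are resolved
#' relative to the config file or against the packaged tables; structures are
#' given inline as `sites`, a list of 1-based `interactions` pairs, and an
#' optional `d_inv` map with `"a-b"` keys.
#'
#' @param path Path to a YAML file (the packaged `sp_s2.yaml`, `sp_s3.yaml`,
#'   `mr_s2.yaml`, `mr_s3.yaml` and `hp_s2.yaml` are found by bare name).
#' @return A list with elements `problem` (a `design_problem`) and `config`
#'   (iterations, backend, shots, seed as given).
#' @export
parse_config <- function(path) {
  path <- resolve_path(path, ".")
  cfg <- yaml::read_yaml(path)
  for (field in c("model", "structure", "table"))
    if (is.null(cfg[[field]])) stop(sprintf("config is missing '%s'", field))
  st <- cfg$structure
  if (is.null(st$sites) || is.null(st$interactions))
    stop("config structure needs 'sites' and 'interactions'")
  pairs <- do.call(rbind, lapply(st$interactions, as.integer))
  d_inv <- NULL
  if (!is.null(st$d_inv)) {
    keys <- apply(pairs, 1, function(pr) paste(sort(pr), collapse = "-"))
    d_inv <- vapply(keys, function(k) {
      v <- st$d_inv[[k]]
      if (is.null(v)) stop(sprintf("missing distance reciprocal for pair %s", k))
      as.numeric(v)
    }, numeric(1))
  }
  structure_obj <- protein_structure(st$sites, pairs, d_inv = d_inv)
  table <- read_energy_table(resolve_path(cfg$table, dirname(path)))
  thr <- cfg$threshold
  problem <- design_problem(model = cfg$model, table = table,
                            structure = structure_obj, p = cfg$p,
                            e_th = thr$e_th, B = thr$B)
  config <- list(iterations = if (is.null(cfg$iterations)) "auto" else cfg$iterations,
                 backend = if (is.null(cfg$backend)) "shortcut" else cfg$backend,
                 shots = cfg$shots, seed = cfg$seed)
  if (!is.null(config$shots) && is.null(config$seed))
    stop("a 'seed' is mandatory when 'shots' are requested")
  list(problem = problem, config = config)
}

#' Generate a reproducible random design problem
#'
#' Draws a random symmetric energy table (integers for SP/HP on the given
#' range; `2^-p`-grid values for MR) and a random interaction set of size `i`,
#' forcing at least one pair to the range minimum so the instance always has a
#' well-defined low-energy answer set under the default threshold. Identical
#' seeds give identical problems; the caller's RNG state is untouched. This
#' powers the oracle-versus-brute-force property suites.
#'
#' @param s Number of designable sites.
#' @param A Alphabet size (>= 2).
#' @param i Number of interactions (defaults to all pairs; forced to all pairs
#'   for MR).
#' @param energy_range Length-2 numeric `c(min, max)` with `min < 0`.
#' @param seed Integer seed.
#' @param model `"SP"`, `"MR"` or `"HP"`-style two-letter model.
#' @param p Fraction bits (MR only).
#' @return A [design_problem()] with the default threshold.
#' @export
generate_fixture <- function(s = 2, A = 4, i = NULL, energy_range = c(-4, 1),
                             seed, model = "SP", p = 5) {
  if (A < 2) stop("'A' needs at least 2 residues")
  if (energy_range[1] >= 0) stop("the energy range must include negative values")
  max_i <- s * (s - 1) / 2
  if (is.null(i) || model == "MR") i <- max_i
  if (i > max_i) stop(sprintf("at most %d interactions are possible for s = %d", max_i, s))
  labels <- paste0("R", seq_len(A))
  with_preserved_seed(seed, {
    if (model == "MR") {
      grid <- seq(energy_range[1], energy_range[2], by = 2^-p)
      vals <- matrix(sample(grid, A * A, replace = TRUE), A, A)
    } else {
      vals <- matrix(sample(energy_range[1]:energy_range[2], A * A, replace = TRUE), A, A)
    }
    vals[lower.tri(vals)] <- t(vals)[lower.tri(vals)]
    pin <- sample(A, 2, replace = TRUE)
    vals[pin[1], pin[2]] <- energy_range[1]
    vals[pin[2], pin[1]] <- energy_range[1]
    dimnames(vals) <- list(labels, labels)
    all_pairs <- t(utils::combn(s, 2))
    pairs <- all_pairs[sample(max_i, i), , drop = FALSE]
    d_inv <- NULL
    if (model == "MR") {
      pairs <- all_pairs
      d_inv <- sample(seq_len(2^p), nrow(pairs), replace = TRUE) / 2^p
    }
    design_problem(model = if (model == "HP") "HP" else model,
                   table = energy_table(vals),
                   structure = protein_structure(s, pairs, d_inv = d_inv),
                   p = if (model == "MR") p else NULL)
  })
}

#' Write / read a Grover run result
#'
#' JSON carries the run summary and the full per-state table (sequence label,
#' bitstring, probability, marked flag); the CSV is the histogram mirror
#' (state label, probability). [read_results()] round-trips the JSON.
#'
#' @param result A `grover_result` from [run_grover()] (run with
#'   `keep_states = TRUE`).
#' @param json_path Output JSON path (NULL to skip).
#' @param csv_path Output histogram CSV path (NULL to skip).
#' @return `json_path`, invisibly.
#' @export
write_results <- function(result, json_path = NULL, csv_path = NULL) {
  if (is.null(result$per_state))
    stop("the result has no per-state table; rerun with keep_states = TRUE")
  if (!is.null(json_path)) {
    payload <- list(model = result$model, s = result$s, N = result$N,
                    M = result$M, R = result$R, E_th = result$e_th,
                    backend = result$backend,
                    success_probability = result$success_probability,
                    per_state = result$per_state[, c("sequence", "bitstring",
                                                     "probability", "marked")])
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  if (!is.null(csv_path)) {
    write.csv(result$per_state[, c("sequence", "bitstring", "probability", "marked")],
              csv_path, row.names = FALSE, quote = FALSE)
  }
  invisible(json_path)
}

#' @rdname write_results
#' @export
read_results <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  x$per_state <- as.data.frame(x$per_state)
  x
}
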