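# Grover pipeline: initialization, diffuser, oracle phases, dynamics, backends.

test_that("initialization creates the uniform superposition", {
  expect_equal(count_gates(build_initialization(1))[["H"]], 1)
  psi <- run_statevector(build_initialization(6))
  expect_equal(abs(psi)^2, rep(1 / 64, 64), tolerance = 1e-12)
  counts <- sample_counts(abs(run_statevector(build_initialization(2)))^2,
                          8192, seed = 3)
  expect_true(all(abs(counts - 2048) < 4 * sqrt(8192 * 0.25 * 0.75)))
})

test_that("the diffuser fixes the unmarked uniform state and squares to identity", {
  n <- 4
  init <- build_initialization(n)
  diff <- build_diffuser(n)
  psi0 <- run_statevector(init)
  psi1 <- run_statevector(append_circuit(init, diff))
  # fixed point of inversion about the mean, up to a global phase
  expect_equal(abs(sum(Conj(psi0) * psi1)), 1, tolerance = 1e-12)
  psi2 <- run_statevector(append_circuit(append_circuit(init, diff), diff))
  expect_equal(psi2, psi0, tolerance = 1e-12)
})

test_that("oracle phases match brute force exactly for the packaged instances", {
  r3 <- oracle_exhaustive(sp2_problem(e_th = -3))
  expect_identical(r3$marked, sort(enumerate_answer_states(sp2_problem(-3))$k))
  expect_length(r3$marked, 2)
  expect_true(r3$work_clean && r3$seq_preserved)
  expect_equal(r3$width, 15)                      # n + 2m + 1 from the budget

  r2 <- oracle_exhaustive(sp2_problem(e_th = -2))
  expect_length(r2$marked, 5)
  expect_identical(r2$marked, sort(enumerate_answer_states(sp2_problem(-2))$k))

  rhp <- oracle_exhaustive(hp2_problem())
  expect_identical(rhp$marked, 0L)                # HH = "00" is the single answer
  expect_equal(rhp$width, 7)

  rmr <- oracle_exhaustive(mr2_problem())
  expect_identical(rmr$marked, sort(enumerate_answer_states(mr2_problem())$k))
  expect_true(rmr$work_clean)
})

test_that("an all-zero table marks nothing", {
  zero <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  prob <- design_problem("SP", table = energy_table(zero),
                         structure = protein_structure(2), e_th = 0)
  r <- oracle_exhaustive(prob, fmt = fixed_point_format(2))
  expect_length(r$marked, 0)
  expect_true(r$work_clean && r$seq_preserved)
})

test_that("random fixtures keep oracle and brute force in lockstep", {
  for (seed in 1:20) {
    fx <- generate_fixture(s = 2, A = 4, i = 1, seed = seed)
    r <- oracle_exhaustive(fx)
    expect_identical(r$marked, sort(enumerate_answer_states(fx)$k))
    expect_true(r$work_clean && r$seq_preserved)
  }
  for (seed in 1:8) {
    fx <- generate_fixture(s = 2, A = 4, seed = seed, model = "MR", p = 3)
    r <- oracle_exhaustive(fx)
    expect_identical(r$marked, sort(enumerate_answer_states(fx)$k))
    expect_true(r$work_clean && r$seq_preserved)
  }
})

test_that("closed-form success probabilities match the reference values", {
  expect_equal(success_probability(64, 2, 1), 0.2583, tolerance = 1e-3)
  expect_equal(success_probability(64, 2, 4), 0.9992, tolerance = 1e-3)
  expect_equal(success_probability(16, 16, 3), 1)
  expect_equal(success_probability(4, 1, 1), 1, tolerance = 1e-12)
  expect_error(success_probability(4, 5, 1), "M cannot exceed N")
})

test_that("optimal iteration counts and their square-root scaling hold", {
  expect_equal(optimal_iterations(64, 2), 4)
  expect_equal(optimal_iterations(64, 5), 2)
  expect_equal(optimal_iterations(64, 3), 3)
  expect_equal(optimal_iterations(4, 1), 1)
  expect_error(optimal_iterations(64, 64), "smaller than N")
  expect_error(optimal_iterations(64, 0), "at least 1")
  for (N in 2^(4:20)) {
    for (M in c(1, 2, 5)) {
      if (M >= N) next
      R <- optimal_iterations(N, M)
      expect_lte(R, ceiling(pi / 4 * sqrt(N / M)))
      # R_max is the argmax among its neighbours
      expect_gte(success_probability(N, M, R),
                 success_probability(N, M, R + 1))
      if (R > 1) expect_gte(success_probability(N, M, R),
                            success_probability(N, M, R - 1))
    }
  }
})

test_that("all three backends agree state by state", {
  prob <- sp2_problem()
  for (R in c(0, 1, 4)) {
    g <- run_grover(prob, R = R, backend = "gate")
    s <- run_grover(prob, R = R, backend = "shortcut")
    a <- run_grover(prob, R = R, backend = "analytic")
    expect_equal(g$probabilities, s$probabilities, tolerance = 1e-9)
    expect_equal(s$probabilities, a$probabilities, tolerance = 1e-9)
  }
})

test_that("R = 0 leaves the uniform distribution", {
  r0 <- run_grover(sp2_problem(), R = 0, backend = "gate")
  expect_equal(r0$probabilities, rep(1 / 64, 64), tolerance = 1e-12)
})

test_that("marked and unmarked classes each share one probability", {
  res <- run_grover(sp2_problem(e_th = -2), R = 1, backend = "gate")
  pm <- res$probabilities[res$marked + 1]
  pu <- res$probabilities[-(res$marked + 1)]
  expect_lt(diff(range(pm)), 1e-12)
  expect_lt(diff(range(pu)), 1e-12)
  expect_gt(pm[1], pu[1])       # answers already more likely at R = 1
})

test_that("instances with equal (N, M) produce identical probability profiles", {
  sp <- run_grover(sp2_problem(e_th = -3), R = 4, backend = "shortcut")
  mr <- run_grover(mr2_problem(B = 0.95), R = 4, backend = "shortcut")
  expect_equal(sp$M, mr$M)
  expect_equal(sort(sp$probabilities), sort(mr$probabilities), tolerance = 1e-12)
  expect_equal(sp$success_probability, mr$success_probability, tolerance = 1e-12)
})

test_that("degenerate instances are guarded behind an explicit override", {
  empty <- sp2_problem(e_th = -4)                 # nothing below the minimum
  expect_error(run_grover(empty, R = 1), "degenerate")
  forced <- run_grover(empty, R = 1, allow_degenerate = TRUE)
  expect_equal(forced$success_probability, 0)
  expect_error(run_grover(empty, R = "auto", allow_degenerate = TRUE), "auto")
})

test_that("iteration sweeps follow sin^2((2R+1) theta) up to R_max", {
  sw <- sweep_iterations(sp2_problem(), 1:4)
  expect_equal(sw$success_probability,
               success_probability(64, 2, 1:4), tolerance = 1e-9)
  expect_equal(sw$success_probability, c(0.258, 0.602, 0.897, 0.999),
               tolerance = 1e-3)
  expect_equal(which.max(sw$success_probability), 4)   # R_max tops the sweep
  # large hairpin instance: rising curve over the first iterations
  sp6 <- design_problem("SP",
                        structure = protein_structure(6, list(c(1, 6), c(2, 5), c(3, 4))))
  sw6 <- sweep_iterations(sp6, 1:4)
  expect_true(all(diff(sw6$success_probability) > 0))
  M6 <- attr(enumerate_answer_states(sp6), "M")
  expect_equal(sw6$success_probability,
               success_probability(sp6$N, M6, 1:4), tolerance = 1e-9)
})

test_that("gate mode rejects circuits beyond the statevector cap", {
  mr <- mr2_problem()          # 81 qubits at p = 5
  expect_error(run_grover(mr, R = 1, backend = "gate"), "statevector cap")
})
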