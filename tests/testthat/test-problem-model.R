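# Classical reference semantics: encoding, energies, thresholds, answer sets.

test_that("sequence encoding uses index-order codes and round-trips", {
  prob <- sp2_problem()
  expect_identical(encode_sequence(c("H1", "H1"), prob), "000000")
  expect_identical(encode_sequence(c("Pos", "Neg"), prob), "100101")
  # bijective over all 64 two-site sequences
  for (k in 0:63) {
    bits <- paste(int_bits(k, 6), collapse = "")
    expect_identical(encode_sequence(decode_sequence(bits, prob), prob), bits)
  }
  expect_error(encode_sequence(c("Pos", "Nope"), prob), "unknown residue")
  expect_error(encode_sequence(c("Pos"), prob), "expected 2 residues")
})

test_that("alphabet derives bits-per-residue and rejects bad input", {
  expect_equal(residue_alphabet(c("H", "P"))$g, 1L)
  expect_equal(residue_alphabet(paste0("R", 1:8))$g, 3L)
  expect_equal(residue_alphabet(paste0("R", 1:5))$g, 3L)
  expect_error(residue_alphabet("H"), "at least 2")
  expect_error(residue_alphabet(c("H", "H")), "unique")
})

test_that("SP total energy sums table entries over the interaction pairs", {
  prob <- sp2_problem()
  expect_equal(total_energy_sp(c("Pos", "Neg"), prob), -4)
  expect_equal(total_energy_sp(c("X1", "X1"), prob), 0)
  expect_equal(total_energy_sp(c("H1", "H1", "H1"), sp3_problem()), -9)
  expect_error(total_energy_sp(c("H1", "H1"), mr2_problem()), "SP and HP")
  expect_error(total_energy_mr(c("H1", "H1"), prob), "MR model")
})

test_that("MR total energy weights by distance reciprocals and quantizes per pair", {
  mr <- mr2_problem()
  expect_equal(total_energy_mr(c("Pos", "Neg"), mr), -4)
  expect_equal(total_energy_mr(c("H1", "H1"), mr), -3.5)
  half <- design_problem("MR", table = default_energy_table("MR"),
                         structure = protein_structure(2, d_inv = 0.5), p = 5)
  expect_equal(total_energy_mr(c("H1", "H2"), half), -1.5)   # -3.0 * 0.5
})

test_that("total energy is symmetric under site relabeling of a pair", {
  prob <- sp2_problem()
  mr <- mr2_problem()
  for (a in prob$alphabet$names) {
    for (b in prob$alphabet$names) {
      expect_equal(total_energy(c(a, b), prob), total_energy(c(b, a), prob))
      expect_equal(total_energy(c(a, b), mr), total_energy(c(b, a), mr))
    }
  }
})

test_that("thresholds follow e_min*i + 1 (SP) and floored B*e_min*sum(d^-1) (MR)", {
  expect_equal(threshold_energy(design_problem("SP", structure = protein_structure(2))), -3)
  expect_equal(threshold_energy(design_problem("SP", structure = protein_structure(3))), -11)
  expect_equal(threshold_energy(sp2_problem(e_th = -2)), -2)
  # -3.8 floors to -3.8125 on the 1/32 grid
  expect_equal(threshold_energy(mr2_problem(B = 0.95)), -3.8125)
  expect_error(design_problem("MR", table = default_energy_table("MR"),
                              structure = protein_structure(2, d_inv = 1.0),
                              B = 1.2), "in \\(0, 1\\]")
  expect_error(sp2_problem(e_th = -2.5), "integer")
})

test_that("brute-force answer sets reproduce the two-site reference counts", {
  ans3 <- enumerate_answer_states(sp2_problem(e_th = -3))
  expect_equal(attr(ans3, "M"), 2L)
  expect_setequal(ans3$sequence, c("Pos-Neg", "Neg-Pos"))
  ans2 <- enumerate_answer_states(sp2_problem(e_th = -2))
  expect_equal(attr(ans2, "M"), 5L)
  # lowering the threshold never adds states
  expect_true(all(ans3$k %in% ans2$k))
  # nothing lies strictly below the attainable minimum
  empty <- enumerate_answer_states(sp2_problem(e_th = -4))
  expect_equal(attr(empty, "M"), 0L)
  expect_error(enumerate_answer_states(sp2_problem(), limit = 32), "brute-force limit")
})

test_that("MR answer counts track the threshold fraction B", {
  counts <- vapply(c(0.95, 0.85, 0.70),
                   function(B) attr(enumerate_answer_states(mr2_problem(B = B)), "M"),
                   integer(1))
  expect_equal(counts, c(2L, 3L, 5L))
})

test_that("MR with unit distances and an integer table collapses onto SP", {
  sp_tab <- default_energy_table("SP")
  for (s in 2:3) {
    sp <- design_problem("SP", table = sp_tab, structure = protein_structure(s))
    mr <- design_problem("MR", table = sp_tab,
                         structure = protein_structure(s, d_inv = rep(1, s * (s - 1) / 2)),
                         p = 5)
    for (e_th in c(-3, -2, -8)) {
      expect_identical(enumerate_answer_states(sp, e_th = e_th)$k,
                       enumerate_answer_states(mr, e_th = e_th)$k)
    }
  }
})

test_that("the packaged SP table satisfies its constraint suite", {
  tab <- default_energy_table("SP")
  expect_equal(tab$e_min, -4)
  expect_equal(tab$e_max, 1)
  expect_equal(sum(tab$values == -4), 2)         # unique unordered minimum
  expect_equal(sum(tab$values == -3), 3)         # exactly 3 ordered pairs at -3
  hp <- default_energy_table("HP")
  expect_equal(hp$e_min, -2)
  expect_equal(sum(hp$values != 0), 1)
})

test_that("quantize rounds to the grid with ties away from zero, idempotently", {
  expect_equal(quantize(0.03125, 5), 0.03125)
  expect_equal(quantize(0, 11), 0)
  expect_equal(quantize(0.01, 5), 0)
  expect_equal(quantize(0.015625, 5), 0.03125)     # exact half, away from zero
  expect_equal(quantize(-0.015625, 5), -0.03125)
  xs <- seq(-4, 4, by = 0.013)
  expect_equal(quantize(quantize(xs, 5), 5), quantize(xs, 5))
})

test_that("problem validation enforces the model contracts", {
  expect_error(design_problem("SP", structure = protein_structure(2, d_inv = 1.0)),
               "not part of the SP/HP")
  expect_error(design_problem("MR", table = default_energy_table("MR"),
                              structure = protein_structure(3, list(c(1, 2), c(2, 3)),
                                                            d_inv = c(1, 1))),
               "complete interaction graph")
  asym <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(energy_table(asym), "symmetric")
  off <- matrix(c(-0.01, 0, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(design_problem("MR", table = energy_table(off),
                              structure = protein_structure(2, d_inv = 1.0), p = 5),
               "not representable")
})
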