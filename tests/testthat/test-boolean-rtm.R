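test_that("transmembrane direction classifies the ratio with tolerance", {
  expect_equal(tmt_direction(0.5), "IN")
  expect_equal(tmt_direction(1.0), "EQ")
  expect_equal(tmt_direction(1.2), "EX")
  expect_equal(tmt_direction(c(0, 0.999999999, 1.000000001, 3)),
               c("IN", "EQ", "EQ", "EX"))
  expect_equal(tmt_direction(0.98, tol = 0.05), "EQ")
  expect_error(tmt_direction(-0.1), "non-negative")
  # scale invariance: multiplying C1 and C2 by a common factor is a no-op
  c1 <- c(2, 5, 0.3); c2 <- c(1, 7, 0.3)
  for (s in c(1e-6, 1, 1e4))
    expect_equal(tmt_direction(s * c2 / (s * c1)), tmt_direction(c2 / c1))
})

test_that("scenario classification follows the tie and saturation rules", {
  g <- make_fixture("uniform")$snapshots[[1]]$grid
  mk <- function(t, C1, C2, C3)
    concentration_state(t, g, matrix(C1, g$n_r, g$n_z),
                        matrix(C2, g$n_r, g$n_z), matrix(C3, g$n_r, g$n_z),
                        rep(C1, g$n_z), g$r_v)
  # toy arithmetic: C1 1->2, C2 0.5->1.5, C3 0.2->0.4
  sc <- scenario_from_states(mk(0, 1, 0.5, 0.2), mk(1800, 2, 1.5, 0.4))
  expect_true(all(sc$trend_C2C1 == "I"))   # 0.5 -> 0.75
  expect_true(all(sc$trend_C3C1 == "I"))   # 0.2 -> 0.2 (tie)
  expect_true(all(sc$trend_C3C2 == "D"))   # 0.4 -> 0.267
  expect_true(all(sc$reaction == "AS"))
  expect_true(all(sc$tmt == "IN"))         # later ratio 0.75
  # identical states: every trend is a tie, classified I
  sc2 <- scenario_from_states(mk(0, 1, 0.5, 0.2), mk(1800, 1, 0.5, 0.2))
  expect_true(all(sc2$trend_C2C1 == "I" & sc2$trend_C3C1 == "I" &
                    sc2$trend_C3C2 == "I" & sc2$trend_C3 == "I"))
  expect_true(all(sc2$reaction == "AS"))
  # saturation: C3 pinned at C0 in both states suppresses the AS reading
  sc3 <- scenario_from_states(mk(0, 1, 0.5, 5), mk(1800, 2, 1.5, 5), C0 = 5)
  expect_true(all(sc3$saturated))
  expect_false(any(scenario_from_states(mk(0, 1, 0.5, 0.2),
                                        mk(1800, 2, 1.5, 0.4),
                                        C0 = 5)$saturated))
  expect_error(scenario_from_states(mk(1800, 1, 1, 1), mk(0, 1, 1, 1)),
               "later")
})

test_that("printed scenario-cell conclusions are returned by the engine", {
  cell <- function(t21, t31, t32, reac, tmt, tc1 = NA)
    infer_mechanisms(list(trend_C2C1 = t21, trend_C3C1 = t31,
                          trend_C3C2 = t32, reaction = reac, tmt = tmt,
                          trend_C1 = tc1))
  expect_equal(cell("I", "I", "D", "AS", "IN")$label, "IN_GE_AS")
  expect_equal(cell("I", "I", "D", "DIS", "IN")$label, "IN_GE_ECTp")
  expect_equal(cell("I", "I", "I", "DIS", "IN")$label, "CONTRADICTION")
  expect_equal(cell("D", "D", "D", "AS", "IN")$label,
               "IN_GE_AS_and_IN_LE_ECTp")
  # C1-trend refinement: rising C1 resolves the first row's disjunction
  expect_equal(cell("I", "I", "I", "AS", "IN", "I")$label, "IN_GE_AS")
  expect_true(cell("I", "I", "I", "AS", "IN", "I")$refined)
  # falling C1 resolves the biconditional cells
  expect_equal(cell("I", "D", "I", "AS", "IN", "D")$label, "IN_LE_AS")
  expect_equal(cell("I", "D", "I", "DIS", "EX", "I")$label, "EX_LE_DIS")
  # reaction can be read off the C3 trend
  expect_equal(infer_mechanisms(list(trend_C2C1 = "I", trend_C3C1 = "I",
                                     trend_C3C2 = "D", trend_C3 = "I",
                                     tmt = "IN"))$label, "IN_GE_AS")
})

test_that("truth-table verifier certifies and refutes derivations", {
  # a biconditional tautology holds under any premises
  expect_true(verify_by_truth_table(c("P14", "!P7"), "iff(P9, P9)")$valid)
  # the transposed sufficiency chain
  expect_true(verify_by_truth_table(
    character(0), "implies(!P16, !P12 | xor(P8, P9))")$valid)
  # the printed end-to-end chain: rising ratios, falling C3/C2,
  # dissociation, inward direction => internalization beats ECT+
  res <- verify_by_truth_table(c("P14", "P15", "!P16", "!P12", "!P10"), "!P11")
  expect_true(res$valid)
  expect_gt(res$n_premise_models, 0)
  # an invalid claim yields a counterexample assignment
  bad <- verify_by_truth_table("P14", "P6")
  expect_false(bad$valid)
  expect_false(bad$counterexample[["P6"]])
  expect_true(bad$counterexample[["P14"]])
  # malformed input is rejected
  expect_error(verify_by_truth_table(character(0), "P8 +"), "")
})

test_that("axiom set encodes the exclusivity structure", {
  M <- ectcord:::axiom_models()
  expect_false(any(M$P12 & M$P13))
  expect_true(all(rowSums(M[c("P1", "P2", "P3")]) == 1))
  expect_false(any(M$P4 & M$P12))
  expect_true(all(xor(M$P8, M$P9) == M$P6))
})
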