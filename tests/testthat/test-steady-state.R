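test_that("tumor-free closed form reproduces the published fixed point", {
  ss <- base_steady_state(table3$params)
  expect_equal(round(ss$x1bar, 4), 1.1586)
  expect_equal(round(ss$x2bar, 4), 231.7238)
  # unit ratios give a unit fixed point for any exponents with gamma != 0
  p1 <- remodeling_params(2, 3, 2, 3, 0.9, -0.7, 1.2, 0.1, 0.1, 0.001)
  ss1 <- base_steady_state(p1)
  expect_equal(c(ss1$x1bar, ss1$x2bar), c(1, 1))
  # gamma = 0 is an error at steady-state time
  pg0 <- remodeling_params(3, 4, 0.2, 0.02, 1.5, -0.5, 1, 0, 0.093, 0.0008)
  expect_error(base_steady_state(pg0), "determinant is zero")
})

test_that("model-1 steady states match the published (1-sigma)-power table", {
  p <- table3$params
  g <- gamma_coupling(p)
  b <- base_steady_state(p)
  # published per-scenario exponents of the (1 - sigma) factor
  h_exponents <- list(
    `0` = c(0, 0), `1` = c(0, 0), `2` = c(0, 0),
    `3` = 2 * c(1 - p$g22 - p$g21, -1 + p$g11 + p$g12) / g,
    `4` = 2 * c(-1 + p$g22 + p$g21, 1 - p$g11 - p$g12) / g,
    `5` = c(1 - p$g22, p$g12) / g,
    `6` = c(1 - p$g22, p$g12) / g,
    `7` = c(p$g21, 1 - p$g11) / g,
    `8` = c(p$g21, 1 - p$g11) / g)
  for (scn in 0:8) for (sig in c(0.05, 0.10, 0.20, 0.40, 0.80, 0.99)) {
    ss <- model1_steady_state(p, sig, scn)
    h <- h_exponents[[as.character(scn)]]
    expect_equal(ss$x1bar, b$x1bar * (1 - sig)^h[1], tolerance = 1e-12)
    expect_equal(ss$x2bar, b$x2bar * (1 - sig)^h[2], tolerance = 1e-12)
  }
})

test_that("scenarios with cancelling modulation keep the tumor-free fixed point", {
  p <- table3$params
  b <- base_steady_state(p)
  for (scn in c(1, 2)) for (sig in c(0.05, 0.4, 0.99)) {
    ss <- model1_steady_state(p, sig, scn)
    expect_equal(c(ss$x1bar, ss$x2bar), c(b$x1bar, b$x2bar))
  }
})

test_that("model-1 steady states are continuous in sigma toward the base point", {
  p <- table3$params
  b <- base_steady_state(p)
  for (scn in 0:8) {
    ss <- model1_steady_state(p, 1e-9, scn)
    expect_equal(ss$x1bar, b$x1bar, tolerance = 1e-6)
    expect_equal(ss$x2bar, b$x2bar, tolerance = 1e-6)
  }
})

test_that("model-2 closed forms: published values vs the ODE fixed point", {
  p <- table3$params
  # neutral coupling reduces to the base point in both readings
  for (consistent in c(FALSE, TRUE)) {
    ss0 <- model2_steady_state(p, 0.3, 0, 0, consistent = consistent)
    expect_equal(round(c(ss0$x1bar, ss0$x2bar), 10),
                 round(c(1.1586192, 231.7238045), 10), tolerance = 1e-6)
  }
  # the published closed form reproduces the published worked examples ...
  ss <- model2_steady_state(p, 0.05, -0.10, 0)
  expect_equal(round(c(ss$x1bar, ss$x2bar), 4), c(0.5479, 490.0362))
  # ... but is not a fixed point of the model-2 ODE (documented sign
  # inconsistency in the published osteoclast exponent)
  spec <- model_spec("model2", g31 = -0.10, g32 = 0)
  tum <- tumor_params(sigma = 0.05)
  expect_gt(steady_state_residual(ss, spec, table3$params, tum), 0.01)
  # the consistent form is: residual at machine precision, oracle-confirmed
  ssc <- model2_steady_state(p, 0.05, -0.10, 0, consistent = TRUE)
  expect_lt(steady_state_residual(ssc, spec, p, tum), 1e-12)
  orc <- steady_state_oracle(spec, p, tum, guess = c(1, 200))
  expect_equal(orc$x1bar, ssc$x1bar, tolerance = 1e-8)
  expect_equal(orc$x2bar, ssc$x2bar, tolerance = 1e-8)
  # the two readings share x2bar when g32 = 0
  expect_equal(ss$x2bar, ssc$x2bar)
})

test_that("model-3 closed form is the fixed point of the modified exponents", {
  p3 <- remodeling_params(3, 4, 0.2, 0.02, 0.005, 0, 0, 0.2, 0.093, 0.0008)
  tum <- tumor_params(sigma = 0.05)
  for (r in list(c(0.3, -0.2, 0.1, 0.25), c(-0.1, 0.4, -0.3, -0.05))) {
    spec <- model_spec("model3", r11 = r[1], r12 = r[2],
                       r21 = r[3], r22 = r[4])
    ss <- model3_steady_state(p3, 0.05, r[1], r[2], r[3], r[4])
    expect_lt(steady_state_residual(ss, spec, p3, tum), 1e-8)
  }
  # all modifiers zero: Lambda = gamma, base point recovered
  ss0 <- model3_steady_state(table3$params, 0.2, 0, 0, 0, 0)
  b <- base_steady_state(table3$params)
  expect_equal(c(ss0$x1bar, ss0$x2bar), c(b$x1bar, b$x2bar))
})

test_that("root-finding oracle certifies the closed forms", {
  p <- table3$params
  orc <- steady_state_oracle(model_spec("base"), p, guess = c(1, 200))
  expect_equal(round(c(orc$x1bar, orc$x2bar), 4), c(1.1586, 231.7238))
  # published scenario-3 value at sigma = 0.40, recovered by root finding
  orc3 <- steady_state_oracle(model_spec("model1", scenario = 3), p,
                              tumor_params(sigma = 0.40), guess = c(50, 3800))
  expect_lt(abs(orc3$x1bar - 53.4325), 1e-4)
  expect_lt(abs(orc3$x2bar - 3847.1469), 1e-4)
  # the oracle stays in the positive orthant, away from the trivial point
  expect_gt(orc$x1bar, 0)
  expect_gt(orc$x2bar, 0)
})

test_that("every closed form satisfies its own RHS at D = sigma (randomized)", {
  sets <- fixture_params(seed = 202, n = 25)
  for (set in sets) {
    for (variant in c("base", "model1", "model2", "model3")) {
      spec <- variant_spec(set, variant)
      ss <- steady_state(spec, set$params, set$tumor,
                         consistent = (variant == "model2"))
      expect_lt(steady_state_residual(ss, spec, set$params, set$tumor), 1e-8)
      if (variant != "base") expect_equal(ss$Dbar, set$tumor$sigma)
    }
  }
})
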