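test_that("characteristic invariants match known factorizations", {
  # (lambda+1)(lambda+2)(lambda+3) = lambda^3 + 6 lambda^2 + 11 lambda + 6
  expect_equal(unname(characteristic_invariants(diag(c(-1, -2, -3)))),
               c(6, 11, 6))
  # block-triangular tumor row: a3 = -J33 * det(cell block)
  J <- matrix(c(0.02, -1e-4, 0.3,
                4e-3, -0.02, -0.1,
                0, 0, -0.005 / log(10)), 3, byrow = TRUE)
  a <- characteristic_invariants(J)
  expect_equal(unname(a["a3"]),
               -J[3, 3] * (J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]))
  # eigenvalues reconstructed from the invariants agree with eigen()
  roots <- polyroot(c(a["a3"], a["a2"], a["a1"], 1))
  ev <- eigen(J, only.values = TRUE)$values
  expect_equal(sort(Re(roots)), sort(Re(ev)), tolerance = 1e-8)
})

test_that("Routh-Hurwitz verdict equals the eigenvalue sign test", {
  expect_true(routh_hurwitz(6, 11, 6))
  expect_false(routh_hurwitz(1, 1, 2))            # a1*a2 - a3 = -1
  expect_true(routh_hurwitz(c(6, 11, 6)))         # vector form
  set.seed(7)
  for (i in 1:500) {
    J <- matrix(stats::rnorm(9, sd = 0.5), 3, 3)
    ev <- eigen(J, only.values = TRUE)$values
    expect_identical(routh_hurwitz(characteristic_invariants(J)),
                     max(Re(ev)) < 0)
  }
})

test_that("the tumor row gives an exact -mu/ln(10) eigenvalue", {
  p <- table3$params
  tum <- tumor_params(sigma = 0.2)
  for (spec in list(model_spec("base"),
                    model_spec("model1", scenario = 3),
                    model_spec("model2", g31 = -0.1, g32 = 0.05),
                    model_spec("model3", r11 = 0.2, r12 = 0.1,
                               r21 = -0.1, r22 = 0.05))) {
    J <- jacobian_at_steady(spec, p, tum)
    expect_identical(unname(J[3, 1:2]), c(0, 0))
    expect_identical(unname(J[3, 3]), -tum$mu / log(10))
    ev <- eigen(J, only.values = TRUE)$values
    expect_true(any(abs(ev - (-tum$mu / log(10))) < 1e-15))
  }
})

test_that("physiological model sits on a center: zero-trace cell block", {
  sr <- stability_report(model_spec("base"), table3$params,
                         tumor_params(sigma = 0.05))
  J <- sr$jacobian
  expect_lt(abs(J[1, 1] + J[2, 2]), 1e-9)
  expect_identical(sr$eig_class, "center_like")
  expect_false(sr$routh_hurwitz_stable)
  expect_gt(max(abs(Im(sr$eigenvalues))), 0.01)   # oscillatory pair
})

test_that("eigenvalue taxonomy follows its explicit rules", {
  expect_identical(classify_eigenvalues(c(-1, -2, -3)), "stable_node")
  expect_identical(classify_eigenvalues(c(-1 + 2i, -1 - 2i, -3)),
                   "stable_spiral")
  expect_identical(classify_eigenvalues(c(2i, -2i, -3)), "center_like")
  expect_identical(classify_eigenvalues(c(0.1, -2, -3)), "unstable")
  # boundary ties resolve to the marginal class
  expect_identical(classify_eigenvalues(c(1e-12, -2, -3), tol = 1e-9),
                   "center_like")
})

test_that("analytic Jacobians agree with central finite differences", {
  sets <- fixture_params(seed = 303, n = 20)
  for (set in sets) {
    for (variant in c("model1", "model2", "model3")) {
      spec <- variant_spec(set, variant)
      ss <- steady_state(spec, set$params, set$tumor,
                         consistent = (variant == "model2"))
      J <- jacobian_at_steady(spec, set$params, set$tumor, steady = ss)
      fd <- fd_jacobian(variant_rhs(set, variant),
                        c(ss$x1bar, ss$x2bar, set$tumor$sigma))
      expect_lt(max_jacobian_err(J, fd, set, ss), 1e-6)
    }
  }
})

test_that("model-1 scenario stability reproduces the published pattern", {
  p <- table3$params
  for (sig in c(0.05, 0.10, 0.20, 0.40)) {
    for (scn in c(2, 3, 6)) {
      sr <- stability_report(model_spec("model1", scenario = scn), p,
                             tumor_params(sigma = sig))
      expect_true(sr$routh_hurwitz_stable,
                  label = sprintf("scenario %d, sigma %.2f stable", scn, sig))
      expect_true(sr$eig_class %in% c("stable_spiral", "stable_node"))
    }
  }
  for (sig in c(0.05, 0.10, 0.20, 0.40, 0.80, 0.99)) {
    for (scn in c(1, 4)) {
      sr <- stability_report(model_spec("model1", scenario = scn), p,
                             tumor_params(sigma = sig))
      expect_identical(sr$eig_class, "unstable")
      expect_false(sr$routh_hurwitz_stable)
    }
  }
})

test_that("region scan is complete and decoupled rows match the base class", {
  p <- table3$params
  grid <- stability_region_scan(p, "model2", sigma = c(0.05, 0.2),
                                g31 = c(-0.1, 0, 0.1), g32 = c(-0.05, 0))
  expect_equal(nrow(grid), 3 * 2 * 2)
  expect_false(any(is.na(grid$class)))
  # g31 = g32 = 0 decouples: same class as the base model at every sigma
  base_class <- stability_report(model_spec("base"), p,
                                 tumor_params(sigma = 0.05),
                                 tol = 1e-6)$eig_class
  sub <- grid[grid$g31 == 0 & grid$g32 == 0, ]
  expect_true(all(sub$class == base_class))
  # the published damped-oscillation example point
  pt <- grid[grid$g31 == -0.1 & grid$g32 == 0 & grid$sigma == 0.05, ]
  expect_identical(pt$class, "stable_spiral")
  # undefined steady states are recorded, not dropped
  pg0 <- remodeling_params(3, 4, 0.2, 0.02, 1.5, -0.5, 1, 0, 0.093, 0.0008)
  g0 <- stability_region_scan(pg0, "model2", sigma = 0.05, g31 = 0, g32 = 0)
  expect_identical(g0$class, "undefined")
})
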