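test_that("energy densities vanish at rest and match independent evaluations", {
  expect_equal(w_iso(1, liver), 0)
  expect_equal(w_aniso(1, liver), 0)
  expect_equal(w_total(1, liver), 0)
  # long-hand re-evaluation of the non-Gaussian energy (independent code path)
  for (lam in c(1.1, 1.2, 1.3))
    expect_equal(w_iso(lam, liver),
                 w_iso_reference(lam, liver$mu, liver$N), tolerance = 1e-12)
  # anisotropic energy at lam = 1.3 against hand arithmetic with I1 = 1.69 + 2/1.3
  I1 <- 1.69 + 2 / 1.3
  expect_equal(I1, 3.228462, tolerance = 1e-6)
  expect_equal(w_aniso(1.3, liver),
               liver$A1 / 3 * (I1 - 3) + liver$A2 / 9 * (I1 - 3)^2,
               tolerance = 1e-12)
  # monotone increasing in tension
  lam <- seq(1, 1.3, by = 1e-3)
  expect_true(all(diff(w_total(lam, liver)) > 0))
})

test_that("mixture rule degenerates correctly and combines component-wise", {
  lam <- c(1.05, 1.2, 1.3)
  p0 <- material_params(mu = liver$mu, N = liver$N, b = liver$b,
                        A1 = liver$A1, A2 = liver$A2, C = liver$C, f = 0)
  p1 <- material_params(mu = liver$mu, N = liver$N, b = liver$b,
                        A1 = liver$A1, A2 = liver$A2, C = liver$C, f = 1)
  expect_equal(w_total(lam, p0), w_iso(lam, p0))
  expect_equal(w_total(lam, p1), w_aniso(lam, p1))
  expect_equal(w_total(lam, liver),
               (1 - liver$f) * w_iso(lam, liver) +
                 liver$f * w_aniso(lam, liver))
})

test_that("quadratic term dominates the anisotropic energy at larger strain", {
  lam <- seq(1.2, 1.3, by = 0.005)
  x <- log(lam^2 + 2 / lam - 3)
  y <- log(w_aniso(lam, liver))
  slope <- stats::coef(stats::lm(y ~ x))[2]
  expect_equal(unname(slope), 2, tolerance = 0.05)
})

test_that("isotropic energy derivative matches its closed form", {
  h <- 1e-6
  fd <- (w_iso(1.1 + h, liver) - w_iso(1.1 - h, liver)) / (2 * h)
  analytic <- response_fn(1.1, liver) * (1.1 - 1.1^-2)
  expect_equal(analytic, fd, tolerance = 1e-6)
})

test_that("closed-form virgin stress agrees with the energy-derivative oracle", {
  lam <- seq(1.01, 1.29, by = 1e-3)
  sig <- virgin_stress(lam, liver)$sigma
  orc <- numeric_stress_oracle(lam, liver)
  expect_lt(max(rel_err(sig, orc)), 1e-3)
  # and the agreement is far tighter than the contract (exact derivative)
  expect_lt(max(rel_err(sig, orc)), 1e-5)
  expect_equal(virgin_stress(1, liver)$sigma, 0)
  expect_true(all(diff(sig) > 0))
  expect_error(virgin_stress(0.9, liver), "lam")
})

test_that("response function is finite at rest and stiffens toward lock", {
  expect_gt(response_fn(1 + 1e-9, liver), 0)
  lam <- seq(1.25, 1.45, by = 0.005)  # approaching lock stretch ~1.5045
  expect_true(all(diff(response_fn(lam, liver)) > 0))
  expect_error(response_fn(1.51, liver), "lock")
})

test_that("with f = 0 the stress reduces to the pure non-Gaussian law", {
  p0 <- material_params(mu = 0.4, N = 2, b = 0, A1 = 1, A2 = 1, C = 0, f = 0)
  lam <- c(1.1, 1.3, 1.5)
  expect_equal(virgin_stress(lam, p0)$sigma,
               response_fn(lam, p0) * (lam - lam^-2), tolerance = 1e-14)
})

test_that("softening variables follow the radical form and its domain", {
  sv <- softening_variables(1, 1.3)
  expect_equal(sv$m, sqrt(3))
  expect_equal(sv$m, 1.732051, tolerance = 1e-6)
  sv2 <- softening_variables(1.3, 1.3)
  expect_identical(sv2$m, sv2$M)
  lam <- seq(1, 1.3, by = 1e-3)
  expect_true(all(diff(softening_variables(lam, 1.3)$m) > 0))
  expect_error(softening_variables(1.31, 1.3), "exceeds")
})

test_that("softening factor is 1 at reversal and monotone below it", {
  sv <- softening_variables(1.3, 1.3)
  expect_identical(softening_factor(sv$m, sv$M, liver$b), 1)
  M <- softening_variables(1.3, 1.3)$M
  m <- softening_variables(seq(1, 1.3, by = 1e-2), 1.3)$m
  fac <- softening_factor(m, M, 3.3389)
  expect_true(all(diff(fac) > 0))
  expect_true(all(fac <= 1))
  # b = 0 leaves only the sqrt(m/M) part
  expect_equal(softening_factor(m, M, 0), sqrt(m / M))
  expect_error(softening_factor(2.1, 2.0, 1), "exceeds")
})

test_that("residual-strain terms are partial derivatives of the set function", {
  phi_term <- function(x, lmax, n) (lmax^n - x^2)^2
  for (case in list(list(x = 1.1, lmax = 1.3, n = 1),
                    list(x = 1.3^-0.45, lmax = 1.3^-0.5, n = 1),
                    list(x = 1.2, lmax = 1.3, n = 2))) {
    h <- 1e-6
    fd <- (phi_term(case$x + h, case$lmax, case$n) -
             phi_term(case$x - h, case$lmax, case$n)) / (2 * h)
    expect_equal(-4 * case$x * (case$lmax^case$n - case$x^2), fd,
                 tolerance = 1e-6)
  }
  # axial factor root at lam = sqrt(lam_max) for n = 1
  g <- residual_g(sqrt(1.3), 1.3, n = 1)
  expect_equal(g$g1, 0, tolerance = 1e-12)
  # n = 2 at lam = lam_max: every component vanishes
  g2 <- residual_g(1.3, 1.3, n = 2)
  expect_equal(abs(c(g2$g1, g2$g2, g2$g3)), c(0, 0, 0), tolerance = 1e-12)
})

test_that("softened branch collapses onto the virgin curve when inert", {
  inert <- material_params(mu = liver$mu, N = liver$N, b = 0, A1 = liver$A1,
                           A2 = liver$A2, C = 0, f = liver$f)
  # at the reversal point the factor is exactly 1 and the C-term absent
  expect_equal(softened_stress(1.3, 1.3, inert)$sigma,
               virgin_stress(1.3, inert)$sigma, tolerance = 1e-14)
})

test_that("softened stress shows residual strain and is dominated below reversal", {
  lam_res <- residual_stretch(1.3, liver)
  expect_gt(lam_res, 1)
  expect_lt(lam_res, 1.3)
  expect_lt(abs(softened_stress(lam_res, 1.3, liver)$sigma), 1e-9)
  # below the residual stretch the stress is compressive (material is slack)
  expect_lt(softened_stress(1.01, 1.3, liver)$sigma, 0)
  # dominance on the branch interior
  grid <- seq(1, 1.3 - 1e-3, by = 1e-3)
  expect_true(all(softened_stress(grid, 1.3, liver)$sigma <=
                    virgin_stress(grid, liver)$sigma + 1e-9))
  # at the reversal point itself the residual-strain term leaves a known
  # stress step above the virgin curve (the model as written is not
  # continuous there for n = 1); its value is the C-term divided by lam
  g <- residual_g(1.3, 1.3, n = 1)
  gap_analytic <- liver$mu * (1 / 1.3) * liver$C *
    (1.3 * g$g1 - 1.3^-0.5 * g$g2) / 1.3
  expect_equal(reversal_stress_gap(1.3, liver), gap_analytic,
               tolerance = 1e-12)
  expect_gt(reversal_stress_gap(1.3, liver), 0)
  expect_lt(reversal_stress_gap(1.3, liver) /
              virgin_stress(1.3, liver)$sigma, 0.02)
  expect_error(softened_stress(1.31, 1.3, liver), "lam_max")
})

test_that("finite-difference oracle is second order and guards its domain", {
  expect_error(numeric_stress_oracle(1 + 1e-5, liver), "1 \\+ h")
  ref <- numeric_stress_oracle(1.15, liver, h = 1e-7)
  e1 <- abs(numeric_stress_oracle(1.15, liver, h = 1e-3) - ref)
  e2 <- abs(numeric_stress_oracle(1.15, liver, h = 2e-3) - ref)
  expect_equal(e2 / e1, 4, tolerance = 0.2)
})

test_that("small-strain modulus approaches the Gaussian-chain limit for large N", {
  modulus <- function(N) {
    p <- material_params(mu = 0.5, N = N, b = 0, A1 = 0, A2 = 0, C = 0, f = 0)
    virgin_stress(1.001, p)$sigma / 0.001
  }
  m <- vapply(c(25, 100, 400), modulus, 0)
  # successive quadruplings converge (Cauchy differences shrink ~ 1/N)
  expect_lt(abs(m[3] - m[2]), 0.4 * abs(m[2] - m[1]))
  expect_lt(abs(m[3] - m[2]) / m[3], 0.02)
})
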