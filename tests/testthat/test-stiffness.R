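nu_ref <- 3.569e-5

test_that("virgin table satisfies the energy-equivalence identity at every node", {
  tab <- build_virgin_table(liver, nu_ref, lam_max = 1.3)
  w_back <- spring_energy(tab$ks_values, tab$lam_grid, nu_ref)
  w_direct <- w_total(tab$lam_grid, liver)
  expect_lt(max(rel_err(w_back, w_direct)), 1e-10)
  # grid is strictly increasing, stiffness finite and non-negative
  expect_true(all(diff(tab$lam_grid) > 0))
  expect_true(all(is.finite(tab$ks_values) & tab$ks_values >= 0))
  # near lam = 1 the removable singularity resolves to ks -> 0
  expect_lt(tab$ks_values[1], 1e-6)
  # continuity: adjacent-node jumps stay a small fraction of the table scale
  expect_lt(max(abs(diff(tab$ks_values))), 0.02 * max(tab$ks_values))
  # reference value at lam = 1.3 from the constitutive oracle
  expect_equal(tail(tab$ks_values, 1),
               2 * nu_ref * w_total(1.3, liver) * 1000 / (1.69 - 1.3),
               tolerance = 1e-12)
  # linearity in nu_ij
  tab2 <- build_virgin_table(liver, 2 * nu_ref, lam_max = 1.3)
  expect_equal(tab2$ks_values, 2 * tab$ks_values, tolerance = 1e-14)
})

test_that("table grid refuses the chain lock limit", {
  expect_error(build_virgin_table(liver, nu_ref, lam_max = 1.55), "lock")
})

test_that("unloading table integrates the softened stress and is dominated", {
  vt <- build_virgin_table(liver, nu_ref, lam_max = 1.3)
  ut <- build_unloading_table(liver, nu_ref, lam_max = 1.3)
  expect_identical(ut$branch, "unloading")
  expect_gt(ut$lam_res, 1)
  # zero stored energy (and stiffness) at and below the residual stretch
  expect_equal(softened_energy(c(1, ut$lam_res), 1.3, liver), c(0, 0))
  below <- ut$lam_grid <= ut$lam_res
  expect_true(all(ut$ks_values[below] == 0))
  # dominance by the virgin table on the common grid
  expect_true(all(ut$ks_values <= vt$ks_values + 1e-12))
  # energy identity holds for the softened branch too
  expect_lt(max(rel_err(spring_energy(ut$ks_values, ut$lam_grid, nu_ref)
                        [ut$lam_grid > ut$lam_res + 0.01],
                        ut$w_values[ut$lam_grid > ut$lam_res + 0.01])), 1e-10)
})

test_that("trapezoid softened energy agrees with adaptive quadrature", {
  lam_res <- residual_stretch(1.3, liver)
  for (lam in c(1.1, 1.2, 1.3)) {
    quad <- stats::integrate(function(l) softened_stress(l, 1.3, liver)$sigma,
                             lam_res, lam, rel.tol = 1e-10)$value
    expect_equal(softened_energy(lam, 1.3, liver), quad, tolerance = 1e-5)
  }
})

test_that("table interpolation is exact at nodes and linear between them", {
  tab <- build_virgin_table(liver, nu_ref, lam_max = 1.3)
  i <- c(5L, 120L, 250L)
  expect_identical(stiffness_at(tab, tab$lam_grid[i]), tab$ks_values[i])
  mid <- (tab$lam_grid[10] + tab$lam_grid[11]) / 2
  expect_equal(stiffness_at(tab, mid),
               (tab$ks_values[10] + tab$ks_values[11]) / 2)
  # out-of-range policy
  expect_error(stiffness_at(tab, 1.31), "beyond")
  expect_warning(stiffness_at(tab, 1 + 1e-8), "first grid node")
  expect_silent(stiffness_at(tab, 1 + 1e-8, warn = FALSE))
  expect_error(stiffness_at(tab, 0.99), "below 1")
})

test_that("grid refinement changes interpolated stiffness by less than 1%", {
  coarse <- build_virgin_table(liver, nu_ref, lam_max = 1.3, dl = 1e-3)
  fine <- build_virgin_table(liver, nu_ref, lam_max = 1.3, dl = 5e-4)
  probe <- seq(1.01, 1.299, by = 7e-4)
  expect_lt(max(rel_err(stiffness_at(coarse, probe),
                        stiffness_at(fine, probe))), 0.01)
})

test_that("axis stiffness triple reduces to one lookup for shared tables", {
  tab <- build_virgin_table(liver, nu_ref, lam_max = 1.3)
  ks <- axis_stiffness(tab, lam = 1.2)
  expect_identical(ks$ksx, ks$ksy)
  expect_identical(ks$ksx, ks$ksz)
  soft <- build_unloading_table(liver, nu_ref, lam_max = 1.3)
  mixed <- axis_stiffness(tab, soft, tab, lam = 1.2)
  expect_lt(mixed$ksy, mixed$ksx)
})

test_that("stiffness table round-trips through CSV plus JSON sidecar", {
  tab <- build_unloading_table(liver, nu_ref, lam_max = 1.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stiffness_table(tab, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- read_stiffness_table(path)
  expect_equal(back$lam_grid, tab$lam_grid)
  expect_equal(back$ks_values, tab$ks_values)
  expect_identical(back$branch, "unloading")
  expect_equal(back$lam_res, tab$lam_res)
  expect_equal(back$nu_ij, tab$nu_ij)
  expect_equal(unclass(back$params), unclass(tab$params))
})

test_that("spring energy follows the identity algebra", {
  expect_identical(spring_energy(2, 1, nu_ref), 0)
  expect_equal(spring_energy(4, 1.2, nu_ref), 2 * spring_energy(2, 1.2, nu_ref))
  expect_error(spring_energy(1, 0.9, nu_ref), "lam")
})
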