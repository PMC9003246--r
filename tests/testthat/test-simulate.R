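nu_ref <- 3.569e-5
tabs <- table_cache(liver, nu_ref, lam_max = 1.35)

test_that("element force vanishes at rest and follows the energy convention", {
  L <- 0.01
  expect_equal(element_force(c(0, 0, 0), c(L, 0, 0), L, tabs),
               c(0, 0, 0), tolerance = 1e-15)
  # stretched to lam = 1.2: F / nu_ij = 2 W_T(1.2) / 0.2 (engineering
  # units; tolerance covers the table interpolation between grid nodes)
  f <- element_force(c(0, 0, 0), c(1.2 * L, 0, 0), L, tabs)
  expect_equal(f[1] / nu_ref, 2 * w_total(1.2, liver) * 1000 / 0.2,
               tolerance = 1e-6)
  expect_equal(f[2:3], c(0, 0))
  # Hooke-extension convention scales by (lam - 1) / lam
  fh <- element_force(c(0, 0, 0), c(1.2 * L, 0, 0), L, tabs,
                      force_convention = "hooke-extension")
  expect_equal(fh[1], f[1] * 0.2 / 1.2, tolerance = 1e-12)
  # frame invariance under rigid translation
  shift <- c(0.3, -0.2, 5)
  f2 <- element_force(shift, c(1.2 * L, 0, 0) + shift, L, tabs)
  expect_equal(f2, f, tolerance = 1e-12)
  expect_error(element_force(c(0, 0, 0), c(0, 0, 0), L, tabs), "coincident")
})

test_that("unloading branch engages when below the historical maximum", {
  L <- 0.01
  f_virgin <- element_force(c(0, 0, 0), c(1.2 * L, 0, 0), L, tabs)
  f_soft <- element_force(c(0, 0, 0), c(1.2 * L, 0, 0), L, tabs,
                          lam_hist = 1.3)
  expect_lt(f_soft[1], f_virgin[1])
  expect_gt(f_soft[1], 0)
})

test_that("compression uses the linearized tangent, not zero resistance", {
  L <- 0.01
  f <- element_force(c(0, 0, 0), c(0.95 * L, 0, 0), L, tabs)
  expect_lt(f[1], 0)  # pushes node i away from j
  expect_equal(f[1], tabs$k_lin * (0.95 - 1), tolerance = 1e-12)
})

test_that("rest state is an equilibrium of the stepper", {
  mesh <- gen_beam_mesh(2, 1, 1, spacing = 0.01)
  cfg <- sim_config(dt = stable_dt(mesh, tabs))
  st <- sim_state(mesh)
  for (k in 1:20) st <- sim_step(st, mesh, tabs, cfg)
  expect_equal(st$positions, mesh$positions, tolerance = 1e-12)
  expect_equal(max(abs(st$velocities)), 0, tolerance = 1e-12)
})

test_that("internal forces cancel pairwise (momentum conservation)", {
  mesh <- gen_beam_mesh(2, 2, 2, spacing = 0.01)
  mesh$fixed_nodes <- integer()
  mesh$driven_nodes <- integer()
  set.seed(4)
  st <- sim_state(mesh)
  st$positions <- mesh$positions * (1 + 0.08 * matrix(stats::runif(length(mesh$positions)), ncol = 3))
  cfg <- sim_config(dt = stable_dt(mesh, tabs) / 2, damping = 0)
  for (k in 1:5) {
    st <- sim_step(st, mesh, tabs, cfg)
    asm <- eesm:::.assemble(st$positions, mesh, tabs, cfg, st$lam_hist)
    expect_lt(max(abs(colSums(asm$forces))), 1e-9)
  }
})

test_that("historical maximum stretch is monotone over time", {
  mesh <- single_element_mesh()
  cfg <- sim_config(dt = stable_dt(mesh, tabs), damping = 100)
  st <- sim_state(mesh)
  hist_trace <- numeric(0)
  for (lam in c(1.1, 1.25, 1.15, 1.3, 1.05)) {
    st$positions[2, 1] <- 0.01 * lam
    st <- sim_step(st, mesh, tabs, cfg)
    hist_trace <- c(hist_trace, st$lam_hist[1])
  }
  expect_true(all(diff(hist_trace) >= 0))
  expect_equal(hist_trace[4], 1.3, tolerance = 1e-12)
})

test_that("energy is conserved by Verlet on a conservative two-element chain", {
  L <- 0.01
  mesh <- spring_mesh(rbind(c(0, 0, 0), c(L, 0, 0), c(2 * L, 0, 0)),
                      rbind(c(1L, 2L), c(2L, 3L)))
  cfg <- sim_config(dt = stable_dt(mesh, tabs) / 4, damping = 0,
                    integrator = "verlet", mullins = FALSE)
  st <- sim_state(mesh)
  st$positions[, 1] <- st$positions[, 1] * 1.15  # initial uniform stretch
  e0 <- total_energy(st, mesh, tabs, cfg)$total
  expect_gt(e0, 0)
  st <- run_simulation(st, mesh, tabs, cfg, n_steps = 1e4)
  e1 <- total_energy(st, mesh, tabs, cfg)$total
  expect_lt(abs(e1 - e0) / e0, 0.01)
})

test_that("instability is detected with an actionable diagnostic", {
  mesh <- single_element_mesh()
  mesh$driven_nodes <- integer()  # free end so the oscillation can diverge
  cfg <- sim_config(dt = stable_dt(mesh, tabs) * 500, damping = 0)
  st <- sim_state(mesh)
  st$positions[2, 1] <- 0.01 * 1.3
  expect_error(
    for (k in 1:50) st <- sim_step(st, mesh, tabs, cfg),
    "dt|instability")
})

test_that("run_simulation honors driven schedules and records frames", {
  mesh <- single_element_mesh()
  cfg <- sim_config(dt = stable_dt(mesh, tabs), damping = 200)
  st <- sim_state(mesh)
  drive <- function(i) matrix(c(0.01 * (1 + 0.001 * min(i, 100)), 0, 0), 1)
  st <- run_simulation(st, mesh, tabs, cfg, n_steps = 50, drive = drive,
                       record_every = 10)
  expect_identical(length(st$frames), 5L)
  expect_identical(st$step_index, 50L)
  expect_identical(length(st$frame_ms), 50L)
  expect_gt(st$lam_hist[1], 1)
})
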