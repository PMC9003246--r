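#' Simulation configuration
#'
#' Integrator and numerical settings for the spring-mass loop. The
#' constitutive side of the model says nothing about time integration;
#' these are simulation choices. Semi-implicit (symplectic) Euler with
#' mass-proportional velocity damping is the default workhorse; velocity
#' Verlet is available for energy-conservation studies.
#'
#' @param dt Time step (s).
#' @param damping Mass-proportional damping coefficient (1/s), >= 0:
#'   the damping force per node is `-damping * m * v`.
#' @param integrator `"semi-implicit-euler"` or `"verlet"`.
#' @param max_steps Step budget guard for [run_simulation()].
#' @param gravity Optional length-3 gravity vector (m/s^2), or `NULL`.
#' @param force_convention `"energy-consistent"` (`F = ks(lam) * lam`, the
#'   convention under which the tabulated spring energy identity is exact)
#'   or `"hooke-extension"` (`F = ks(lam) * (lam - 1)`, the classic
#'   spring-mass force law with stiffness `ks/L` in N/m).
#' @param mullins Track per-element historical maximum stretch and switch
#'   to softened unloading tables below it. Disable for conservative-force
#'   studies (energy bookkeeping).
#' @param lam_hist_quantum Quantization of the historical maximum stretch
#'   used as the unloading-table cache key.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, damping = 50,
                       integrator = c("semi-implicit-euler", "verlet"),
                       max_steps = 1e6, gravity = NULL,
                       force_convention = c("energy-consistent",
                                            "hooke-extension"),
                       mullins = TRUE, lam_hist_quantum = 1e-3) {
  stopifnot(dt > 0, damping >= 0)
  structure(list(dt = dt, damping = damping,
                 integrator = match.arg(integrator),
                 max_steps = max_steps, gravity = gravity,
                 force_convention = match.arg(force_convention),
                 mullins = mullins, lam_hist_quantum = lam_hist_quantum),
            class = "sim_config")
}

#' Stiffness table cache for a simulation
#'
#' Holds the virgin table plus lazily built, memoized unloading tables
#' keyed by the quantized reversal stretch, and the linearized compression
#' stiffness used for stretches below 1 (where the energy-equivalence
#' formula is undefined; the small-strain tangent extrapolated from the
#' first table nodes is used instead).
#'
#' @inheritParams build_virgin_table
#' @param quantum Reversal-stretch quantization for the cache key.
#' @return A list of class `table_cache` with elements `virgin`,
#'   `unloading(lam_hist)`, `k_lin` (N per unit stretch), `params`,
#'   `nu_ij`.
#' @export
table_cache <- function(params, nu_ij, lam_max, dl = 1e-3, quantum = 1e-3) {
  virgin <- build_virgin_table(params, nu_ij, lam_max, dl)
  f <- virgin$ks_values * virgin$lam_grid
  k_lin <- (f[2] - f[1]) / (virgin$lam_grid[2] - virgin$lam_grid[1])
  store <- new.env(parent = emptyenv())
  get_unloading <- function(lam_hist) {
    key <- sprintf("%.6f", ceiling(lam_hist / quantum - 1e-9) * quantum)
    if (is.null(store[[key]]))
      store[[key]] <- build_unloading_table(params, nu_ij, as.numeric(key), dl)
    store[[key]]
  }
  structure(list(virgin = virgin, unloading = get_unloading, k_lin = k_lin,
                 params = params, nu_ij = nu_ij, quantum = quantum),
            class = "table_cache")
}

#' Force exerted on node i by one spring element
#'
#' The element stretch is `lam = |p_j - p_i| / L_ij`. The branch is chosen
#' by Mullins history: virgin if `lam` has reached the element's historical
#' maximum, otherwise the softened unloading table for that maximum. The
#' force magnitude follows the configured convention (default
#' energy-consistent `F = ks(lam) * lam`), acts along the element, and is
#' equal and opposite on node j. For `lam < 1` the linearized compression
#' response of the cache is used.
#'
#' @param p_i,p_j Node positions (length-3).
#' @param L_ij Rest length (m), > 0.
#' @param tables A [table_cache()] (or a bare virgin `stiffness_table`).
#' @param lam_hist Historical maximum stretch of this element (default 1).
#' @param force_convention See [sim_config()].
#' @return Length-3 force vector on node i (N).
#' @export
element_force <- function(p_i, p_j, L_ij, tables, lam_hist = 1,
                          force_convention = "energy-consistent") {
  d <- p_j - p_i
  len <- sqrt(sum(d^2))
  if (len <= 0) stop("element_force: coincident nodes")
  lam <- len / L_ij
  if (inherits(tables, "stiffness_table"))
    tables <- list(virgin = tables, unloading = function(h) tables,
                   k_lin = {
                     f <- tables$ks_values * tables$lam_grid
                     (f[2] - f[1]) / (tables$lam_grid[2] - tables$lam_grid[1])
                   })
  if (lam < 1) {
    mag <- tables$k_lin * (lam - 1)
  } else {
    tab <- if (lam >= lam_hist - 1e-12 || lam_hist <= 1 + 1e-3)
      tables$virgin else tables$unloading(lam_hist)
    ks <- stiffness_at(tab, lam, warn = FALSE)
    mag <- if (force_convention == "energy-consistent") ks * lam
           else ks * (lam - 1)
  }
  mag * d / len
}

# Vectorized force assembly over all elements.
# Returns forces (n x 3), per-element stretches, and (optionally) stored
# elastic energy consistent with the applied force law.
.assemble <- function(pos, mesh, tables, config, lam_hist, energy = FALSE) {
  el <- mesh$elements
  d <- pos[el[, 2], , drop = FALSE] - pos[el[, 1], , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  if (any(len <= 0))
    stop("simulation: coincident nodes in element ", which(len <= 0)[1])
  lam <- len / mesh$rest_lengths
  if (any(!is.finite(lam)))
    stop("simulation: non-finite stretch in element ",
         which(!is.finite(lam))[1], "; reduce dt (see stable_dt())")
  m <- nrow(el)
  mag <- numeric(m)
  ep <- if (energy) numeric(m) else NULL
  comp <- lam < 1
  if (any(comp)) {
    mag[comp] <- tables$k_lin * (lam[comp] - 1)
    if (energy)
      ep[comp] <- mesh$rest_lengths[comp] * tables$k_lin * (lam[comp] - 1)^2 / 2
  }
  tens <- which(!comp)
  if (length(tens)) {
    lt <- lam[tens]
    hh <- lam_hist[tens]
    use_virgin <- !config$mullins | lt >= hh - 1e-12 |
      hh <= 1 + config$lam_hist_quantum
    groups <- list()
    if (any(use_virgin)) groups[["virgin"]] <- which(use_virgin)
    if (any(!use_virgin)) {
      # quantize upward so the cached table always covers the element stretch
      q <- ceiling(hh[!use_virgin] / config$lam_hist_quantum - 1e-9) *
        config$lam_hist_quantum
      for (key in unique(q))
        groups[[sprintf("u%.6f", key)]] <- which(!use_virgin)[q == key]
    }
    for (nm in names(groups)) {
      ii <- groups[[nm]]
      tab <- if (nm == "virgin") tables$virgin
             else tables$unloading(as.numeric(sub("^u", "", nm)))
      gmax <- utils::tail(tab$lam_grid, 1)
      if (any(lt[ii] > gmax + 1e-12)) {
        bad <- tens[ii][which.max(lt[ii])]
        stop("simulation: element ", bad, " stretched to lam = ",
             signif(max(lt[ii]), 5), ", beyond the tabulated maximum ",
             signif(gmax, 5),
             " - likely instability; reduce dt (see stable_dt()) or ",
             "rebuild tables with a larger lam_max")
      }
      ks <- stiffness_at(tab, lt[ii], warn = FALSE)
      mag[tens[ii]] <- if (config$force_convention == "energy-consistent")
        ks * lt[ii] else ks * (lt[ii] - 1)
      if (energy) {
        # exact integral of the piecewise-linear interpolated force law
        g <- tab$lam_grid
        fnode <- if (config$force_convention == "energy-consistent")
          tab$ks_values * g else tab$ks_values * (g - 1)
        cw <- c(0, cumsum(diff(g) *
                            (utils::head(fnode, -1) + utils::tail(fnode, -1)) / 2))
        seg <- pmin(pmax(findInterval(lt[ii], g), 1), length(g) - 1)
        frac_f <- fnode[seg] + (fnode[seg + 1] - fnode[seg]) *
          (lt[ii] - g[seg]) / (g[seg + 1] - g[seg])
        w_at <- cw[seg] + (lt[ii] - g[seg]) * (fnode[seg] + frac_f) / 2
        ep[tens[ii]] <- mesh$rest_lengths[tens[ii]] * w_at
      }
    }
  }
  unit <- d / len
  fvec <- unit * mag
  forces <- matrix(0, nrow(pos), 3)
  for (k in 1:3) {
    fi <- rowsum(fvec[, k], el[, 1])
    forces[as.integer(rownames(fi)), k] <-
      forces[as.integer(rownames(fi)), k] + fi[, 1]
    fj <- rowsum(fvec[, k], el[, 2])
    forces[as.integer(rownames(fj)), k] <-
      forces[as.integer(rownames(fj)), k] - fj[, 1]
  }
  list(forces = forces, lam = lam, energy = if (energy) sum(ep) else NA_real_)
}

#' Initialize a simulation state
#'
#' @param mesh A [spring_mesh()].
#' @return A list of class `sim_state` with `positions`, `velocities`,
#'   `step_index`, `lam` (current per-element stretch), `lam_hist`
#'   (per-element historical maximum stretch, non-decreasing over time),
#'   `frame_ms` (per-step wall time log).
#' @export
sim_state <- function(mesh) {
  structure(list(positions = mesh$positions,
                 velocities = matrix(0, nrow(mesh$positions), 3),
                 step_index = 0L,
                 lam = rep(1, nrow(mesh$elements)),
                 lam_hist = rep(1, nrow(mesh$elements)),
                 frame_ms = numeric(0)),
            class = "sim_state")
}

#' Advance the simulation by one step
#'
#' Assembles all element forces plus damping (and optional gravity),
#' advances free nodes by the configured integrator, pins fixed and driven
#' nodes, and updates each element's historical maximum stretch. Aborts
#' with a diagnostic naming the first offending element if the state goes
#' non-finite or an element leaves the tabulated stretch range.
#'
#' @param state A [sim_state()].
#' @param mesh A [spring_mesh()].
#' @param tables A [table_cache()].
#' @param config A [sim_config()].
#' @return The advanced `sim_state`.
#' @export
sim_step <- function(state, mesh, tables, config) {
  t0 <- proc.time()[["elapsed"]]
  pos <- state$positions
  vel <- state$velocities
  minv <- 1 / mesh$masses
  pinned <- c(mesh$fixed_nodes, mesh$driven_nodes)
  asm <- .assemble(pos, mesh, tables, config, state$lam_hist)
  acc <- asm$forces * minv
  if (!is.null(config$gravity)) acc <- sweep(acc, 2, config$gravity, `+`)
  acc <- acc - config$damping * vel
  if (config$integrator == "semi-implicit-euler") {
    vel <- vel + config$dt * acc
    if (length(pinned)) vel[pinned, ] <- 0
    pos <- pos + config$dt * vel
  } else {  # velocity Verlet
    pos_new <- pos + config$dt * vel + 0.5 * config$dt^2 * acc
    if (length(pinned)) pos_new[pinned, ] <- pos[pinned, ]
    asm2 <- .assemble(pos_new, mesh, tables, config, state$lam_hist)
    acc2 <- asm2$forces * minv
    if (!is.null(config$gravity)) acc2 <- sweep(acc2, 2, config$gravity, `+`)
    acc2 <- acc2 - config$damping * vel
    vel <- vel + 0.5 * config$dt * (acc + acc2)
    if (length(pinned)) vel[pinned, ] <- 0
    pos <- pos_new
    asm <- asm2
  }
  if (any(!is.finite(pos)))
    stop("simulation: non-finite position at node ",
         which(!is.finite(rowSums(pos)))[1],
         " on step ", state$step_index + 1L,
         "; reduce dt (see stable_dt())")
  state$positions <- pos
  state$velocities <- vel
  state$lam <- asm$lam
  if (config$mullins) state$lam_hist <- pmax(state$lam_hist, asm$lam)
  state$step_index <- state$step_index + 1L
  state$frame_ms <- c(state$frame_ms,
                      (proc.time()[["elapsed"]] - t0) * 1000)
  state
}

#' Run a fixed number of simulation steps
#'
#' @inheritParams step
#' @param n_steps Number of steps (must not exceed `config$max_steps`).
#' @param drive Optional function `(step_index) -> k x 3 matrix` of
#'   positions for the driven nodes, applied before each step.
#' @param record_every Record node positions every this many steps
#'   (0 = never).
#' @return The final `sim_state`, with recorded frames (list of position
#'   matrices) in `$frames` when `record_every > 0`.
#' @export
run_simulation <- function(state, mesh, tables, config, n_steps,
                           drive = NULL, record_every = 0) {
  stopifnot(n_steps <= config$max_steps)
  frames <- list()
  for (s in seq_len(n_steps)) {
    if (!is.null(drive))
      state$positions[mesh$driven_nodes, ] <- drive(state$step_index + 1L)
    state <- sim_step(state, mesh, tables, config)
    if (record_every > 0 && s %% record_every == 0)
      frames[[length(frames) + 1L]] <- state$positions
  }
  if (record_every > 0) state$frames <- frames
  state
}

#' Total mechanical energy of a state
#'
#' Kinetic energy plus the stored elastic energy of every element,
#' integrated consistently with the (piecewise-linear interpolated) force
#' law actually applied, so that with zero damping and the Verlet
#' integrator the sum is conserved up to integrator drift. Meaningful for
#' conservative runs (`mullins = FALSE`); with Mullins branch switching the
#' force law is history-dependent and dissipative by design.
#'
#' @inheritParams step
#' @return A list with `kinetic`, `elastic`, `total` (J).
#' @export
total_energy <- function(state, mesh, tables, config) {
  asm <- .assemble(state$positions, mesh, tables, config, state$lam_hist,
                   energy = TRUE)
  ke <- 0.5 * sum(mesh$masses * rowSums(state$velocities^2))
  list(kinetic = ke, elastic = asm$energy, total = ke + asm$energy)
}

#' Stable time-step heuristic
#'
#' Estimates the stiffest element mode from the maximum slope of the
#' tabulated force law (`d(ks lam)/dlam` over the grid, divided by the
#' shortest rest length) and the lightest node, and returns
#' `safety * 2 / omega_max`. A warning-level guide, not a guarantee: mesh
#' connectivity can concentrate stiffness, hence the conservative default
#' safety factor.
#'
#' @param mesh A [spring_mesh()].
#' @param tables A [table_cache()] (its virgin table is used).
#' @param safety Fraction of the estimated stability limit (default 0.25).
#' @return Suggested `dt` (s).
#' @export
stable_dt <- function(mesh, tables, safety = 0.25) {
  tab <- tables$virgin
  f <- tab$ks_values * tab$lam_grid
  kmax <- max(abs(diff(f)) / diff(tab$lam_grid)) / min(mesh$rest_lengths)
  omega <- sqrt(4 * kmax / min(mesh$masses))
  safety * 2 / omega
}
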