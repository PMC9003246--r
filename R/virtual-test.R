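#' Virtual displacement-controlled uniaxial tension test
#'
#' Reproduces the cyclic tensile protocol on a spring mesh: the driven face
#' (nodes tagged `driven_nodes`, normal to x) is ramped quasi-statically to
#' each target stretch and back down to 1, while the fixed face stays
#' pinned. At every increment the interior is relaxed by damped
#' semi-implicit Euler substeps until the free-node force residual drops
#' below `ftol` times the boundary reaction (or `max_relax` substeps), and
#' the reaction force on the driven face divided by the reference area is
#' recorded as engineering stress. Loading follows the virgin tables;
#' unloading engages the softened tables for each element's historical
#' maximum stretch, so successive cycles trace nested Mullins loops
#' enclosing positive dissipated area.
#'
#' Quasi-staticity is monitored online: the kinetic/elastic energy ratio at
#' each recorded increment is returned in the diagnostics and should stay
#' well below 1%.
#'
#' @param mesh A [spring_mesh()] with `fixed_nodes` and `driven_nodes`
#'   tagged on two opposite faces normal to x.
#' @param params A [material_params()] object.
#' @param lam_targets Target stretches, one per cycle (e.g.
#'   `c(1.15, 1.23, 1.30)`).
#' @param nu_ij Transversal-area parameter of each element (m^2).
#' @param n_increments Stretch increments per branch of each cycle.
#' @param dl Stiffness-table grid spacing.
#' @param ref_area Reference cross-section area for converting the reaction
#'   force to engineering stress; default `length(driven_nodes) * nu_ij`
#'   (one element cross-section per driven node, exact for chain lattices).
#' @param ftol Relative force-residual tolerance for the inner relaxation.
#' @param max_relax Substep cap per increment.
#' @return An `experiment_curve` data frame (`lam`, `sigma` in kPa,
#'   `branch`, `cycle`) with a `diagnostics` attribute (time step used,
#'   relaxation substeps, kinetic/elastic ratios) and a `tables` attribute
#'   carrying the [table_cache()] used.
#' @export
run_virtual_uniaxial_test <- function(mesh, params, lam_targets = 1.3,
                                      nu_ij = 3.569e-5, n_increments = 25,
                                      dl = 1e-3, ref_area = NULL,
                                      ftol = 1e-3, max_relax = 2000) {
  stopifnot(length(mesh$fixed_nodes) > 0, length(mesh$driven_nodes) > 0,
            all(diff(c(1, lam_targets)) > 0))
  tables <- table_cache(params, nu_ij, lam_max = max(lam_targets) + 0.05,
                        dl = dl)
  if (is.null(ref_area)) ref_area <- length(mesh$driven_nodes) * nu_ij
  config <- sim_config(dt = stable_dt(mesh, tables), mullins = TRUE)
  config$damping <- 0.1 / config$dt  # strong but sub-critical for all modes
  state <- sim_state(mesh)
  x_fix <- mean(mesh$positions[mesh$fixed_nodes, 1])
  driven0 <- mesh$positions[mesh$driven_nodes, , drop = FALSE]
  out <- NULL
  ke_ratio <- numeric(0)
  relax_used <- integer(0)
  lam_prev <- 1
  for (ci in seq_along(lam_targets)) {
    lt <- lam_targets[ci]
    sched <- c(seq(1, lt, length.out = n_increments + 1)[-1],
               seq(lt, 1, length.out = n_increments + 1)[-1])
    branch <- rep(c("loading", "unloading"), each = n_increments)
    for (si in seq_along(sched)) {
      lam_app <- sched[si]
      # warm start: affine axial rescale of the whole mesh toward the new
      # applied stretch (fixed face sits at x = 0), then pin the driven
      # face exactly; avoids kicking the boundary-adjacent elements
      state$positions[, 1] <- x_fix +
        (state$positions[, 1] - x_fix) * lam_app / lam_prev
      state$positions[mesh$driven_nodes, 1] <- x_fix +
        (driven0[, 1] - x_fix) * lam_app
      state$velocities[] <- 0
      lam_prev <- lam_app
      res <- .relax(state, mesh, tables, config, ftol, max_relax)
      state <- res$state
      relax_used <- c(relax_used, res$substeps)
      # external pull on the driven face balances the internal x-force
      reaction <- -sum(res$forces[mesh$driven_nodes, 1])
      sigma <- reaction / ref_area / 1000  # kPa
      en <- total_energy(state, mesh, tables, config)
      ke_ratio <- c(ke_ratio,
                    if (en$elastic > 0) en$kinetic / en$elastic else 0)
      out <- rbind(out, data.frame(lam = lam_app, sigma = sigma,
                                   branch = branch[si], cycle = ci))
    }
  }
  structure(out,
            diagnostics = list(dt = config$dt, damping = config$damping,
                               relax_substeps = relax_used,
                               ke_over_elastic = ke_ratio,
                               frame_ms = state$frame_ms),
            tables = tables,
            source = "eesm::run_virtual_uniaxial_test",
            class = c("experiment_curve", "data.frame"))
}

# Damped relaxation toward static equilibrium at fixed boundary positions.
# The force reference is floored at 0.1% of the table's maximum element
# force so near-zero-reaction increments (slack unloading tail) converge.
.relax <- function(state, mesh, tables, config, ftol, max_relax) {
  free <- setdiff(seq_len(nrow(mesh$positions)),
                  c(mesh$fixed_nodes, mesh$driven_nodes))
  f_floor <- 1e-3 * max(tables$virgin$ks_values * tables$virgin$lam_grid)
  substeps <- 0L
  repeat {
    for (k in 1:25) state <- sim_step(state, mesh, tables, config)
    substeps <- substeps + 25L
    asm <- .assemble(state$positions, mesh, tables, config, state$lam_hist)
    fref <- max(abs(asm$forces[mesh$driven_nodes, 1]), f_floor)
    fres <- if (length(free))
      max(abs(asm$forces[free, , drop = FALSE])) else 0
    if (fres <= ftol * fref || substeps >= max_relax) break
  }
  list(state = state, forces = asm$forces, substeps = substeps)
}

#' Hysteresis loop area of a loading/unloading cycle
#'
#' Trapezoid integral of stress over stretch along the loading branch minus
#' the unloading branch of one cycle: the energy dissipated per unit
#' reference volume by the Mullins effect (kPa = kJ/m^3). Positive for a
#' softening material; zero when softening is disabled.
#'
#' @param curve An `experiment_curve`.
#' @param cycle Which cycle to integrate (default the last).
#' @return Loop area (kPa).
#' @export
hysteresis_area <- function(curve, cycle = max(curve$cycle)) {
  cc <- curve[curve$cycle == cycle, ]
  up <- cc[cc$branch == "loading", ]
  dn <- cc[cc$branch == "unloading", ]
  if (nrow(up) < 2 || nrow(dn) < 2)
    stop("hysteresis_area: cycle ", cycle, " lacks a loading or unloading branch")
  tz <- function(x, y) {
    o <- order(x)
    sum(diff(x[o]) * (utils::head(y[o], -1) + utils::tail(y[o], -1)) / 2)
  }
  tz(up$lam, up$sigma) - tz(dn$lam, dn$sigma)
}
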