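#' Build the virgin-branch equivalent spring stiffness table
#'
#' The defining step of the equivalent-energy spring model: the strain
#' energy density of the tissue at stretch `lam` is equated with the stored
#' energy of a one-dimensional spring of variable stiffness,
#' `W_s = ks lam (lam - 1) / (2 nu_ij)`, giving
#' `ks(lam) = 2 nu_ij W_T(lam) / (lam^2 - lam)`. The table is precomputed
#' once on a dense stretch grid during initialization and looked up in O(1)
#' during simulation; it is never rebuilt inside the simulation loop.
#'
#' Units: energy densities are kPa (= 1000 J/m^3) and `nu_ij` is in m^2, so
#' `ks` carries units of newtons and the element force law is
#' `F = ks(lam) * lam` (see [element_force()]).
#'
#' The grid runs from `1 + 1e-6` to `lam_max` in steps of `dl` (with
#' `lam_max` appended exactly). At the first node the 0/0 limit of the
#' ratio is harmless: `W_T ~ O((lam-1)^2)` since both the energy and the
#' stress vanish at `lam = 1`, so `ks -> 0` there; [stiffness_at()]
#' interpolates through the implicit `(1, 0)` anchor for stretches below
#' the first node.
#'
#' @param params A [material_params()] object.
#' @param nu_ij Transversal-area geometric parameter (m^2).
#' @param lam_max Largest tabulated stretch; must stay below the chain lock
#'   stretch `sqrt` of the solution of `lam^2 + 2/lam = 3 N`.
#' @param dl Grid spacing in stretch (default 1e-3).
#' @return An object of class `stiffness_table`: a list with `lam_grid`,
#'   `ks_values` (N), `w_values` (kPa), `work` (cumulative force-law work
#'   integral, N, for energy bookkeeping), `nu_ij`, `branch`, `lam_max`,
#'   `lam_res`, `dl`, `params`.
#' @seealso [build_unloading_table()], [stiffness_at()], [spring_energy()]
#' @export
#' @examples
#' tab <- build_virgin_table(liver_params(), nu_ij = 3.569e-5, lam_max = 1.3)
#' tab
build_virgin_table <- function(params, nu_ij, lam_max, dl = 1e-3) {
  stopifnot(inherits(params, "material_params"), nu_ij > 0, dl > 0, lam_max > 1)
  grid <- .lam_grid(lam_max, dl)
  w <- w_total(grid, params)                        # kPa
  ks <- 2 * nu_ij * (w * 1000) / (grid * (grid - 1))    # N
  .new_stiffness_table(grid, ks, w, nu_ij, "virgin", lam_max,
                       lam_res = 1, dl = dl, params = params)
}

.lam_grid <- function(lam_max, dl) {
  grid <- seq(1 + 1e-6, lam_max, by = dl)
  if (utils::tail(grid, 1) < lam_max) grid <- c(grid, lam_max)
  grid
}

.new_stiffness_table <- function(grid, ks, w, nu_ij, branch, lam_max,
                                 lam_res, dl, params) {
  if (any(!is.finite(ks)) || any(ks < -1e-12))
    stop("stiffness table: non-finite or negative stiffness encountered")
  ks <- pmax(ks, 0)
  # cumulative work of the force law F = ks * lam along the grid
  # (trapezoid; exact for the piecewise-linear interpolated force)
  f <- ks * grid
  work <- c(0, cumsum(diff(grid) * (utils::head(f, -1) + utils::tail(f, -1)) / 2))
  structure(list(lam_grid = grid, ks_values = ks, w_values = w, work = work,
                 nu_ij = nu_ij, branch = branch, lam_max = lam_max,
                 lam_res = lam_res, dl = dl, params = params),
            class = "stiffness_table")
}

#' @export
print.stiffness_table <- function(x, ...) {
  cat(sprintf("Stiffness table (%s branch): %d nodes, lam in [%.6f, %g]\n",
              x$branch, length(x$lam_grid), x$lam_grid[1], x$lam_max))
  cat(sprintf("  nu_ij = %g m^2, dl = %g, ks range [%.4g, %.4g] N\n",
              x$nu_ij, x$dl, min(x$ks_values), max(x$ks_values)))
  if (x$branch == "unloading")
    cat(sprintf("  residual stretch lam_res = %.6f\n", x$lam_res))
  invisible(x)
}

#' Build the unloading-branch stiffness table
#'
#' The softened (Mullins) branch needs a stored-energy function of its own.
#' It is obtained as the work along the unloading path: the softened
#' engineering stress is integrated (trapezoid on a refined grid, step
#' `dl/32`) from the residual stretch `lam_res` (where the softened stress
#' crosses zero) up to `lam`, and the same energy-equivalence conversion
#' `ks = 2 nu_ij W_s / (lam^2 - lam)` is applied. Below `lam_res` the
#' stored energy and stiffness are zero (the element carries no tension
#' below its permanent set). The unloading stiffness is dominated by the
#' virgin stiffness at every common stretch.
#'
#' @inheritParams build_virgin_table
#' @param lam_max The reversal stretch from which the material unloads.
#' @return A `stiffness_table` with `branch = "unloading"`.
#' @export
build_unloading_table <- function(params, nu_ij, lam_max, dl = 1e-3) {
  stopifnot(inherits(params, "material_params"), nu_ij > 0, dl > 0, lam_max > 1)
  lam_res <- residual_stretch(lam_max, params)
  grid <- .lam_grid(lam_max, dl)
  w <- softened_energy(grid, lam_max, params, lam_res = lam_res, dl = dl)
  ks <- 2 * nu_ij * (w * 1000) / (grid * (grid - 1))
  .new_stiffness_table(grid, ks, w, nu_ij, "unloading", lam_max,
                       lam_res = lam_res, dl = dl, params = params)
}

#' Softened-branch stored energy density
#'
#' Work of the softened engineering stress along the unloading path from
#' the residual stretch (zero-stress crossing) up to `lam`:
#' `W_s(lam) = integral from lam_res to lam of sigma_s`. Zero for
#' `lam <= lam_res`. Computed by cumulative trapezoid integration on a grid
#' refined to `dl/32` (the softening factor has a square-root cusp at the
#' reversal point, so the integrand needs a fine step to keep the
#' trapezoid error below ~1e-5 relative), then interpolated to the
#' requested stretches.
#'
#' @param lam Stretches at which to evaluate (vector, in `[1, lam_max]`).
#' @param lam_max Reversal stretch.
#' @param params A [material_params()] object.
#' @param lam_res Residual stretch; computed via [residual_stretch()] when
#'   not supplied.
#' @param dl Base step controlling the integration grid (`dl/32`).
#' @return Energy densities in kPa.
#' @export
softened_energy <- function(lam, lam_max, params, lam_res = NULL, dl = 1e-3) {
  if (is.null(lam_res)) lam_res <- residual_stretch(lam_max, params)
  out <- numeric(length(lam))
  above <- lam > lam_res
  if (any(above)) {
    g <- seq(lam_res, lam_max, by = dl / 32)
    if (utils::tail(g, 1) < lam_max) g <- c(g, lam_max)
    s <- softened_stress(g, lam_max, params)$sigma
    cum <- c(0, cumsum(diff(g) * (utils::head(s, -1) + utils::tail(s, -1)) / 2))
    out[above] <- stats::approx(g, cum, xout = lam[above], rule = 2)$y
  }
  out
}

#' Interpolate a stiffness table
#'
#' Linear interpolation between bracketing grid nodes; exact at the nodes.
#' Stretches below the first grid node (but >= 1) are interpolated through
#' the analytic anchor `ks(1) = 0` with a warning (suppressible for the
#' hot simulation path via `warn = FALSE`); stretches above `lam_max` raise
#' an error, since extrapolating the energy equivalence past the tabulated
#' reversal stretch is unsafe.
#'
#' @param table A `stiffness_table`.
#' @param lam Stretches at which to evaluate (vector).
#' @param warn Emit a warning when clamping below the first node.
#' @return Stiffness values (N).
#' @export
stiffness_at <- function(table, lam, warn = TRUE) {
  stopifnot(inherits(table, "stiffness_table"))
  gmax <- utils::tail(table$lam_grid, 1)
  if (any(lam > gmax + 1e-12))
    stop("stiffness_at: lam = ", signif(max(lam), 6),
         " beyond table maximum ", signif(gmax, 6),
         "; extrapolation past the tabulated reversal stretch is unsafe")
  gmin <- table$lam_grid[1]
  if (any(lam < gmin)) {
    if (any(lam < 1 - 1e-12))
      stop("stiffness_at: lam = ", signif(min(lam), 6), " below 1")
    if (warn)
      warning("stiffness_at: lam below first grid node ", signif(gmin, 8),
              "; interpolating through ks(1) = 0")
  }
  stats::approx(c(1, table$lam_grid), c(0, table$ks_values),
                xout = pmin(pmax(lam, 1), gmax))$y
}

#' Spring stored-energy density from the energy-equivalence identity
#'
#' `W_s = ks lam (lam - 1) / (2 nu_ij)` (in kPa with `ks` in N and `nu_ij`
#' in m^2): the stored energy density of an equivalent-energy spring
#' element at stretch `lam`. By construction this recovers the tissue
#' strain energy density when `ks` comes from the matching table node.
#'
#' @param ks Stiffness values (N).
#' @param lam Stretch values, >= 1.
#' @param nu_ij Transversal area (m^2).
#' @return Energy densities (kPa).
#' @export
spring_energy <- function(ks, lam, nu_ij) {
  if (any(lam < 1)) stop("spring_energy: lam must be >= 1")
  ks * lam * (lam - 1) / (2 * nu_ij) / 1000
}

#' Per-axis stiffness triple
#'
#' Looks up one stiffness per coordinate axis for anisotropic element
#' assignments. For the isotropized liver model all three tables are the
#' same object and the triple is three equal values (the documented
#' default).
#'
#' @param table_x,table_y,table_z `stiffness_table` objects.
#' @param lam Stretch (vector).
#' @return A list with components `ksx`, `ksy`, `ksz`.
#' @export
axis_stiffness <- function(table_x, table_y = table_x, table_z = table_x, lam) {
  list(ksx = stiffness_at(table_x, lam, warn = FALSE),
       ksy = stiffness_at(table_y, lam, warn = FALSE),
       ksz = stiffness_at(table_z, lam, warn = FALSE))
}

#' Write / read a stiffness table (CSV + JSON sidecar)
#'
#' The table itself is a two-column CSV (`lam`, `ks_N`); grid metadata, the
#' geometric parameter, the branch, and the full generating material
#' parameters travel in a JSON sidecar (`<path>.json`) so a table can be
#' rebuilt and verified from its own provenance.
#'
#' @param table A `stiffness_table`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @return `write_stiffness_table()` returns `path` invisibly;
#'   `read_stiffness_table()` returns a `stiffness_table`.
#' @export
write_stiffness_table <- function(table, path) {
  stopifnot(inherits(table, "stiffness_table"))
  utils::write.csv(data.frame(lam = table$lam_grid, ks_N = table$ks_values),
                   path, row.names = FALSE)
  side <- list(nu_ij_m2 = table$nu_ij, branch = table$branch,
               lam_max = table$lam_max, lam_res = table$lam_res,
               dl = table$dl,
               params = stats::setNames(unclass(table$params)[names(.params_json_keys)],
                                        unname(.params_json_keys)))
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stiffness_table
#' @export
read_stiffness_table <- function(path) {
  tab <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pp <- side$params
  params <- material_params(mu = pp$mu_kPa, N = pp$N, b = pp$b, A1 = pp$A1_kPa,
                            A2 = pp$A2_kPa, C = pp$C_kPa, f = pp$f, n = pp$n)
  w <- spring_energy(tab$ks_N, tab$lam, side$nu_ij_m2)
  .new_stiffness_table(tab$lam, tab$ks_N, w, side$nu_ij_m2, side$branch,
                       side$lam_max, side$lam_res, side$dl, params)
}
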