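#' Configuration for synthetic cyclic uniaxial test data
#'
#' Describes a loading/unloading cyclic tensile protocol: three cycles to
#' increasing maximum stretches (default 1.15, 1.23, 1.30 — the reversal
#' stretches of the reference liver spring tests), a number of samples per
#' branch, and multiplicative noise of a given coefficient of variation.
#'
#' @param params A [material_params()] object generating the curves.
#' @param cycle_lam_maxes Strictly increasing reversal stretches, one per
#'   cycle.
#' @param points_per_branch Samples per loading and per unloading branch.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   (lognormal, mean-1) observation noise; 0 gives the exact model curve.
#' @param seed Integer seed making the generated data reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(params = liver_params(),
                         cycle_lam_maxes = c(1.15, 1.23, 1.30),
                         points_per_branch = 40,
                         noise_cv = 0.02,
                         seed = 1L) {
  stopifnot(inherits(params, "material_params"),
            length(cycle_lam_maxes) >= 1,
            all(diff(cycle_lam_maxes) > 0),
            all(cycle_lam_maxes > 1),
            points_per_branch >= 2,
            noise_cv >= 0)
  if (any((cycle_lam_maxes^2 + 2 / cycle_lam_maxes) / 3 >= params$N))
    stop("synth_config: a cycle reversal stretch reaches the chain lock limit")
  structure(list(params = params, cycle_lam_maxes = cycle_lam_maxes,
                 points_per_branch = points_per_branch,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate synthetic loading/unloading uniaxial cycles
#'
#' Emulates a cyclic tensile test on soft tissue: each cycle loads to its
#' reversal stretch and unloads back down to the residual stretch (where
#' the softened stress crosses zero — real tensile samples go slack there).
#' Reloading in later cycles starts from the previous residual stretch and
#' follows the softened branch of the previous reversal stretch until the
#' historical maximum is exceeded, then rejoins the virgin curve — the
#' standard Mullins idealization. Noise is i.i.d. multiplicative lognormal
#' with mean 1 and the configured coefficient of variation (stress data are
#' positive and heteroscedastic); `additive = TRUE` switches to additive
#' Gaussian noise with standard deviation `noise_cv * max(|sigma|)`.
#'
#' @param config A [synth_config()] object.
#' @param additive Use additive Gaussian instead of multiplicative
#'   lognormal noise.
#' @return An `experiment_curve` data frame with columns `lam`,
#'   `sigma` (kPa), `branch` (`"loading"`/`"unloading"`), `cycle`, plus
#'   attributes `lam_maxes`, `noise_cv`, `seed`, `source`.
#' @export
#' @examples
#' curve <- gen_uniaxial_cycles(synth_config(noise_cv = 0, seed = 7))
#' head(curve)
gen_uniaxial_cycles <- function(config, additive = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  p <- config$params
  npts <- config$points_per_branch
  sched <- NULL
  lam_start <- 1
  hist_max <- 1
  for (ci in seq_along(config$cycle_lam_maxes)) {
    lmax <- config$cycle_lam_maxes[ci]
    lam_load <- seq(lam_start, lmax, length.out = npts)
    # branch bookkeeping: below the historical max the reloading path is
    # softened (previous cycle's reversal), above it the virgin path
    soft <- lam_load < hist_max - 1e-12
    sig_load <- numeric(npts)
    if (any(soft))
      sig_load[soft] <- softened_stress(lam_load[soft], hist_max, p)$sigma
    sig_load[!soft] <- virgin_stress(pmax(lam_load[!soft], 1), p)$sigma
    sched <- rbind(sched,
                   data.frame(lam = lam_load, sigma = sig_load,
                              branch = "loading", cycle = ci))
    hist_max <- lmax
    lam_res <- residual_stretch(lmax, p)
    lam_unload <- seq(lmax, lam_res, length.out = npts)
    sig_unload <- softened_stress(lam_unload, lmax, p)$sigma
    sched <- rbind(sched,
                   data.frame(lam = lam_unload, sigma = sig_unload,
                              branch = "unloading", cycle = ci))
    lam_start <- lam_res
  }
  if (config$noise_cv > 0) {
    set.seed(config$seed)
    n <- nrow(sched)
    if (additive) {
      sched$sigma <- sched$sigma +
        stats::rnorm(n, 0, config$noise_cv * max(abs(sched$sigma)))
    } else {
      s2 <- log(1 + config$noise_cv^2)
      sched$sigma <- sched$sigma * stats::rlnorm(n, -s2 / 2, sqrt(s2))
    }
  }
  structure(sched,
            lam_maxes = config$cycle_lam_maxes,
            noise_cv = config$noise_cv, seed = config$seed,
            source = "eesm::gen_uniaxial_cycles",
            class = c("experiment_curve", "data.frame"))
}

#' Write / read an experiment curve as CSV
#'
#' Columns `lam`, `stress_kPa`, `branch` (`loading`/`unloading`), `cycle`.
#' Provenance (cycle reversal stretches, noise level, seed, generator) is
#' carried in a JSON sidecar `<path>.json` when written by this package and
#' restored on read when present.
#'
#' @param curve An `experiment_curve` data frame.
#' @param path CSV path.
#' @return `write_curve()` returns `path` invisibly; `read_curve()` an
#'   `experiment_curve`.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(data.frame(lam = curve$lam, stress_kPa = curve$sigma,
                              branch = curve$branch, cycle = curve$cycle),
                   path, row.names = FALSE)
  side <- list(lam_maxes = attr(curve, "lam_maxes"),
               noise_cv = attr(curve, "noise_cv"),
               seed = attr(curve, "seed"),
               source = attr(curve, "source"))
  side <- side[!vapply(side, is.null, logical(1))]
  if (length(side))
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  x <- utils::read.csv(path)
  need <- c("lam", "stress_kPa", "branch", "cycle")
  if (!all(need %in% names(x)))
    stop("read_curve: ", path, " must have columns ",
         paste(need, collapse = ", "))
  out <- data.frame(lam = x$lam, sigma = x$stress_kPa,
                    branch = x$branch, cycle = x$cycle)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    for (nm in names(side)) attr(out, nm) <- side[[nm]]
  }
  class(out) <- c("experiment_curve", "data.frame")
  out
}

#' Generate a regular beam lattice mesh
#'
#' Nodes on a regular `(nx+1) x (ny+1) x (nz+1)` lattice with the given
#' spacing; axis-aligned edges always become elements, and with
#' `diagonals = TRUE` (default) both face diagonals of every lattice face
#' are added for shear stiffness, giving rest lengths in
#' `{spacing, spacing * sqrt(2)}`. The two faces normal to x are tagged:
#' `fixed_nodes` at `x = 0` and `driven_nodes` at `x = max` for
#' displacement-controlled tension tests. Without diagonals, homogeneous
#' axial extension is an exact equilibrium of the lattice, which makes the
#' beam tension test directly comparable to the single-element prediction.
#'
#' @param nx,ny,nz Number of cells along each axis (>= 1).
#' @param spacing Lattice spacing (m).
#' @param diagonals Add face-diagonal elements.
#' @return A [spring_mesh()].
#' @export
gen_beam_mesh <- function(nx, ny, nz, spacing = 0.01, diagonals = TRUE) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, spacing > 0)
  dims <- c(nx, ny, nz) + 1L
  idx <- function(i, j, k) i + dims[1] * (j + dims[2] * k) + 1L
  coords <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  pos <- as.matrix(coords) * spacing
  colnames(pos) <- c("x", "y", "z")
  el <- list()
  add <- function(a, b) el[[length(el) + 1L]] <<- c(a, b)
  for (k in 0:nz) for (j in 0:ny) for (i in 0:nx) {
    a <- idx(i, j, k)
    if (i < nx) add(a, idx(i + 1, j, k))
    if (j < ny) add(a, idx(i, j + 1, k))
    if (k < nz) add(a, idx(i, j, k + 1))
    if (diagonals) {
      if (i < nx && j < ny) { add(a, idx(i + 1, j + 1, k))
                              add(idx(i + 1, j, k), idx(i, j + 1, k)) }
      if (i < nx && k < nz) { add(a, idx(i + 1, j, k + 1))
                              add(idx(i + 1, j, k), idx(i, j, k + 1)) }
      if (j < ny && k < nz) { add(a, idx(i, j + 1, k + 1))
                              add(idx(i, j + 1, k), idx(i, j, k + 1)) }
    }
  }
  elements <- do.call(rbind, el)
  spring_mesh(pos, elements,
              fixed_nodes = which(coords$i == 0),
              driven_nodes = which(coords$i == nx))
}

#' Generate a subdivided-icosahedron ellipsoid surface mesh
#'
#' Stand-in for organ-like closed surfaces: an icosahedron subdivided
#' `subdivisions` times (each level quadruples the face count), with
#' vertices projected to the unit sphere and scaled by the three radii.
#' Edges become spring elements. At subdivision 0 the mesh is the bare
#' icosahedron (12 vertices, 30 edges, 20 faces); subdivision `s` has
#' `20 * 4^s` faces and `30 * 4^s` edges.
#'
#' @param subdivisions Non-negative integer subdivision depth.
#' @param radii Length-3 vector of semi-axes (m).
#' @return A [spring_mesh()] with a `faces` attribute (triangle indices).
#' @export
gen_ellipsoid_mesh <- function(subdivisions = 2, radii = c(0.1, 0.06, 0.04)) {
  stopifnot(subdivisions >= 0, length(radii) == 3, all(radii > 0))
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[4 * t - 3, ] <- c(a, ab, ca)
      newf[4 * t - 2, ] <- c(b, bc, ab)
      newf[4 * t - 1, ] <- c(cc, ca, bc)
      newf[4 * t, ]     <- c(ab, bc, ca)
    }
    f <- newf
  }
  pos <- sweep(v, 2, radii, `*`)
  colnames(pos) <- c("x", "y", "z")
  edges <- unique(t(apply(rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)]), 1, sort)))
  mesh <- spring_mesh(pos, edges)
  attr(mesh, "faces") <- f
  mesh
}
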