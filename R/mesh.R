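#' Spring mesh of equivalent-energy elements
#'
#' A deformable object as point masses connected by one-dimensional
#' variable-stiffness spring elements. Elements are undirected node pairs
#' with rest lengths taken from the initial geometry. Node masses are
#' lumped proportionally to the total rest length of incident elements so
#' that the given tissue density times the reference volume is conserved.
#'
#' @param positions Numeric `n x 3` matrix of node coordinates (m).
#' @param elements Integer `m x 2` matrix of node index pairs (1-based);
#'   duplicates are removed (with a message) and endpoints must differ.
#' @param fixed_nodes,driven_nodes Optional node index vectors marking
#'   boundary-condition faces.
#' @param density Tissue density (kg/m^3, default 1060 — soft tissue).
#' @param volume Reference volume used for mass lumping (m^3); defaults to
#'   the bounding-box volume of the positions (or a small positive value
#'   for degenerate/flat meshes).
#' @return An object of class `spring_mesh`: list with `positions`,
#'   `elements`, `rest_lengths`, `masses`, `fixed_nodes`, `driven_nodes`.
#' @export
spring_mesh <- function(positions, elements, fixed_nodes = integer(),
                        driven_nodes = integer(), density = 1060,
                        volume = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, is.numeric(positions))
  elements <- matrix(as.integer(elements), ncol = 2)
  if (any(elements < 1 | elements > nrow(positions)))
    stop("spring_mesh: element index out of range")
  if (any(elements[, 1] == elements[, 2]))
    stop("spring_mesh: element endpoints must be distinct")
  elements <- t(apply(elements, 1, sort))
  dup <- duplicated(elements)
  if (any(dup)) {
    message("spring_mesh: removed ", sum(dup), " duplicate element(s)")
    elements <- elements[!dup, , drop = FALSE]
  }
  d <- positions[elements[, 2], , drop = FALSE] -
       positions[elements[, 1], , drop = FALSE]
  rest <- sqrt(rowSums(d^2))
  if (any(rest <= 0)) stop("spring_mesh: zero-length element")
  if (is.null(volume)) {
    rng <- apply(positions, 2, range)
    volume <- prod(pmax(rng[2, ] - rng[1, ], 1e-6))
  }
  # lump mass per node proportional to incident rest length
  inc <- numeric(nrow(positions))
  for (c2 in 1:2) {
    agg <- rowsum(rest, elements[, c2])
    ii <- as.integer(rownames(agg))
    inc[ii] <- inc[ii] + agg[, 1]
  }
  masses <- density * volume * inc / sum(inc)
  structure(list(positions = positions, elements = elements,
                 rest_lengths = rest, masses = masses,
                 fixed_nodes = as.integer(fixed_nodes),
                 driven_nodes = as.integer(driven_nodes)),
            class = "spring_mesh")
}

#' @export
print.spring_mesh <- function(x, ...) {
  cat(sprintf("Spring mesh: %d nodes, %d elements\n",
              nrow(x$positions), nrow(x$elements)))
  cat(sprintf("  rest lengths [%.4g, %.4g] m, total mass %.4g kg\n",
              min(x$rest_lengths), max(x$rest_lengths), sum(x$masses)))
  if (length(x$fixed_nodes))
    cat(sprintf("  %d fixed, %d driven nodes\n",
                length(x$fixed_nodes), length(x$driven_nodes)))
  invisible(x)
}

#' Load a mesh from an OBJ or VTK legacy file
#'
#' OBJ files must carry triangle faces (`v`/`f` lines; `f` entries may use
#' the `v/vt/vn` syntax); VTK legacy ASCII files must be `UNSTRUCTURED_GRID`
#' datasets with triangle (type 5) or tetrahedron (type 10) cells, or
#' `POLYDATA` with triangle `POLYGONS`. The unique edges of the cells
#' become spring elements with rest lengths from the file geometry.
#'
#' @param path File path; format chosen by extension (`.obj` / `.vtk`).
#' @param ... Passed to [spring_mesh()] (e.g. `density`).
#' @return A [spring_mesh()] with a `faces` or `cells` attribute.
#' @export
load_mesh <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .load_obj(path, ...),
         vtk = .load_vtk(path, ...),
         stop("load_mesh: unsupported extension '", ext,
              "' (expected obj or vtk)"))
}

.edges_from_cells <- function(cells) {
  k <- ncol(cells)
  pairs <- utils::combn(k, 2)
  e <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
    cells[, pairs[, i], drop = FALSE]))
  unique(t(apply(e, 1, sort)))
}

.load_obj <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl))
    stop("load_mesh: ", path, " has no vertices or no faces (line 1: '",
         if (length(lines)) lines[1] else "", "')")
  pos <- do.call(rbind, lapply(vl, function(s)
    as.numeric(strsplit(trimws(sub("^v", "", s)), "\\s+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(seq_along(fl), function(i) {
    toks <- strsplit(trimws(sub("^f", "", fl[i])), "\\s+")[[1]]
    if (length(toks) != 3)
      stop("load_mesh: non-triangular face at OBJ face line ", i)
    as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1))
  }))
  dup <- duplicated(t(apply(faces, 1, sort)))
  if (any(dup)) {
    message("load_mesh: removed ", sum(dup),
            " duplicate face(s); edges deduplicated")
    faces <- faces[!dup, , drop = FALSE]
  }
  mesh <- spring_mesh(pos, .edges_from_cells(faces), ...)
  attr(mesh, "faces") <- faces
  mesh
}

.load_vtk <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  ip <- grep("^POINTS", lines)
  if (!length(ip)) stop("load_mesh: ", path, " has no POINTS block")
  npts <- as.integer(strsplit(lines[ip[1]], "\\s+")[[1]][2])
  nums <- as.numeric(scan(text = paste(lines[(ip[1] + 1):length(lines)],
                                       collapse = " "),
                          what = numeric(), n = 3 * npts, quiet = TRUE))
  pos <- matrix(nums, ncol = 3, byrow = TRUE)
  ic <- grep("^(CELLS|POLYGONS)", lines)
  if (!length(ic)) stop("load_mesh: ", path, " has no CELLS/POLYGONS block")
  hd <- strsplit(lines[ic[1]], "\\s+")[[1]]
  ncell <- as.integer(hd[2]); ntok <- as.integer(hd[3])
  toks <- scan(text = paste(lines[(ic[1] + 1):length(lines)], collapse = " "),
               what = integer(), n = ntok, quiet = TRUE)
  cells <- list(); i <- 1
  while (length(cells) < ncell) {
    k <- toks[i]
    cells[[length(cells) + 1L]] <- toks[(i + 1):(i + k)] + 1L  # 0- to 1-based
    i <- i + k + 1
  }
  sizes <- lengths(cells)
  if (!all(sizes %in% c(2L, 3L, 4L)))
    stop("load_mesh: ", path,
         " has cells that are not lines, triangles or tets")
  edges <- unique(do.call(rbind, lapply(cells, function(cl)
    .edges_from_cells(matrix(cl, nrow = 1)))))
  mesh <- spring_mesh(pos, edges, ...)
  attr(mesh, "cells") <- cells
  mesh
}

#' Save a mesh to an OBJ or VTK legacy file
#'
#' Writes the node positions plus the original faces/cells when the mesh
#' carries them (from [load_mesh()] or [gen_ellipsoid_mesh()]); otherwise
#' the spring elements are written as VTK line cells (OBJ output then
#' requires faces). Topology round-trips identically through
#' `load_mesh(save_mesh(...))`.
#'
#' @param mesh A [spring_mesh()].
#' @param path Output path (`.obj` or `.vtk`).
#' @return `path`, invisibly.
#' @export
save_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  pos <- mesh$positions
  if (ext == "obj") {
    faces <- attr(mesh, "faces")
    if (is.null(faces)) stop("save_mesh: OBJ output needs triangle faces")
    writeLines(c(sprintf("v %.17g %.17g %.17g", pos[, 1], pos[, 2], pos[, 3]),
                 sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3])),
               path)
  } else if (ext == "vtk") {
    cells <- attr(mesh, "cells")
    if (is.null(cells)) {
      faces <- attr(mesh, "faces")
      cells <- if (!is.null(faces)) asplit(faces, 1)
               else asplit(mesh$elements, 1)
    }
    sizes <- lengths(cells)
    types <- c(`2` = 3L, `3` = 5L, `4` = 10L)[as.character(sizes)]
    body <- vapply(cells, function(cl)
      paste(c(length(cl), cl - 1L), collapse = " "), "")
    writeLines(c("# vtk DataFile Version 3.0", "eesm mesh", "ASCII",
                 "DATASET UNSTRUCTURED_GRID",
                 sprintf("POINTS %d double", nrow(pos)),
                 sprintf("%.17g %.17g %.17g", pos[, 1], pos[, 2], pos[, 3]),
                 sprintf("CELLS %d %d", length(cells),
                         sum(sizes) + length(cells)),
                 body,
                 sprintf("CELL_TYPES %d", length(cells)),
                 as.character(types)),
               path)
  } else stop("save_mesh: unsupported extension '", ext, "'")
  invisible(path)
}

#' Write a deformation frame series as VTK legacy files
#'
#' One `UNSTRUCTURED_GRID` file per frame (`<prefix>_NNNN.vtk`) with the
#' element connectivity as line cells, viewable as a time series in
#' standard VTK viewers.
#'
#' @param frames List of `n x 3` position matrices.
#' @param mesh The [spring_mesh()] providing connectivity.
#' @param prefix Output path prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_vtk_series <- function(frames, mesh, prefix) {
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    m2 <- mesh
    m2$positions <- frames[[i]]
    attr(m2, "cells") <- NULL
    attr(m2, "faces") <- NULL
    paths[i] <- save_mesh(m2, sprintf("%s_%04d.vtk", prefix, i))
  }
  invisible(paths)
}
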