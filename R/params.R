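#' Material parameter set for the equivalent-energy spring model
#'
#' Bundles the constants of the hybrid strain energy density: an isotropic
#' non-Gaussian (finite-extensibility) matrix phase mixed with an
#' "isotropized" anisotropic fibre phase, plus the Mullins stress-softening
#' and residual-strain constants.
#'
#' @param mu Shear-modulus-like constant of the non-Gaussian matrix (kPa),
#'   must be > 0.
#' @param N Number of chain links; the lock stretch of a chain is
#'   `sqrt(N)`, so `N > 1` is required.
#' @param b Dimensionless softening exponent, >= 0.
#' @param A1,A2 Energy constants of the isotropized anisotropic phase (kPa),
#'   >= 0.
#' @param C Residual-strain constant (kPa), >= 0.
#' @param f Anisotropic volume fraction in `[0, 1]`.
#' @param n Residual-strain fitting exponent (dimensionless, default 1).
#'
#' @return An object of class `material_params` (a named list).
#' @seealso [liver_params()] for the porcine-liver constants,
#'   [read_material_params()] / [write_material_params()] for JSON I/O.
#' @export
#' @examples
#' p <- material_params(mu = 0.1, N = 1.2, b = 3, A1 = 10, A2 = 7500,
#'                      C = 9.5, f = 0.27)
#' p$N
material_params <- function(mu, N, b, A1, A2, C, f, n = 1) {
  vals <- list(mu = mu, N = N, b = b, A1 = A1, A2 = A2, C = C, f = f, n = n)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("material_params: '", nm, "' must be a single finite number")
  }
  vals <- lapply(vals, as.numeric)  # storage mode independent of input/JSON
  if (mu <= 0) stop("material_params: mu must be > 0 (got ", mu, ")")
  if (N <= 1) stop("material_params: N must be > 1 (got ", N,
                   "); sqrt(N) is the lock stretch")
  if (b < 0) stop("material_params: b must be >= 0 (got ", b, ")")
  if (A1 < 0 || A2 < 0) stop("material_params: A1 and A2 must be >= 0")
  if (C < 0) stop("material_params: C must be >= 0 (got ", C, ")")
  if (f < 0 || f > 1) stop("material_params: f must lie in [0, 1] (got ", f, ")")
  structure(vals, class = "material_params")
}

#' Porcine-liver material constants
#'
#' The constants estimated from uniaxial loading/unloading tensile tests on
#' porcine liver parenchyma; used throughout the examples and tests as the
#' reference soft-tissue material.
#'
#' @return A [material_params()] object with mu = 0.1 kPa, N = 1.1974,
#'   b = 3.3389, A1 = 9.6754 kPa, A2 = 7543.6 kPa, C = 9.5273 kPa,
#'   f = 0.2755, n = 1.
#' @export
#' @examples
#' liver_params()
liver_params <- function() {
  material_params(mu = 0.1, N = 1.1974, b = 3.3389,
                  A1 = 9.6754, A2 = 7543.6, C = 9.5273,
                  f = 0.2755, n = 1)
}

#' @export
print.material_params <- function(x, ...) {
  cat("Equivalent-energy spring model material parameters\n")
  cat(sprintf("  mu = %g kPa   N = %g (lock stretch sqrt(N) = %.4f)\n",
              x$mu, x$N, sqrt(x$N)))
  cat(sprintf("  A1 = %g kPa   A2 = %g kPa   f = %g\n", x$A1, x$A2, x$f))
  cat(sprintf("  softening: b = %g   C = %g kPa   n = %g\n", x$b, x$C, x$n))
  invisible(x)
}

# JSON key <-> field mapping (units carried in the key names)
.params_json_keys <- c(mu = "mu_kPa", N = "N", b = "b", A1 = "A1_kPa",
                       A2 = "A2_kPa", C = "C_kPa", f = "f", n = "n")

#' Read and write material parameters as JSON
#'
#' Parameters are serialized as a flat JSON object with exactly the keys
#' `mu_kPa`, `N`, `b`, `A1_kPa`, `A2_kPa`, `C_kPa`, `f`, `n`. Values
#' round-trip exactly (full double precision is written).
#'
#' @param path File path of the JSON parameter file.
#' @param params A [material_params()] object.
#' @return `read_material_params()` returns a [material_params()] object;
#'   `write_material_params()` returns `path` invisibly.
#' @export
read_material_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- unname(.params_json_keys)
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file ", path, " is missing keys: ",
         paste(miss, collapse = ", "))
  material_params(mu = x$mu_kPa, N = x$N, b = x$b, A1 = x$A1_kPa,
                  A2 = x$A2_kPa, C = x$C_kPa, f = x$f, n = x$n)
}

#' @rdname read_material_params
#' @export
write_material_params <- function(params, path) {
  stopifnot(inherits(params, "material_params"))
  out <- stats::setNames(unclass(params)[names(.params_json_keys)],
                         unname(.params_json_keys))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
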