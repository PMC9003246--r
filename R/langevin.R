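#' Langevin function
#'
#' `L(beta) = coth(beta) - 1/beta`, the chain-statistics function whose
#' inverse governs finite-extensibility stiffening. The removable
#' singularity at `beta = 0` is handled by the Taylor series
#' `beta/3 - beta^3/45 + 2 beta^5/945 - beta^7/4725` for `|beta| < 0.15`
#' (below that threshold the series truncation error is < 1e-12 while the
#' direct form starts losing digits to cancellation).
#'
#' @param beta Numeric vector, >= 0.
#' @return `L(beta)`, in `[0, 1)`.
#' @export
#' @examples
#' langevin(0)            # 0
#' langevin(1e6)          # ~1 (saturation)
langevin <- function(beta) {
  if (any(beta < 0)) stop("langevin: beta must be >= 0")
  out <- numeric(length(beta))
  small <- beta < 0.15
  b <- beta[small]
  out[small] <- b / 3 - b^3 / 45 + 2 * b^5 / 945 - b^7 / 4725
  b <- beta[!small]
  out[!small] <- 1 / tanh(b) - 1 / b
  out
}

#' Puso approximation to the inverse Langevin function
#'
#' The Pade-type approximant `beta = 3 lam_r / (1 - lam_r^3)`, used inside
#' the non-Gaussian strain energy density. Monotone increasing on `[0, 1)`
#' and divergent as `lam_r -> 1` (the chain lock limit).
#'
#' @param lam_r Relative chain stretch, in `[0, 1)`.
#' @return The approximate inverse Langevin value `beta`.
#' @seealso [inv_langevin()] for the exact (Newton-iterated) inverse used
#'   as a cross-check.
#' @export
#' @examples
#' inv_langevin_puso(0.5)   # 1.714286
inv_langevin_puso <- function(lam_r) {
  bad <- !is.finite(lam_r) | lam_r < 0 | lam_r >= 1
  if (any(bad))
    stop("inv_langevin_puso: lam_r must lie in [0, 1); got ",
         paste(utils::head(lam_r[bad], 3), collapse = ", "))
  3 * lam_r / (1 - lam_r^3)
}

# d beta / d lam_r of the Puso approximant
.inv_langevin_puso_deriv <- function(lam_r) {
  (3 + 6 * lam_r^3) / (1 - lam_r^3)^2
}

#' Exact inverse Langevin function by Newton iteration
#'
#' Solves `coth(beta) - 1/beta = x` to machine precision, starting from the
#' Puso approximant. Serves as the independent reference when quantifying
#' the Puso approximation error; it is never used inside the constitutive
#' evaluation path.
#'
#' @param x Values in `[0, 1)`.
#' @param tol Convergence tolerance on `|L(beta) - x|`.
#' @return `beta` such that `langevin(beta) == x` within `tol`.
#' @export
inv_langevin <- function(x, tol = 1e-14) {
  if (any(x < 0 | x >= 1)) stop("inv_langevin: x must lie in [0, 1)")
  beta <- inv_langevin_puso(x)
  # L'(beta) = 1/beta^2 - csch(beta)^2; series 1/3 - beta^2/15 near 0
  for (it in 1:100) {
    r <- langevin(beta) - x
    if (all(abs(r) <= tol)) break
    small <- beta < 1e-4
    dL <- numeric(length(beta))
    dL[small] <- 1 / 3 - beta[small]^2 / 15
    bb <- beta[!small]
    dL[!small] <- 1 / bb^2 - 1 / sinh(bb)^2
    beta <- pmax(beta - r / dL, .Machine$double.eps)
  }
  beta
}
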