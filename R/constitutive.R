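#' Uniaxial kinematic state
#'
#' For incompressible simple extension the principal stretches are
#' `(lam, lam^-1/2, lam^-1/2)`, which keeps the third invariant
#' `I3 = 1` identically. This helper derives the invariants and the
#' chain-statistics quantities used by the strain energy density, plus the
#' Mullins softening variables `m` (current) and `M` (at the reversal
#' stretch `lam_max`).
#'
#' @param lam Axial stretch (vector), > 0.
#' @param params A [material_params()] object (for the chain-link count N).
#' @param lam_max Reversal stretch defining the softening history
#'   (default `lam`, i.e. a point on the primary loading path).
#' @return A data frame of class `uniaxial_state` with columns `lam`,
#'   `lam2`, `I1`, `I3`, `lam_chain`, `lam_r`, `m`, `M`.
#' @export
#' @examples
#' uniaxial_state(c(1, 1.15, 1.3), liver_params())
uniaxial_state <- function(lam, params, lam_max = lam) {
  stopifnot(inherits(params, "material_params"))
  if (any(lam <= 0)) stop("uniaxial_state: lam must be > 0")
  lam2 <- lam^(-0.5)
  I1 <- lam^2 + 2 / lam
  lam_chain <- sqrt(I1 / 3)
  lam_r <- lam_chain / sqrt(params$N)
  sv <- softening_variables(pmin(lam, lam_max), lam_max)
  out <- data.frame(lam = lam, lam2 = lam2, I1 = I1, I3 = rep(1, length(lam)),
                    lam_chain = lam_chain, lam_r = lam_r,
                    m = sv$m, M = sv$M)
  class(out) <- c("uniaxial_state", class(out))
  out
}

# Relative chain stretch for axial stretch lam; guards the lock limit.
.lam_r <- function(lam, params) {
  lr <- sqrt((lam^2 + 2 / lam) / (3 * params$N))
  if (any(lr >= 0.999999))
    stop("chain lock limit reached: lam_r = ",
         signif(max(lr), 6), " at lam = ", signif(lam[which.max(lr)], 6),
         " (lock stretch sqrt(N) = ", signif(sqrt(params$N), 6), ")")
  lr
}

.coerce_lam <- function(state) {
  if (inherits(state, "uniaxial_state")) state$lam else state
}

#' Isotropic non-Gaussian strain energy density
#'
#' The finite-extensibility (Langevin-chain) energy of the matrix phase,
#' `mu * [N (beta lam_r + log(beta / sinh beta)) - log(beta lam_r)] + c`,
#' with `beta` from the Puso inverse-Langevin approximant and the
#' integration constant `c` fixed so that the energy vanishes in the
#' undeformed state (`lam = 1`). Zero rest energy keeps the equivalent
#' spring-stiffness conversion well behaved near `lam = 1`.
#'
#' @param state A [uniaxial_state()] or a numeric vector of axial stretches.
#' @param params A [material_params()] object.
#' @return Energy density in kPa.
#' @export
w_iso <- function(state, params) {
  lam <- .coerce_lam(state)
  lr <- .lam_r(lam, params)
  .w_iso_bracket(lr, params) - .w_iso_bracket(.lam_r(1, params), params)
}

# mu * [ N (beta lam_r + log(beta/sinh beta)) - log(beta lam_r) ]
# log(beta/sinh(beta)) computed overflow-safely: log(2 beta) - beta - log1p(-exp(-2 beta))
.w_iso_bracket <- function(lam_r, params) {
  beta <- inv_langevin_puso(lam_r)
  log_b_over_sinh <- log(2 * beta) - beta - log1p(-exp(-2 * beta))
  params$mu * (params$N * (beta * lam_r + log_b_over_sinh) - log(beta * lam_r))
}

#' Isotropized anisotropic strain energy density
#'
#' Quadratic-in-`(I1 - 3)` energy representing the fibre contribution after
#' isotropization: `A1/3 (I1-3) + A2/9 (I1-3)^2 - (2 A1/3) log(sqrt(I3))`.
#' Under the incompressible uniaxial kinematics used here `I3 = 1`, so the
#' logarithmic term vanishes identically.
#'
#' @inheritParams w_iso
#' @return Energy density in kPa.
#' @export
w_aniso <- function(state, params) {
  lam <- .coerce_lam(state)
  I1 <- lam^2 + 2 / lam
  params$A1 / 3 * (I1 - 3) + params$A2 / 9 * (I1 - 3)^2
}

#' Total (mixture) strain energy density
#'
#' `W_T = (1 - f) W_iso + f W_aniso`; zero at `lam = 1` and strictly
#' increasing in `lam` for tensile stretches with physical constants.
#'
#' @inheritParams w_iso
#' @return Energy density in kPa.
#' @export
#' @examples
#' w_total(c(1, 1.15, 1.3), liver_params())
w_total <- function(state, params) {
  lam <- .coerce_lam(state)
  (1 - params$f) * w_iso(lam, params) + params$f * w_aniso(lam, params)
}

#' Non-Gaussian response function
#'
#' The isotropic-phase response function `aleph` entering the Cauchy stress
#' as `T_iso_i = aleph * lam_i^2 - p`. It is the exact derivative of the
#' isotropic energy with respect to the first invariant (times two):
#' `aleph = (dW_iso/dlam_r) / (3 N lam_r)` with
#' `dW_iso/dlam_r = mu (N (beta + beta' (lam_r - L(beta))) - beta'/beta - 1/lam_r)`
#' where `beta`, `beta'` are the Puso approximant and its derivative and
#' `L` the Langevin function. The `beta' (lam_r - L(beta))` correction is
#' what makes the closed-form stress the exact derivative of the energy as
#' implemented: it would vanish if `beta` were the exact inverse Langevin,
#' and stays below the Puso approximation error otherwise. Tends to a
#' finite positive limit (the initial modulus contribution) as `lam -> 1`.
#'
#' @inheritParams w_iso
#' @return Response function value in kPa.
#' @export
response_fn <- function(state, params) {
  lam <- .coerce_lam(state)
  lr <- .lam_r(lam, params)
  beta <- inv_langevin_puso(lr)
  dbeta <- .inv_langevin_puso_deriv(lr)
  dW_dlr <- params$mu *
    (params$N * (beta + dbeta * (lr - langevin(beta))) - dbeta / beta - 1 / lr)
  dW_dlr / (3 * params$N * lr)
}

# Bracket of the virgin Cauchy stress difference:
# (1 - f) aleph + (2 f / 3) (A1 + (2 A2 / 3)(I1 - 3))
.stress_bracket <- function(lam, params) {
  I1 <- lam^2 + 2 / lam
  (1 - params$f) * response_fn(lam, params) +
    2 * params$f / 3 * (params$A1 + 2 * params$A2 / 3 * (I1 - 3))
}

#' Virgin-material engineering stress
#'
#' Engineering (first Piola) uniaxial stress of the never-softened
#' material. The hydrostatic pressure is eliminated by forming the Cauchy
#' stress difference `T1 - T2` with traction-free lateral faces, then
#' converting by `sigma = T / lam`:
#' `sigma(lam) = bracket(lam) * (lam - lam^-2)` where the bracket combines
#' the non-Gaussian response function and the anisotropic terms. This
#' closed form equals the derivative `dW_T/dlam` of the uniaxial energy.
#'
#' @param lam Axial stretch (vector), >= 1.
#' @param params A [material_params()] object.
#' @return A data frame of class `stress_point` with columns `lam`,
#'   `sigma` (kPa), `branch` (`"virgin"`), `lam_max` (`NA`).
#' @export
#' @examples
#' virgin_stress(c(1, 1.1, 1.2, 1.3), liver_params())
virgin_stress <- function(lam, params) {
  if (any(lam < 1)) stop("virgin_stress: lam must be >= 1 (tension only)")
  sigma <- .stress_bracket(lam, params) * (lam - lam^-2)
  structure(data.frame(lam = lam, sigma = sigma, branch = "virgin",
                       lam_max = NA_real_),
            class = c("stress_point", "data.frame"))
}

#' Mullins softening variables
#'
#' `m = sqrt(lam^4 + 2 lam^-2)` is the deformation magnitude driving
#' softening and `M = m(lam_max)` its value at the reversal point, so that
#' `m = M` exactly at reversal (where the softening factor must be 1).
#' `m(1) = sqrt(3)` and `m` is strictly increasing on `lam >= 1`.
#'
#' @param lam Current stretch, in `[1, lam_max]`.
#' @param lam_max Reversal stretch (maximum stretch on the primary path).
#' @return A list with vectors `m` and `M`.
#' @export
softening_variables <- function(lam, lam_max) {
  if (any(lam > lam_max + 1e-12))
    stop("softening_variables: lam (", signif(max(lam), 6),
         ") exceeds lam_max (", signif(min(lam_max), 6), ")")
  list(m = sqrt(lam^4 + 2 * lam^-2),
       M = sqrt(lam_max^4 + 2 * lam_max^-2))
}

#' Mullins softening factor
#'
#' `exp(-b sqrt(M - m)) * sqrt(m / M)`, in `(0, 1]`: equal to 1 at the
#' reversal point (`m = M`, virgin response recovered) and monotonically
#' decreasing as the material unloads away from it.
#'
#' @param m Current softening variable (from [softening_variables()]).
#' @param M Softening variable at the reversal stretch.
#' @param b Softening exponent, >= 0.
#' @return The softening factor.
#' @export
softening_factor <- function(m, M, b) {
  if (any(m <= 0)) stop("softening_factor: m must be > 0")
  if (any(m > M + 1e-12))
    stop("softening_factor: m (", signif(max(m), 6),
         ") exceeds M (", signif(min(M), 6), ")")
  exp(-b * sqrt(pmax(M - m, 0))) * sqrt(m / M)
}

#' Residual-strain derivative terms
#'
#' The gradient `g_k = dPhi/dlam_k` of
#' `Phi = sum_a (lam_max_a^n - lam_a^2)^2`, i.e.
#' `g_k = -4 lam_k (lam_max_k^n - lam_k^2)`, evaluated on the uniaxial
#' principal stretches `(lam, lam^-1/2, lam^-1/2)` with reversal stretches
#' `(lam_max, lam_max^-1/2, lam_max^-1/2)`. These terms inject the residual
#' strain into the softened stress; each `g_k` vanishes where
#' `lam_k^2 = lam_max_k^n`.
#'
#' @param lam Current stretch, in `[1, lam_max]`.
#' @param lam_max Reversal stretch.
#' @param n Residual-strain exponent (default 1).
#' @return A list with vectors `g1`, `g2`, `g3` (`g3 == g2` by symmetry).
#' @export
residual_g <- function(lam, lam_max, n = 1) {
  lam2 <- lam^(-0.5)
  lmax2 <- lam_max^(-0.5)
  g1 <- -4 * lam * (lam_max^n - lam^2)
  g2 <- -4 * lam2 * (lmax2^n - lam2^2)
  list(g1 = g1, g2 = g2, g3 = g2)
}

#' Stress-softened engineering stress (unloading branch)
#'
#' Engineering stress on the unloading/reloading path below the historical
#' maximum stretch `lam_max`: the virgin Cauchy stress difference plus the
#' residual-strain term `mu lam2^2 C (lam1 g1 - lam2 g2)`, the whole
#' multiplied by the [softening_factor()] and converted to engineering
#' stress. For `C > 0` the softened stress crosses zero at a residual
#' stretch `lam_res > 1` (see [residual_stretch()]).
#'
#' Note the softened branch is not exactly continuous with the virgin curve
#' at the reversal point when `n = 1`: the residual-strain term does not
#' vanish at `lam = lam_max`, leaving a small stress step there (about 1%
#' of the virgin stress for the liver constants at `lam_max = 1.3`). This
#' is a property of the constitutive form as written, reported by
#' [reversal_stress_gap()].
#'
#' @param lam Stretch on the unloading path, in `[1, lam_max]`.
#' @param lam_max Reversal stretch.
#' @param params A [material_params()] object.
#' @return A `stress_point` data frame with `branch = "softened"`.
#' @export
#' @examples
#' softened_stress(seq(1, 1.3, by = 0.05), 1.3, liver_params())
softened_stress <- function(lam, lam_max, params) {
  if (any(lam < 1)) stop("softened_stress: lam must be >= 1")
  if (any(lam > lam_max + 1e-12))
    stop("softened_stress: lam exceeds lam_max = ", lam_max)
  lam <- pmin(lam, lam_max)
  lam2sq <- 1 / lam
  g <- residual_g(lam, lam_max, params$n)
  virgin_diff <- .stress_bracket(lam, params) * (lam^2 - 1 / lam)
  resid <- params$mu * lam2sq * params$C *
    (lam * g$g1 - lam^(-0.5) * g$g2)
  sv <- softening_variables(lam, lam_max)
  fac <- softening_factor(sv$m, sv$M, params$b)
  sigma <- (virgin_diff + resid) * fac / lam
  structure(data.frame(lam = lam, sigma = sigma, branch = "softened",
                       lam_max = lam_max),
            class = c("stress_point", "data.frame"))
}

#' Residual stretch of an unloading branch
#'
#' The stretch `lam_res` in `(1, lam_max)` at which the softened
#' engineering stress crosses zero: the permanent-set stretch left after
#' unloading from `lam_max`. Found by root bracketing/bisection on
#' [softened_stress()]. Returns 1 when the softened stress is already
#' non-negative at `lam = 1` (e.g. `C = 0`, no residual strain).
#'
#' @param lam_max Reversal stretch.
#' @param params A [material_params()] object.
#' @param tol Root tolerance on `lam`.
#' @return The residual stretch (scalar).
#' @export
#' @examples
#' residual_stretch(1.3, liver_params())
residual_stretch <- function(lam_max, params, tol = 1e-10) {
  fn <- function(l) softened_stress(l, lam_max, params)$sigma
  lo <- 1
  if (fn(lo) >= 0) return(1)
  hi <- lam_max
  if (fn(hi) <= 0)
    stop("residual_stretch: softened stress non-positive on the whole branch")
  stats::uniroot(fn, c(lo, hi), tol = tol)$root
}

#' Stress step between softened and virgin branches at reversal
#'
#' Magnitude of the (engineering) stress discontinuity
#' `sigma_softened(lam_max) - sigma_virgin(lam_max)` left by the
#' residual-strain term at the reversal point (zero only when `C = 0` or
#' the term happens to vanish, e.g. `n = 2`).
#'
#' @inheritParams residual_stretch
#' @return Stress gap in kPa (positive: softened branch starts above the
#'   virgin curve).
#' @export
reversal_stress_gap <- function(lam_max, params) {
  softened_stress(lam_max, lam_max, params)$sigma -
    virgin_stress(lam_max, params)$sigma
}

#' Finite-difference stress oracle
#'
#' Independent check of the closed-form virgin stress: the central
#' difference `[W_T(lam + h) - W_T(lam - h)] / (2 h)` of the incompressible
#' uniaxial strain energy density, which for this kinematics equals the
#' engineering stress. Second-order accurate in `h`; default `h = 1e-5`.
#' Requires `lam > 1 + h` (stretches too close to 1 would need the
#' out-of-domain value at `lam - h`; an error is raised rather than
#' silently switching to a one-sided difference).
#'
#' @param lam Axial stretch (vector), each > `1 + h`.
#' @param params A [material_params()] object.
#' @param h Step size.
#' @return Numeric vector of engineering stresses (kPa).
#' @export
numeric_stress_oracle <- function(lam, params, h = 1e-5) {
  if (any(lam <= 1 + h))
    stop("numeric_stress_oracle: lam must exceed 1 + h = ", 1 + h)
  (w_total(lam + h, params) - w_total(lam - h, params)) / (2 * h)
}
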