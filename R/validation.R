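# Independent analytic references and brute-force oracles used by the test
# suite: semi-infinite erf cooling, the classical two-phase Neumann-Stefan
# solution, and a dense loop-per-node reference stepper.  Exposed as part of
# the API so users extending the material library can validate their setups.

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Semi-infinite constant-property cooling profile
#'
#' Closed-form solution for a half-space initially at `T_init` whose surface
#' is held at `T_wall`:
#' `T(z, t) = T_wall + (T_init - T_wall) * erf(z / (2 sqrt(alpha t)))`.
#'
#' @param T_init initial temperature, degrees C.
#' @param T_wall wall temperature, degrees C.
#' @param alpha thermal diffusivity, m^2/s.
#' @param z depth(s), m.
#' @param t time, s (`> 0`).
#' @return temperature(s), degrees C.
#' @export
semi_infinite_profile <- function(T_init, T_wall, alpha, z, t) {
  stopifnot(t > 0, alpha > 0)
  T_wall + (T_init - T_wall) * erf(z / (2 * sqrt(alpha * t)))
}

#' Parameters of the two-phase Neumann-Stefan problem
#'
#' Constant per-phase properties for the classical one-dimensional
#' solidification problem: a half-space of liquid at `T_init` whose wall is
#' suddenly held at `T_wall` below the (sharp) phase-change temperature
#' `T_phase`.
#'
#' @param alpha_s,alpha_l frozen / unfrozen diffusivities, m^2/s.
#' @param k_s,k_l frozen / unfrozen conductivities, W/(m K).
#' @param L latent heat, J/kg.
#' @param rho density (common to both phases), kg/m^3.
#' @param T_wall,T_phase,T_init temperatures, degrees C, with
#'   `T_wall < T_phase < T_init`.
#' @return a validated list of class `neumann_params`.
#' @export
neumann_params <- function(alpha_s, alpha_l, k_s, k_l, L, rho,
                           T_wall, T_phase, T_init) {
  stopifnot(alpha_s > 0, alpha_l > 0, k_s > 0, k_l > 0, L > 0, rho > 0,
            T_wall < T_phase, T_phase < T_init)
  structure(list(alpha_s = alpha_s, alpha_l = alpha_l, k_s = k_s, k_l = k_l,
                 L = L, rho = rho, T_wall = T_wall, T_phase = T_phase,
                 T_init = T_init),
            class = "neumann_params")
}

#' Neumann similarity root
#'
#' Solves the transcendental Stefan balance for the similarity constant
#' `lambda` (front at `X(t) = 2 lambda sqrt(alpha_s t)`):
#' `St_s e^{-lambda^2} / (sqrt(pi) erf(lambda))
#'  - St_l e^{-nu^2 lambda^2} / (nu sqrt(pi) erfc(nu lambda)) - lambda = 0`
#' with `St_s = c_s (T_phase - T_wall) / L`,
#' `St_l = c_l (T_init - T_phase) / L`, `nu = sqrt(alpha_s / alpha_l)` and
#' `c = k / (rho alpha)` per phase.  Bracketed root search; the residual at
#' the returned root is below 1e-12.
#'
#' @param params a `neumann_params`.
#' @return `lambda` (dimensionless).
#' @export
neumann_lambda <- function(params) {
  p <- params
  c_s <- p$k_s / (p$rho * p$alpha_s)
  c_l <- p$k_l / (p$rho * p$alpha_l)
  St_s <- c_s * (p$T_phase - p$T_wall) / p$L
  St_l <- c_l * (p$T_init - p$T_phase) / p$L
  nu <- sqrt(p$alpha_s / p$alpha_l)
  g <- function(lam)
    St_s * exp(-lam^2) / (sqrt(pi) * erf(lam)) -
      St_l * exp(-nu^2 * lam^2) / (nu * sqrt(pi) * erfc(nu * lam)) - lam
  lo <- 1e-9; hi <- 6
  if (g(lo) <= 0 || g(hi) >= 0)
    stop("no sign change in the lambda bracket [1e-9, 6]")
  lam <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.9,
                        maxiter = 2000)$root
  if (abs(g(lam)) >= 1e-12)
    stop("Neumann root did not converge: residual ", abs(g(lam)))
  lam
}

#' Neumann front position
#'
#' Position of the sharp freezing front, `X(t) = 2 lambda sqrt(alpha_s t)`.
#'
#' @param params a `neumann_params`.
#' @param t time(s), s.
#' @return front position(s), m.
#' @export
neumann_front_position <- function(params, t) {
  2 * neumann_lambda(params) * sqrt(params$alpha_s * t)
}

#' Dense reference time step
#'
#' Independent loop-per-node re-implementation of the explicit five-point
#' update with no masking shortcuts or pair-sharing, used as the oracle in
#' equivalence tests against the compiled stepper.  It consumes the same
#' property lookup tables the kernel uses (via an R-side mirror of the
#' interpolation), so any disagreement isolates a defect in the stencil,
#' masking or radial weighting.  Limited to small grids.
#'
#' @param field temperature storage matrix.
#' @param grid a `cryo_grid` (at most 64 x 64 interior nodes).
#' @param materials material registry matching the grid.
#' @param dt time step, s.
#' @param nsteps number of steps.
#' @param fixed logical storage matrix of non-updated nodes.
#' @param mat optional material mask override.
#' @return the updated temperature matrix.
#' @export
reference_step_dense <- function(field, grid,
                                 materials = material_library(), dt,
                                 nsteps = 1L,
                                 fixed = grid$fixed | grid$applicator,
                                 mat = grid$mat) {
  check_library_matches_grid(grid, materials)
  stopifnot(grid$N_z <= 64, grid$N_r <= 64)
  nz <- nrow(field); nr <- ncol(field)
  km <- kernel_materials(materials)
  A <- matrix(as.numeric(field), nz, nr)
  harm <- function(k1, k2) if (k1 + k2 > 0) 2 * k1 * k2 / (k1 + k2) else 0
  prop <- function(which, m, T)
    lut_eval(km[[m]][[which]], km[[m]]$lut_lo, km[[m]]$lut_inv_step, T)
  for (s in seq_len(nsteps)) {
    K <- matrix(0, nz, nr)
    for (i in seq_len(nz)) for (j in seq_len(nr))
      if (mat[i, j] > 0L) K[i, j] <- prop("k_lut", mat[i, j], A[i, j])
    B <- A
    for (j in 2:(nr - 1)) {
      for (i in 2:(nz - 1)) {
        if (mat[i, j] == 0L || fixed[i, j]) next
        Tij <- A[i, j]
        kup <- harm(K[i, j], K[i - 1, j])
        kdn <- harm(K[i, j], K[i + 1, j])
        klf <- harm(K[i, j], K[i, j - 1])
        krt <- harm(K[i, j], K[i, j + 1])
        num <- (kdn * (A[i + 1, j] - Tij) + kup * (A[i - 1, j] - Tij)) /
                 (grid$dz * grid$dz) +
               (krt * grid$r_plus[j] * (A[i, j + 1] - Tij) +
                klf * grid$r_minus[j] * (A[i, j - 1] - Tij)) /
                 (grid$r_storage[j] * grid$dr * grid$dr)
        B[i, j] <- Tij + dt * num * prop("invC_lut", mat[i, j], Tij)
      }
    }
    A <- B
  }
  A
}
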