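# HGO fiber-reinforced nearly-incompressible hyperelasticity.
#
# W = C10 (I1bar - 3) + (1/D) ((J^2 - 1)/2 - ln J)
#   + sum_i k1/(2 k2) [exp(k2 eps_i^2) - 1],   eps_i > 0 only,
# eps_i = kappa (I1bar - 3) + (1 - 3 kappa) (Iibar - 1),  i in {4, 6}.
#
# Local material frame: e1 = circumferential, e2 = axial, e3 = radial.
# Fiber families M = (cos theta, sin theta, 0), N = (cos theta, -sin theta, 0).

#' HGO material parameter set
#'
#' Constructs a validated parameter set for the Holzapfel--Gasser--Ogden
#' (HGO) model of the arterial wall with two symmetric dispersed collagen
#' fiber families.
#'
#' @param C10 Ground-matrix (neo-Hookean) constant, kPa.
#' @param k1 Fiber stiffness, kPa.
#' @param k2 Dimensionless fiber stiffening exponent, > 0.
#' @param kappa Fiber dispersion parameter in [0, 1/3]; 1/3 is isotropic
#'   dispersion, at which the response loses all dependence on the fiber
#'   invariants.
#' @param theta_deg Mean fiber angle measured from the circumferential
#'   direction, degrees.
#' @param D Volumetric compliance, 1/kPa; the bulk term is
#'   (1/D)((J^2-1)/2 - ln J). Small D enforces near-incompressibility.
#' @return An object of class `hgo_params`.
#' @seealso [hgo_media()], [hgo_adventitia()] for the bundled human aortic
#'   wall parameter sets.
#' @export
hgo_params <- function(C10, k1, k2, kappa, theta_deg, D) {
  stopifnot(is.numeric(C10), is.numeric(k1), is.numeric(k2),
            is.numeric(kappa), is.numeric(theta_deg), is.numeric(D))
  if (k2 <= 0) stop("k2 must be positive")
  if (kappa < 0 || kappa > 1 / 3) stop("kappa must lie in [0, 1/3]")
  if (D <= 0) stop("D must be positive")
  if (k1 < 0) stop("k1 must be non-negative")
  structure(list(C10 = C10, k1 = k1, k2 = k2, kappa = kappa,
                 theta_deg = theta_deg, D = D),
            class = "hgo_params")
}

#' @export
print.hgo_params <- function(x, ...) {
  cat("HGO material parameters (kPa/mm units):\n")
  cat(sprintf("  C10 = %g kPa, k1 = %g kPa, k2 = %g\n", x$C10, x$k1, x$k2))
  cat(sprintf("  kappa = %g, theta = %g deg, D = %g 1/kPa\n",
              x$kappa, x$theta_deg, x$D))
  invisible(x)
}

# Bundled constants (loaded from inst/extdata/hgo_human_aorta.yaml)
.load_bulk_constants <- function() {
  path <- system.file("extdata", "hgo_human_aorta.yaml", package = "aortafem")
  yaml::read_yaml(path)
}

#' Bundled human aortic media / adventitia HGO parameters
#'
#' Parameter sets for the medial and adventitial layers of the human
#' thoracic aorta, as determined from biaxial testing, bundled with the
#' package in `extdata/hgo_human_aorta.yaml`. Fibers are nearly exactly
#' circumferential (theta below 0.001 degrees).
#'
#' @return An `hgo_params` object.
#' @export
hgo_media <- function() {
  p <- .load_bulk_constants()$media
  hgo_params(p$C10_kPa, p$k1_kPa, p$k2, p$kappa, p$theta_deg, p$D_per_kPa)
}

#' @rdname hgo_media
#' @export
hgo_adventitia <- function() {
  p <- .load_bulk_constants()$adventitia
  hgo_params(p$C10_kPa, p$k1_kPa, p$k2, p$kappa, p$theta_deg, p$D_per_kPa)
}

#' Kinematic quantities entering the HGO energy
#'
#' Computes, from a deformation gradient expressed in the local
#' circumferential--axial--radial frame, the volume ratio, the isochoric
#' right Cauchy--Green tensor, its invariants, and the fiber strain-like
#' quantities of the two fiber families.
#'
#' @param F Deformation gradient, 3x3 matrix, det F > 0.
#' @param theta_deg Mean fiber angle from the circumferential direction,
#'   degrees.
#' @return An object of class `hgo_kinematics` with fields `F`, `J`,
#'   `Cbar`, `I1bar`, `I4bar`, `I6bar`, `M`, `N`, `eps1`, `eps2`,
#'   `kappa_pending` (eps values require kappa, so they are returned as a
#'   function of kappa by [strain_energy_density()]; the `eps1`/`eps2`
#'   stored here are the dispersion-free fiber stretch measures
#'   `I4bar - 1` and `I6bar - 1`).
#' @export
compute_kinematics <- function(F, theta_deg) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3L, 3L)), all(is.finite(F)))
  J <- det(F)
  if (J <= 0) stop("invalid deformation: det F must be positive")
  C <- crossprod(F)            # F^T F
  Cbar <- J^(-2 / 3) * C
  th <- theta_deg * pi / 180
  M <- c(cos(th), sin(th), 0)
  N <- c(cos(th), -sin(th), 0)
  I1bar <- sum(diag(Cbar))
  I4bar <- drop(M %*% Cbar %*% M)
  I6bar <- drop(N %*% Cbar %*% N)
  structure(list(F = F, J = J, C = C, Cbar = Cbar,
                 I1bar = I1bar, I4bar = I4bar, I6bar = I6bar,
                 M = M, N = N, theta_deg = theta_deg),
            class = "hgo_kinematics")
}

# fiber strain-like quantities eps_i for a given parameter set
.hgo_eps <- function(state, p) {
  c(eps1 = p$kappa * (state$I1bar - 3) + (1 - 3 * p$kappa) * (state$I4bar - 1),
    eps2 = p$kappa * (state$I1bar - 3) + (1 - 3 * p$kappa) * (state$I6bar - 1))
}

#' Strain energy density of the HGO model
#'
#' Evaluates the strain energy per unit reference volume. A fiber family
#' contributes only while its strain-like quantity is positive
#' (tension-only convention; compressed fibers store no energy).
#'
#' @param state An `hgo_kinematics` object from [compute_kinematics()].
#' @param p An `hgo_params` object.
#' @return Energy per reference volume, kPa. Non-finite (with a warning)
#'   if the exponential fiber term overflows.
#' @export
strain_energy_density <- function(state, p) {
  stopifnot(inherits(state, "hgo_kinematics"), inherits(p, "hgo_params"))
  J <- state$J
  W <- p$C10 * (state$I1bar - 3) + (1 / p$D) * ((J^2 - 1) / 2 - log(J))
  eps <- .hgo_eps(state, p)
  for (e in eps) {
    if (e > 0 && p$k1 > 0) {
      W <- W + p$k1 / (2 * p$k2) * (exp(p$k2 * e^2) - 1)
    }
  }
  if (!is.finite(W)) warning("non-finite strain energy (fiber term overflow)")
  W
}

# Second Piola-Kirchhoff stress S = 2 dW/dC, local frame.
.hgo_pk2 <- function(state, p) {
  J <- state$J
  C <- state$C
  Cinv <- solve(C)
  I3 <- diag(3)
  Jm23 <- J^(-2 / 3)
  # d I1bar / dC, d I4bar / dC, d I6bar / dC
  dI1 <- Jm23 * I3 - (state$I1bar / 3) * Cinv
  MM <- tcrossprod(state$M)
  NN <- tcrossprod(state$N)
  dI4 <- Jm23 * MM - (state$I4bar / 3) * Cinv
  dI6 <- Jm23 * NN - (state$I6bar / 3) * Cinv
  eps <- .hgo_eps(state, p)
  psi1 <- if (eps[1] > 0) p$k1 * eps[1] * exp(p$k2 * eps[1]^2) else 0
  psi2 <- if (eps[2] > 0) p$k1 * eps[2] * exp(p$k2 * eps[2]^2) else 0
  Siso <- 2 * (p$C10 * dI1 +
               psi1 * (p$kappa * dI1 + (1 - 3 * p$kappa) * dI4) +
               psi2 * (p$kappa * dI1 + (1 - 3 * p$kappa) * dI6))
  # volumetric: dWvol/dJ = (1/D)(J - 1/J); dJ/dC = J/2 Cinv
  Svol <- (1 / p$D) * (J - 1 / J) * J * Cinv
  Siso + Svol
}

#' First Piola-Kirchhoff stress
#'
#' @param state An `hgo_kinematics` object.
#' @param p An `hgo_params` object.
#' @return 3x3 first Piola-Kirchhoff (nominal) stress, kPa, in the local
#'   frame of `state`.
#' @export
pk1_stress <- function(state, p) {
  state$F %*% .hgo_pk2(state, p)
}

#' Cauchy stress of the HGO model
#'
#' sigma = J^-1 P F^T with P the first Piola-Kirchhoff stress; symmetric,
#' and exactly zero in the reference configuration.
#'
#' @inheritParams pk1_stress
#' @return Symmetric 3x3 Cauchy stress, kPa.
#' @export
cauchy_stress <- function(state, p) {
  sig <- (1 / state$J) * pk1_stress(state, p) %*% t(state$F)
  (sig + t(sig)) / 2   # symmetrize roundoff
}

#' Consistent material tangent (spatial elasticity tensor)
#'
#' Computes the material elasticity tensor CC = 2 dS/dC by central
#' differencing of the analytic second Piola-Kirchhoff stress over
#' symmetric perturbations of C, then pushes it forward to the spatial
#' tensor c_ijkl = J^-1 F_iA F_jB F_kC F_lD CC_ABCD. Both minor symmetries
#' and the major symmetry hold by construction.
#'
#' @inheritParams pk1_stress
#' @param h Relative perturbation for the differencing (default 1e-6).
#' @return A 3x3x3x3 array, kPa: the spatial elasticity tensor.
#' @export
material_tangent <- function(state, p, h = 1e-6) {
  F <- state$F
  CC <- array(0, c(3, 3, 3, 3))
  scale <- max(abs(state$C))
  for (A in 1:3) for (B in A:3) {
    dC <- matrix(0, 3, 3)
    dC[A, B] <- dC[B, A] <- h * scale / 2   # symmetric perturbation
    Sp <- .hgo_pk2(.state_from_C(state$C + dC, state$theta_deg), p)
    Sm <- .hgo_pk2(.state_from_C(state$C - dC, state$theta_deg), p)
    dS <- (Sp - Sm) / (h * scale)           # dS/dC_AB (+ dS/dC_BA if A != B)
    mult <- if (A == B) 2 else 1            # CC = 2 dS/dC
    CC[, , A, B] <- mult * dS
    CC[, , B, A] <- mult * dS
  }
  # push forward
  cc <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    acc <- 0
    for (A in 1:3) for (B in 1:3) for (Cc in 1:3) for (Dd in 1:3) {
      acc <- acc + F[i, A] * F[j, B] * F[k, Cc] * F[l, Dd] * CC[A, B, Cc, Dd]
    }
    cc[i, j, k, l] <- acc / state$J
  }
  cc
}

# kinematic state from a right Cauchy-Green tensor (for tangent FD):
# uses the principal square root, which leaves all invariants intact.
.state_from_C <- function(C, theta_deg) {
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  F <- e$vectors %*% diag(sqrt(pmax(e$values, .Machine$double.eps))) %*%
    t(e$vectors)
  compute_kinematics(F, theta_deg)
}
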