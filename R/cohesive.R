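# Bilinear mixed-mode cohesive traction-separation law for the lamellar
# interface of the aortic media.
#
# Linear rise T = K S to the initiation traction T_C (at S_0 = T_C/K),
# then linear softening to zero at S_t = 2 G_C / T_C, so that the enclosed
# area equals the critical fracture energy G_C = T_C S_t / 2. Initiation
# under combined loading follows the quadratic nominal stress criterion
# (tension-only in the normal direction); complete failure follows the
# power law on the per-mode dissipated energies.

#' Cohesive interface parameter set
#'
#' Bilinear mixed-mode cohesive-zone parameters for the three interface
#' damage modes: opening (mode I, normal) and the two sliding modes
#' (mode II in-plane/circumferential, mode III out-of-plane/axial).
#' Defaults are the bundled calibrated values for the human aortic media
#' (see [cohesive_media()]).
#'
#' @param TnC,TsC,TtC Initiation tractions for modes I, II, III, kPa.
#' @param GIC,GIIC,GIIIC Critical fracture energies, mN/mm (= N/m).
#' @param Kn,Ks,Kt Initial (penalty) stiffnesses, mN/mm^3.
#' @param alpha Power-law exponent of the mixed-mode failure criterion;
#'   default 1.
#' @param contact_factor Normal penalty stiffness for penetration is
#'   `contact_factor * Kn`; penetration is resisted by contact, never by
#'   the cohesive law, and produces no damage.
#' @param mu_visc Viscous regularization time constant for the damage
#'   variable (in load-factor units); 0 disables regularization.
#' @return An object of class `cohesive_params` with derived initiation
#'   separations `S0 = T_C/K` and failure separations `St = 2 G_C/T_C`.
#' @export
cohesive_params <- function(TnC = 131, TsC = 97, TtC = 120,
                            GIC = 49, GIIC = 200, GIIIC = 240,
                            Kn = 1638, Ks = 35000, Kt = 35000,
                            alpha = 1, contact_factor = 10, mu_visc = 0) {
  vals <- c(TnC, TsC, TtC, GIC, GIIC, GIIIC, Kn, Ks, Kt, alpha)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all cohesive parameters must be positive and finite")
  }
  S0 <- c(n = TnC / Kn, s = TsC / Ks, t = TtC / Kt)
  St <- c(n = 2 * GIC / TnC, s = 2 * GIIC / TsC, t = 2 * GIIIC / TtC)
  if (any(St <= S0)) {
    stop("inconsistent parameters: failure separation St = 2 G_C/T_C must ",
         "exceed initiation separation S0 = T_C/K for every mode")
  }
  structure(list(TnC = TnC, TsC = TsC, TtC = TtC,
                 GIC = GIC, GIIC = GIIC, GIIIC = GIIIC,
                 Kn = Kn, Ks = Ks, Kt = Kt, alpha = alpha,
                 contact_factor = contact_factor, mu_visc = mu_visc,
                 S0 = S0, St = St),
            class = "cohesive_params")
}

#' @export
print.cohesive_params <- function(x, ...) {
  cat("Bilinear mixed-mode cohesive parameters:\n")
  cat(sprintf("  mode I   : TnC = %g kPa, GIC = %g mN/mm, Kn = %g mN/mm^3\n",
              x$TnC, x$GIC, x$Kn))
  cat(sprintf("  mode II  : TsC = %g kPa, GIIC = %g mN/mm, Ks = %g mN/mm^3\n",
              x$TsC, x$GIIC, x$Ks))
  cat(sprintf("  mode III : TtC = %g kPa, GIIIC = %g mN/mm, Kt = %g mN/mm^3\n",
              x$TtC, x$GIIIC, x$Kt))
  cat(sprintf("  alpha = %g; S0 = (%.4g, %.4g, %.4g) mm; St = (%.4g, %.4g, %.4g) mm\n",
              x$alpha, x$S0[1], x$S0[2], x$S0[3], x$St[1], x$St[2], x$St[3]))
  invisible(x)
}

#' Bundled calibrated cohesive parameters of the human aortic media
#'
#' Loads the bundled parameter table (`extdata/cohesive_media.yaml`)
#' calibrated against peel, direct-tension and shear experiments on human
#' medial tissue.
#'
#' @param ... Overrides passed on to [cohesive_params()] (e.g. `mu_visc`).
#' @return A `cohesive_params` object.
#' @export
cohesive_media <- function(...) {
  path <- system.file("extdata", "cohesive_media.yaml", package = "aortafem")
  y <- yaml::read_yaml(path)
  args <- list(TnC = y$mode_I$T_C_kPa, TsC = y$mode_II$T_C_kPa,
               TtC = y$mode_III$T_C_kPa,
               GIC = y$mode_I$G_C_mN_per_mm, GIIC = y$mode_II$G_C_mN_per_mm,
               GIIIC = y$mode_III$G_C_mN_per_mm,
               Kn = y$mode_I$K_mN_per_mm3, Ks = y$mode_II$K_mN_per_mm3,
               Kt = y$mode_III$K_mN_per_mm3, alpha = y$alpha)
  do.call(cohesive_params, modifyList(args, list(...)))
}

.cohpar_vec <- function(p) {
  c(p$Kn, p$Ks, p$Kt, p$TnC, p$TsC, p$TtC, p$GIC, p$GIIC, p$GIIIC,
    p$alpha, p$contact_factor * p$Kn, p$mu_visc)
}

#' Fresh cohesive point state
#'
#' @return An object of class `cohesive_state`: zero damage, zero
#'   dissipated energies, empty history.
#' @export
cohesive_state <- function() {
  structure(list(d = 0, history = 0, GI = 0, GII = 0, GIII = 0,
                 failed = FALSE, Gstab = 0, sep = c(dn = 0, ds = 0, dt = 0)),
            class = "cohesive_state")
}

.state_vec <- function(s) {
  c(s$d, s$history, s$GI, s$GII, s$GIII, as.numeric(s$failed), s$Gstab, s$sep)
}

.state_from_vec <- function(v) {
  structure(list(d = v[1], history = v[2], GI = v[3], GII = v[4], GIII = v[5],
                 failed = v[6] > 0.5, Gstab = v[7],
                 sep = c(dn = v[8], ds = v[9], dt = v[10])),
            class = "cohesive_state")
}

#' Update a cohesive point to new separations
#'
#' Advances the bilinear mixed-mode law from the committed `state` to the
#' separations `sep`. Pre-initiation response is linear, `T_i = K_i d_i`;
#' after initiation the traction softens linearly toward complete failure,
#' with secant unloading/reloading through the origin. Damage and the
#' per-mode dissipated energies are non-decreasing. Compressive normal
#' separation produces a penalty contact reaction and never contributes to
#' damage or dissipation. The point is flagged failed once the power-law
#' energy criterion reaches one.
#'
#' @param state A `cohesive_state` (committed history).
#' @param sep Numeric length-3: separations `(dn, ds, dt)` in mm, `dn`
#'   signed with tension positive.
#' @param p A `cohesive_params` object.
#' @param dtime Pseudo-time increment for viscous regularization (ignored
#'   when `p$mu_visc == 0`).
#' @return A list with the updated `state` and a `traction` result of
#'   class `traction_result`: fields `Tn`, `Ts`, `Tt` (kPa),
#'   `initiation_value` (quadratic stress criterion) and `failure_value`
#'   (power-law energy criterion).
#' @export
traction_update <- function(state, sep, p, dtime = 1) {
  stopifnot(inherits(state, "cohesive_state"), inherits(p, "cohesive_params"))
  sep <- as.numeric(sep)
  if (length(sep) != 3L || any(!is.finite(sep))) {
    stop("separations must be three finite numbers")
  }
  r <- .czm_update_cpp(.state_vec(state), sep, .cohpar_vec(p), FALSE, dtime)
  tr <- structure(list(Tn = r$traction[1], Ts = r$traction[2],
                       Tt = r$traction[3],
                       initiation_value = r$initiation_value,
                       failure_value = r$failure_value),
                  class = "traction_result")
  list(state = .state_from_vec(r$state), traction = tr)
}

#' Quadratic nominal stress initiation criterion
#'
#' `f = <Tn>^2/TnC^2 + Ts^2/TsC^2 + Tt^2/TtC^2` with `<.>` the Macaulay
#' bracket (compression contributes nothing). Damage initiates when
#' `f >= 1`.
#'
#' @param Tn,Ts,Tt Nominal tractions, kPa (or a `traction_result` as `Tn`).
#' @param p A `cohesive_params` object.
#' @return Scalar criterion value `f`.
#' @export
initiation_criterion <- function(Tn, Ts = NULL, Tt = NULL, p) {
  if (inherits(Tn, "traction_result")) {
    Ts <- Tn$Ts; Tt <- Tn$Tt; Tn <- Tn$Tn
  }
  stopifnot(is.finite(Tn), is.finite(Ts), is.finite(Tt))
  (max(Tn, 0) / p$TnC)^2 + (Ts / p$TsC)^2 + (Tt / p$TtC)^2
}

#' Power-law mixed-mode failure criterion
#'
#' `g = (GI/GIC)^alpha + (GII/GIIC)^alpha + (GIII/GIIIC)^alpha`; the
#' interface point is completely damaged when `g >= 1`.
#'
#' @param GI,GII,GIII Dissipated energies per area, mN/mm.
#' @param p A `cohesive_params` object (supplies the critical energies and
#'   `alpha`).
#' @return Scalar criterion value `g`.
#' @export
failure_criterion <- function(GI, GII, GIII, p) {
  stopifnot(all(c(GI, GII, GIII) >= 0))
  (GI / p$GIC)^p$alpha + (GII / p$GIIC)^p$alpha + (GIII / p$GIIIC)^p$alpha
}

#' Mode mix ratio
#'
#' `m = 1 - GI/GT` with `GT = GI + GII + GIII`: 0 for pure opening, 1 for
#' pure sliding.
#'
#' @param GI,GII,GIII Dissipated energies per area, mN/mm.
#' @return Scalar in [0, 1], or `NA_real_` when no energy has been
#'   dissipated (`GT = 0`).
#' @export
mode_mix_ratio <- function(GI, GII, GIII) {
  GT <- GI + GII + GIII
  if (GT <= 0) return(NA_real_)
  1 - GI / GT
}
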