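# Idealized bilayer cylindrical aorta with an in-plane medial tear:
# mesh generation, semi-analytic extension-inflation oracle, simplified
# opening-angle residual-stress prestrain, critical-pressure search and
# parameter sweeps.

#' Idealized bilayer tube geometry and discretization
#'
#' The human descending aorta idealized as a bilayer cylinder: inner
#' radius 7.5 mm, outer radius 9 mm, media/adventitia thickness ratio
#' 5:3. Tube length is the tear length plus 3 mm (1.5 mm per end).
#'
#' @param Ri,Ro Inner/outer reference radii, mm.
#' @param media_frac Media share of the wall thickness (5/8).
#' @param n_circ Circumferential element count (over the modelled span).
#' @param n_axial Axial element count.
#' @param nr_inner Radial elements between lumen and tear interface.
#' @param nr_mid Radial elements between tear interface and adventitia.
#' @param nr_adv Radial elements in the adventitia.
#' @param half_model Use the theta in [0, 180 deg] symmetric half (valid
#'   for a tear centered at theta = 0 under symmetric loading).
#' @param half_axial Use the axially symmetric half (tear axially
#'   centered): the mesh spans mid-plane to top.
#' @param front_band_deg,n_fine_circ Width (degrees) of the refined
#'   circumferential band straddling the tear edge and its element count
#'   per side of the edge; the cohesive process zone at the tear front
#'   must be resolved by a few elements for a mesh-converged critical
#'   pressure.
#' @param front_band_mm,n_fine_axial Same for the axial tear front.
#' @return List of class `tube_spec`.
#' @export
tube_spec <- function(Ri = 7.5, Ro = 9, media_frac = 5 / 8,
                      n_circ = 18, n_axial = 6, nr_inner = 2, nr_mid = 2,
                      nr_adv = 1, half_model = TRUE, half_axial = FALSE,
                      front_band_deg = 9, n_fine_circ = 3,
                      front_band_mm = 1.5, n_fine_axial = 3) {
  stopifnot(Ro > Ri, media_frac > 0, media_frac < 1)
  structure(list(Ri = Ri, Ro = Ro, media_frac = media_frac,
                 tm = media_frac * (Ro - Ri),
                 n_circ = n_circ, n_axial = n_axial, nr_inner = nr_inner,
                 nr_mid = nr_mid, nr_adv = nr_adv,
                 half_model = half_model, half_axial = half_axial,
                 front_band_deg = front_band_deg,
                 n_fine_circ = n_fine_circ,
                 front_band_mm = front_band_mm,
                 n_fine_axial = n_fine_axial),
            class = "tube_spec")
}

#' Initial tear description
#'
#' @param eta_deg Central angle of the tear, degrees (tear centered at
#'   theta = 0).
#' @param s_mm Axial tear length, mm (axially centered).
#' @param t_ratio Depth ratio t = t1/tm: distance from lumen to tear over
#'   media thickness.
#' @return List of class `tear_geometry` with derived `t1_mm` and, once
#'   combined with a [tube_spec()], the interface radius `Ri + t1`.
#' @export
tear_geometry <- function(eta_deg = 150, s_mm = 10, t_ratio = 0.4) {
  if (!(t_ratio > 0 && t_ratio < 1)) stop("t_ratio must lie in (0, 1)")
  if (!(eta_deg > 0 && eta_deg <= 360)) stop("eta_deg must lie in (0, 360]")
  if (s_mm <= 0) stop("s_mm must be positive")
  structure(list(eta_deg = eta_deg, s_mm = s_mm, t_ratio = t_ratio),
            class = "tear_geometry")
}

#' Loading conditions for the tube pipeline
#'
#' @param lambda_axial Axial stretch (>= 1) applied before pressurization.
#' @param p_TL,p_FL End-of-ramp true/false lumen pressures, kPa; they are
#'   ramped proportionally from zero, so their ratio is held fixed (the
#'   critical event is reported at the true-lumen value).
#' @param opening_angle_deg Residual-stress opening angle (0 = none).
#' @return List of class `load_case`.
#' @export
load_case <- function(lambda_axial = 1.02, p_TL = 500, p_FL = 500,
                      opening_angle_deg = 0) {
  stopifnot(lambda_axial >= 1, p_TL >= 0, p_FL >= 0,
            opening_angle_deg >= 0, opening_angle_deg < 180)
  structure(list(lambda_axial = lambda_axial, p_TL = p_TL, p_FL = p_FL,
                 LPD = p_TL - p_FL, opening_angle_deg = opening_angle_deg),
            class = "load_case")
}

#' Interface radius of a tear in a tube
#' @param spec A [tube_spec()]. @param tear A [tear_geometry()].
#' @return Radius of the cohesive interface, mm.
#' @export
interface_radius <- function(spec, tear) {
  spec$Ri + tear$t_ratio * spec$tm
}

#' Build the bilayer tube model with an embedded medial interface
#'
#' Generates a structured hexahedral mesh of the bilayer tube with one
#' zero-thickness cohesive surface at the tear radius spanning the whole
#' modelled circumference and length. Cohesive elements inside the tear
#' footprint (|theta| <= eta/2, axially centered length s) are flagged
#' pre-torn: they carry no cohesive stiffness but keep the contact
#' contract, and their two faces form the false-lumen pressure set.
#'
#' Boundary conditions: bottom face axially constrained, top face carries
#' the axial stretch; the node lines at theta = 0/90/180(/270) degrees are
#' fixed circumferentially.
#'
#' @param spec A [tube_spec()]. @param tear A [tear_geometry()] or `NULL`
#'   for an intact tube (no interface).
#' @param materials List (media, adventitia) of [hgo_params()].
#' @param coh_params A [cohesive_params()].
#' @param controls A [fem_controls()].
#' @return An [fe_model()] with pressure sets `TL` (lumen) and `FL` (both
#'   faces of the torn region), tube metadata in `$tube`.
#' @export
build_tube_mesh <- function(spec, tear = NULL,
                            materials = list(hgo_media(), hgo_adventitia()),
                            coh_params = cohesive_media(),
                            controls = fem_controls()) {
  intact <- is.null(tear)
  L <- if (intact) 6 else tear$s_mm + 3
  r_int <- if (intact) NA else interface_radius(spec, tear)
  R_ma <- spec$Ri + spec$tm
  if (!intact && !(r_int > spec$Ri && r_int < R_ma)) {
    stop("tear interface must lie strictly inside the media")
  }
  th_max <- if (spec$half_model) 180 else 360
  if (!intact && tear$eta_deg > 360) stop("tear footprint exceeds mesh")

  # graded breakpoints: a refined band straddles each tear front so the
  # cohesive process zone is resolved; elsewhere the grid is coarse
  graded <- function(lo, hi, edge, band, n_fine, n_coarse_total) {
    if (is.na(edge) || edge <= lo + 1e-9 || edge >= hi - 1e-9) {
      return(seq(lo, hi, length.out = max(2, n_coarse_total + 1)))
    }
    b_lo <- min(band, (edge - lo) * 0.6)
    b_hi <- min(band, (hi - edge) * 0.9)
    pts <- c()
    nA <- max(1, round(n_coarse_total * (edge - b_lo - lo) / (hi - lo)))
    pts <- seq(lo, edge - b_lo, length.out = nA + 1)
    fine <- seq(edge - b_lo, edge + b_hi, length.out = 2 * n_fine + 1)
    pts <- c(pts, fine[-1])
    if (edge + b_hi < hi - 1e-9) {
      nC <- max(1, round(n_coarse_total * (hi - edge - b_hi) / (hi - lo)))
      pts <- c(pts, seq(edge + b_hi, hi, length.out = nC + 1)[-1])
    }
    pts
  }

  e_th <- if (intact || tear$eta_deg >= th_max * (if (spec$half_model) 2 else 1)) {
    NA
  } else tear$eta_deg / 2
  th_deg <- graded(0, th_max, e_th, spec$front_band_deg, spec$n_fine_circ,
                   spec$n_circ)
  # the circumferential-fix node lines (cross sections at 90/270 deg)
  # must exist in the grid
  fixlines <- if (spec$half_model) 90 else c(90, 270)
  for (fl in fixlines) {
    if (min(abs(th_deg - fl)) > 1e-6) th_deg <- sort(c(th_deg, fl))
  }
  th <- th_deg * pi / 180
  nth <- length(th) - 1L
  if (spec$half_axial) {
    # model z in [0, L/2] with the mid-plane at z = 0 (tear centered)
    e_z <- if (intact) NA else tear$s_mm / 2
    zs <- graded(0, L / 2, e_z, spec$front_band_mm, spec$n_fine_axial,
                 spec$n_axial)
  } else if (intact) {
    zs <- seq(0, L, length.out = spec$n_axial + 1)
  } else {
    # grade the upper half around its tear front and mirror it
    zu <- graded(L / 2, L, L / 2 + tear$s_mm / 2, spec$front_band_mm,
                 spec$n_fine_axial, max(1, ceiling(spec$n_axial / 2)))
    lower <- L - rev(zu)
    zs <- c(lower[-length(lower)], zu)
  }
  nz <- length(zs) - 1L
  wrap <- !spec$half_model
  nthn <- if (wrap) nth else nth + 1L  # unique circumferential node count

  # radial node layers, inner part (lumen..interface) and outer part
  if (intact) {
    rs_in <- seq(spec$Ri, R_ma, length.out = spec$nr_inner + spec$nr_mid + 1)
    rs_out <- seq(R_ma, spec$Ro, length.out = spec$nr_adv + 1)
    rs <- c(rs_in, rs_out[-1])
    rlist <- list(rs)
  } else {
    rs_lo <- seq(spec$Ri, r_int, length.out = spec$nr_inner + 1)
    rs_hi <- c(seq(r_int, R_ma, length.out = spec$nr_mid + 1),
               seq(R_ma, spec$Ro, length.out = spec$nr_adv + 1)[-1])
    rlist <- list(rs_lo, rs_hi)
  }

  # node numbering: for each radial block, grid (itheta, iz, ir)
  nodes <- NULL
  idxs <- list()
  off <- 0L
  nzn <- nz + 1L
  for (b in seq_along(rlist)) {
    rs <- rlist[[b]]
    nr <- length(rs)
    idx <- array(0L, dim = c(nthn, nzn, nr))
    coo <- matrix(0, nthn * nzn * nr, 3)
    k <- 0L
    for (ir in seq_len(nr)) for (iz in seq_len(nzn)) for (it in seq_len(nthn)) {
      k <- k + 1L
      idx[it, iz, ir] <- off + k
      coo[k, ] <- c(rs[ir] * cos(th[it]), rs[ir] * sin(th[it]), zs[iz])
    }
    nodes <- rbind(nodes, coo)
    idxs[[b]] <- idx
    off <- off + k
  }
  thw <- function(it) if (wrap && it == nth + 1) 1L else it  # wrap theta

  # hexahedra
  hex <- NULL; hmat <- NULL; hcent_th <- NULL; hcent_r <- NULL
  for (b in seq_along(rlist)) {
    rs <- rlist[[b]]
    idx <- idxs[[b]]
    for (ir in seq_len(length(rs) - 1)) {
      for (iz in seq_len(nz)) for (it in seq_len(nth)) {
        i2 <- thw(it + 1L)
        hex <- rbind(hex, c(idx[it, iz, ir], idx[i2, iz, ir],
                            idx[i2, iz + 1, ir], idx[it, iz + 1, ir],
                            idx[it, iz, ir + 1], idx[i2, iz, ir + 1],
                            idx[i2, iz + 1, ir + 1], idx[it, iz + 1, ir + 1]))
        rc <- (rs[ir] + rs[ir + 1]) / 2
        hmat <- c(hmat, if (rc < R_ma) 1L else 2L)
        tc <- (th[it] + th[it + 1]) / 2
        hcent_th <- c(hcent_th, tc)
        hcent_r <- c(hcent_r, rc)
      }
    }
  }

  # fibers: +/- theta_f from circumferential at the element angle
  nhex <- nrow(hex)
  fibM <- matrix(0, nhex, 3); fibN <- matrix(0, nhex, 3)
  for (e in seq_len(nhex)) {
    thf <- materials[[hmat[e]]]$theta_deg * pi / 180
    eth <- c(-sin(hcent_th[e]), cos(hcent_th[e]), 0)
    ez <- c(0, 0, 1)
    fibM[e, ] <- cos(thf) * eth + sin(thf) * ez
    fibN[e, ] <- cos(thf) * eth - sin(thf) * ez
  }

  # cohesive elements at the interface + tear footprint + FL faces
  coh <- matrix(integer(0), 0, 8); torn <- logical(0)
  meta <- NULL
  fl_faces <- NULL
  if (!intact) {
    iL <- idxs[[1]]; nrL <- dim(iL)[3]
    iU <- idxs[[2]]
    for (iz in seq_len(nz)) for (it in seq_len(nth)) {
      i2 <- thw(it + 1L)
      bot <- c(iL[it, iz, nrL], iL[i2, iz, nrL],
               iL[i2, iz + 1, nrL], iL[it, iz + 1, nrL])
      top <- c(iU[it, iz, 1], iU[i2, iz, 1],
               iU[i2, iz + 1, 1], iU[it, iz + 1, 1])
      coh <- rbind(coh, c(bot, top))
      tc_deg <- (th[it] + th[it + 1]) / 2 * 180 / pi
      if (!spec$half_model && tc_deg > 180) tc_deg <- tc_deg - 360
      zc <- (zs[iz] + zs[iz + 1]) / 2
      z_center <- if (spec$half_axial) 0 else L / 2
      is_torn <- abs(tc_deg) <= tear$eta_deg / 2 + 1e-9 &&
        abs(zc - z_center) <= tear$s_mm / 2 + 1e-9
      torn <- c(torn, is_torn)
      meta <- rbind(meta, data.frame(theta_deg = tc_deg, z = zc,
                                     eta_half = tear$eta_deg / 2,
                                     s_half = tear$s_mm / 2,
                                     z_center = z_center))
      if (is_torn) {
        # FL pressure: push the inner flap inward, the outer wall outward
        fl_faces <- rbind(fl_faces,
                          bot[c(1, 4, 3, 2)],  # normal -e_r
                          top)                  # normal +e_r
      }
    }
  }

  # TL pressure: lumen surface (innermost radial layer)
  iL <- idxs[[1]]
  tl_faces <- NULL
  for (iz in seq_len(nz)) for (it in seq_len(nth)) {
    i2 <- thw(it + 1L)
    tl_faces <- rbind(tl_faces, c(iL[it, iz, 1], iL[i2, iz, 1],
                                  iL[i2, iz + 1, 1], iL[it, iz + 1, 1]))
  }
  psets <- list(TL = tl_faces)
  if (!is.null(fl_faces)) psets$FL <- fl_faces

  # boundary conditions
  tol <- 1e-8
  Lz <- max(zs)
  bottom <- which(abs(nodes[, 3]) < tol)   # full: bottom face; half: mid-plane
  top <- which(abs(nodes[, 3] - Lz) < tol)
  dir <- rbind(
    data.frame(node = bottom, dof = 3L, value = 0),
    data.frame(node = top, dof = 3L, value = 0),  # stage target set later
    data.frame(node = which(abs(nodes[, 2]) < 1e-6), dof = 2L, value = 0),
    data.frame(node = which(abs(nodes[, 1]) < 1e-6 &
                            nodes[, 2] > 0), dof = 1L, value = 0))
  if (!spec$half_model) {
    dir <- rbind(dir,
                 data.frame(node = which(abs(nodes[, 1]) < 1e-6 &
                                         nodes[, 2] < 0), dof = 1L, value = 0))
  }
  dir <- dir[!duplicated(dir[, c("node", "dof")]), ]

  model <- fe_model(nodes, hex, hmat, materials, fibM, fibN,
                    coh = coh, coh_torn = torn, coh_params = coh_params,
                    dirichlet = dir, pressure_sets = psets,
                    coh_meta = meta, controls = controls)
  model$tube <- list(spec = spec, tear = tear, L = L, Lz_model = Lz,
                     top_nodes = top, r_interface = r_int, intact = intact,
                     sym_factor = if (spec$half_model) 2 else 1)
  model
}

# incompressible plane deformation energy of a layered tube wall:
# local frame (circ, axial, radial), diagonal stretches
.tube_What <- function(lt, lz, mat) {
  F <- diag(c(lt, lz, 1 / (lt * lz)))
  st <- compute_kinematics(F, mat$theta_deg)
  # incompressible: volumetric term vanishes at J = 1
  strain_energy_density(st, mat)
}

.tube_dW <- function(lt, lz, mat, h = 1e-6) {
  c(dlt = (.tube_What(lt + h, lz, mat) - .tube_What(lt - h, lz, mat)) / (2 * h),
    dlz = (.tube_What(lt, lz + h, mat) - .tube_What(lt, lz - h, mat)) / (2 * h))
}

#' Semi-analytic extension-inflation of the intact bilayer tube
#'
#' Solves the axisymmetric, incompressible extension-inflation problem of
#' the intact bilayer tube by radial integration of the equilibrium
#' equation with the fiber-reinforced energy: the deformed inner radius
#' is found so that the radial stress vanishes on the outer surface with
#' internal pressure `p` on the inner surface. Serves as the verification
#' oracle for the FEM tube.
#'
#' @param spec A [tube_spec()].
#' @param lambda Axial stretch.
#' @param p Lumen pressure, kPa.
#' @param materials List (media, adventitia) of [hgo_params()].
#' @param n_grid Radial integration grid size.
#' @return List of class `tube_inflation`: `ri`, `ro` (deformed radii,
#'   mm) and `profile`, a data.frame with deformed radius `r`, reference
#'   radius `R`, `layer`, and Cauchy stresses `s_rr`, `s_tt`, `s_zz`
#'   (kPa).
#' @export
semi_analytic_inflation <- function(spec, lambda = 1.02, p = 12.8,
                                    materials = list(hgo_media(),
                                                     hgo_adventitia()),
                                    n_grid = 400) {
  R_ma <- spec$Ri + spec$tm
  radial_profile <- function(ri) {
    ro <- sqrt(ri^2 + (spec$Ro^2 - spec$Ri^2) / lambda)
    r <- seq(ri, ro, length.out = n_grid)
    R <- sqrt(spec$Ri^2 + lambda * (r^2 - ri^2))
    lt <- r / R
    dsig <- vapply(seq_along(r), function(i) {
      mat <- materials[[if (R[i] < R_ma) 1 else 2]]
      dw <- .tube_dW(lt[i], lambda, mat)
      lt[i] * dw[["dlt"]]
    }, numeric(1))
    h <- dsig / r
    integ <- cumsum(c(0, diff(r) * (h[-1] + h[-length(r)]) / 2))
    list(r = r, R = R, lt = lt, dsig = dsig, s_rr = -p + integ)
  }
  f <- function(ri) radial_profile(ri)$s_rr[n_grid]
  lo <- spec$Ri * 0.6; hi <- spec$Ri * 2.5
  sol <- uniroot(f, c(lo, hi), tol = 1e-10)
  pr <- radial_profile(sol$root)
  szz <- vapply(seq_along(pr$r), function(i) {
    mat <- materials[[if (pr$R[i] < R_ma) 1 else 2]]
    dw <- .tube_dW(pr$lt[i], lambda, mat)
    pr$s_rr[i] + lambda * dw[["dlz"]]
  }, numeric(1))
  profile <- data.frame(r = pr$r, R = pr$R,
                        layer = ifelse(pr$R < R_ma, "media", "adventitia"),
                        s_rr = pr$s_rr, s_tt = pr$s_rr + pr$dsig,
                        s_zz = szz)
  structure(list(ri = sol$root, ro = pr$r[n_grid], lambda = lambda, p = p,
                 profile = profile),
            class = "tube_inflation")
}

# gauss point order used by the compiled hex loop (x fastest, then y, z)
.hex_gp_order <- local({
  g <- 1 / sqrt(3)
  expand.grid(xi = c(-g, g), eta = c(-g, g), zeta = c(-g, g))
})

#' Apply simplified opening-angle residual-stress prestrain
#'
#' Implements classical opening-angle kinematics as a multiplicative
#' prestrain: the stress-free state is a sector of angle 2*pi - alpha
#' that is closed into the full reference cylinder (circumferential
#' prestretch k R / rho, incompressible in-plane). The opened inner
#' radius is chosen so that the closed, unloaded tube is self-equilibrated
#' (radial stress vanishing on both surfaces in the incompressible
#' semi-analytic solution); the FEM then relaxes the small remainder.
#' The result compresses the inner wall and tensions the outer wall
#' circumferentially, flattening the transmural stress gradient under
#' load.
#'
#' @param model A tube [fe_model()] from [build_tube_mesh()].
#' @param opening_angle_deg Opening angle alpha in [0, 180).
#' @return The model with its per-Gauss-point `prestrain` field set
#'   (identity when the angle is zero).
#' @export
apply_residual_prestrain <- function(model, opening_angle_deg) {
  stopifnot(!is.null(model$tube), opening_angle_deg >= 0,
            opening_angle_deg < 180)
  if (opening_angle_deg == 0) {
    model$prestrain <- NULL
    return(model)
  }
  spec <- model$tube$spec
  alpha <- opening_angle_deg * pi / 180
  k <- 2 * pi / (2 * pi - alpha)
  R_ma <- spec$Ri + spec$tm
  mats <- model$materials
  # closed-tube hoop stress differential for a given opened inner radius
  srr_outer <- function(rho_i, n = 200) {
    R <- seq(spec$Ri, spec$Ro, length.out = n)
    rho <- sqrt(rho_i^2 + k * (R^2 - spec$Ri^2))
    lt <- k * R / rho
    dsig <- vapply(seq_len(n), function(i) {
      mat <- mats[[if (R[i] < R_ma) 1 else 2]]
      dw <- .tube_dW(lt[i], 1, mat)
      lt[i] * dw[["dlt"]]
    }, numeric(1))
    sum(diff(R) * ((dsig / R)[-1] + (dsig / R)[-n]) / 2)
  }
  sol <- uniroot(srr_outer, c(spec$Ri * 0.8, spec$Ri * 1.6 / sqrt(k)),
                 extendInt = "yes", tol = 1e-9)
  rho_i <- sol$root
  # per-Gauss-point prestrain in the cylindrical basis
  nhex <- nrow(model$hex)
  pre <- matrix(0, nhex * 8, 9)
  gp <- .hex_gp_order
  for (e in seq_len(nhex)) {
    Xe <- model$nodes[model$hex[e, ], ]
    for (g in 1:8) {
      sgn <- rbind(c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
                   c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))
      Nf <- 0.125 * (1 + sgn[, 1] * gp$xi[g]) * (1 + sgn[, 2] * gp$eta[g]) *
        (1 + sgn[, 3] * gp$zeta[g])
      X <- colSums(Nf * Xe)
      R <- sqrt(X[1]^2 + X[2]^2)
      thp <- atan2(X[2], X[1])
      rho <- sqrt(rho_i^2 + k * (R^2 - spec$Ri^2))
      lt <- k * R / rho
      lr <- 1 / lt
      er <- c(cos(thp), sin(thp), 0)
      et <- c(-sin(thp), cos(thp), 0)
      ez <- c(0, 0, 1)
      Fp <- lr * tcrossprod(er) + lt * tcrossprod(et) + tcrossprod(ez)
      pre[8 * (e - 1) + g, ] <- as.vector(t(Fp))  # row-major
    }
  }
  model$prestrain <- pre
  model$tube$opening_angle_deg <- opening_angle_deg
  model
}

#' Pressurize a tube model to the critical propagation event
#'
#' Applies the axial stretch, then ramps the true- and false-lumen
#' pressures proportionally (fixed ratio) until the first cohesive
#' element is completely damaged; the load factor is refined to 1 kPa.
#' With a residual-stress opening angle the prestrained model is first
#' relaxed to self-equilibrium under zero load.
#'
#' @param model A tube [fe_model()].
#' @param case A [load_case()].
#' @param p_resolution Critical-pressure bisection resolution, kPa.
#' @return List of class `tube_result`: `event` (a `critical_event` or
#'   `NULL`), `trajectory`, `interface` (per-element damage/energy/mode
#'   mix summary), `case`.
#' @export
run_pressurization <- function(model, case = load_case(),
                               p_resolution = 1) {
  stopifnot(!is.null(model$tube))
  if (case$opening_angle_deg > 0) {
    model <- apply_residual_prestrain(model, case$opening_angle_deg)
  }
  L <- model$tube$Lz_model
  top <- model$tube$top_nodes
  stages <- list()
  if (!is.null(model$prestrain)) {
    stages <- c(stages, list(list(name = "relax", prestrain_ramp = TRUE)))
  }
  stages <- c(stages, list(
    list(name = "stretch",
         dirichlet = data.frame(node = top, dof = 3L,
                                value = (case$lambda_axial - 1) * L)),
    list(name = "pressurize",
         dirichlet = data.frame(node = top, dof = 3L,
                                value = (case$lambda_axial - 1) * L),
         pressures = c(TL = case$p_TL, FL = case$p_FL),
         critical = TRUE, p_resolution = p_resolution)))
  traj <- solve_quasi_static(model, stages)
  ev <- detect_critical_event(traj, model, pressure_set = "TL")
  structure(list(event = ev, trajectory = traj,
                 interface = interface_summary(traj, model),
                 case = case, status = traj$status),
            class = "tube_result")
}

#' @export
print.tube_result <- function(x, ...) {
  if (is.null(x$event)) {
    cat("No critical event within the pressure schedule (status: ",
        x$status, ")\n", sep = "")
  } else {
    print(x$event)
  }
  invisible(x)
}

#' Parameter sweep over tear geometry and loading
#'
#' Runs [run_pressurization()] over a grid of tear/loading parameters and
#' collects one row per case. Individual failures are recorded and the
#' sweep continues.
#'
#' @param grid data.frame with any of the columns `eta_deg`, `s_mm`,
#'   `t_ratio`, `lambda`, `opening_angle_deg`, `p_TL`, `p_FL` (missing
#'   columns take the baseline values eta = 150, s = 10, t = 0.4,
#'   lambda = 1.02, equal pressures, no residual stress).
#' @param spec A [tube_spec()] (discretization reused for every case).
#' @param materials,coh_params,controls Passed to [build_tube_mesh()].
#' @param p_cap Pressure-ramp cap, kPa.
#' @return data.frame: the grid plus `Pc` (kPa), `direction`, `m`, `Tn`,
#'   `Ts`, `Tt`, `status`.
#' @export
parameter_sweep <- function(grid, spec = tube_spec(),
                            materials = list(hgo_media(), hgo_adventitia()),
                            coh_params = cohesive_media(),
                            controls = fem_controls(), p_cap = 500) {
  defaults <- list(eta_deg = 150, s_mm = 10, t_ratio = 0.4, lambda = 1.02,
                   opening_angle_deg = 0, p_TL = p_cap, p_FL = p_cap)
  for (nm in names(defaults)) {
    if (is.null(grid[[nm]])) grid[[nm]] <- defaults[[nm]]
  }
  out <- grid
  out$Pc <- NA_real_; out$direction <- NA_character_; out$m <- NA_real_
  out$Tn <- NA_real_; out$Ts <- NA_real_; out$Tt <- NA_real_
  out$status <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      tear <- tear_geometry(grid$eta_deg[i], grid$s_mm[i], grid$t_ratio[i])
      model <- build_tube_mesh(spec, tear, materials, coh_params, controls)
      cs <- load_case(grid$lambda[i], grid$p_TL[i], grid$p_FL[i],
                      grid$opening_angle_deg[i])
      run_pressurization(model, cs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$status[i] <- paste("error:", conditionMessage(res))
    } else {
      out$status[i] <- res$status
      if (!is.null(res$event)) {
        out$Pc[i] <- res$event$Pc
        el <- res$event$elements[1, ]
        out$direction[i] <- el$direction
        out$m[i] <- el$m
        out$Tn[i] <- el$Tn; out$Ts[i] <- el$Ts; out$Tt[i] <- el$Tt
      }
    }
  }
  out
}
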