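# Assembly, follower pressure, quasi-static solver, critical event
# detection, global energy balance.

media <- hgo_media()

test_that("single hexahedron under homogeneous stretch: nodal forces
           equal closed-form nominal stress times face area", {
  mb <- aortafem:::.mesh_block(c(0, 1), c(0, 1), c(0, 1))
  fib <- aortafem:::.specimen_fibers(1, media$theta_deg)
  m <- fe_model(mb$nodes, mb$hex, 1L, list(media), fib$M, fib$N)
  Fh <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  u <- as.vector(t(mb$nodes %*% t(Fh) - mb$nodes))
  a <- assemble(m, u, want_matrix = FALSE)
  P <- pk1_stress(compute_kinematics(Fh, media$theta_deg), media)
  f <- matrix(a$fint, ncol = 3, byrow = TRUE)
  # unit-area face x = 1 carries nodes 2, 4, 6, 8 of the grid ordering
  xface <- which(mb$nodes[, 1] == 1)
  expect_equal(colSums(f[xface, ]), P[, 1], tolerance = 1e-8 * max(abs(P)))
  yface <- which(mb$nodes[, 2] == 1)
  expect_equal(colSums(f[yface, ]), P[, 2], tolerance = 1e-8 * max(abs(P)))
})

test_that("patch test: a linear displacement field gives zero interior
           residual", {
  mb <- aortafem:::.mesh_block(seq(0, 1, 0.5), seq(0, 1, 0.5), seq(0, 1, 0.5))
  fib <- aortafem:::.specimen_fibers(nrow(mb$hex), media$theta_deg)
  m <- fe_model(mb$nodes, mb$hex, rep(1L, nrow(mb$hex)), list(media),
                fib$M, fib$N)
  Fh <- diag(c(1.08, 0.99, 0.95)); Fh[1, 2] <- 0.03
  u <- as.vector(t(mb$nodes %*% t(Fh) - mb$nodes))
  a <- assemble(m, u, want_matrix = FALSE)
  interior <- which(apply(mb$nodes, 1, function(x) all(x > 0 & x < 1)))
  res <- matrix(a$residual, ncol = 3, byrow = TRUE)[interior, ]
  expect_lt(max(abs(res)), 1e-8 * max(abs(a$fint)))
})

test_that("assembled tangent matches finite differences of the residual", {
  mb <- aortafem:::.mesh_block(seq(0, 1, 0.5), seq(0, 1, 0.5), c(0, 0.5),
                               iface_y = 0.5)
  fib <- aortafem:::.specimen_fibers(nrow(mb$hex), media$theta_deg)
  m <- fe_model(mb$nodes, mb$hex, rep(1L, nrow(mb$hex)), list(media),
                fib$M, fib$N, coh = mb$coh,
                coh_torn = rep(FALSE, nrow(mb$coh)))
  set.seed(21)
  u <- stats::rnorm(m$ndof, sd = 0.01)
  u[seq(2, m$ndof, 3)] <- u[seq(2, m$ndof, 3)] + 0.002  # small opening
  a <- assemble(m, u)
  K <- as.matrix(a$K)
  h <- 1e-6
  for (d in sample(seq_len(m$ndof), 8)) {
    up <- u; up[d] <- up[d] + h
    um <- u; um[d] <- um[d] - h
    cfd <- (assemble(m, up, want_matrix = FALSE)$residual -
            assemble(m, um, want_matrix = FALSE)$residual) / (2 * h)
    expect_lt(max(abs(cfd - K[, d])) / max(abs(K[, d])), 1e-4)
  }
})

test_that("follower pressure: flat square resultant, closed-box balance,
           thin-wall ring hoop stress", {
  # flat unit square, p = 10 kPa -> 10 mN along the normal
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  mq <- fe_model(nodes, matrix(integer(0), 0, 8), integer(0), list(media),
                 matrix(0, 0, 3), matrix(0, 0, 3),
                 pressure_sets = list(S = matrix(1:4, 1)))
  f <- matrix(apply_pressure(mq, "S", 10), ncol = 3, byrow = TRUE)
  expect_equal(colSums(f), c(0, 0, 10), tolerance = 1e-12)

  # closed unit cube: zero resultant
  mb <- aortafem:::.mesh_block(c(0, 1), c(0, 1), c(0, 1))
  faces <- rbind(c(1, 3, 4, 2), c(5, 6, 8, 7),  # z faces (outward)
                 c(1, 2, 6, 5), c(3, 7, 8, 4),  # y faces
                 c(1, 5, 7, 3), c(2, 4, 8, 6))  # x faces
  mc <- fe_model(mb$nodes, matrix(integer(0), 0, 8), integer(0),
                 list(media), matrix(0, 0, 3), matrix(0, 0, 3),
                 pressure_sets = list(S = faces))
  fc <- matrix(apply_pressure(mc, "S", 5), ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colSums(fc))), 1e-10)

  # internally pressurized thin ring: hoop stress ~ p r / t
  spec <- tube_spec(Ri = 10, Ro = 10.5, n_circ = 24, n_axial = 1,
                    nr_inner = 1, nr_mid = 1, nr_adv = 1, half_model = TRUE)
  model <- build_tube_mesh(spec, tear = NULL,
                           materials = list(media, media))
  traj <- solve_quasi_static(model, list(
    list(name = "p", pressures = c(TL = 1))))
  expect_equal(traj$status, "completed")
  bs <- bulk_stress(model, traj$u)
  th <- atan2(bs$y, bs$x)
  s_tt <- bs$sxx * sin(th)^2 - 2 * bs$sxy * sin(th) * cos(th) +
    bs$syy * cos(th)^2
  r_m <- mean(sqrt(bs$x^2 + bs$y^2))
  expect_equal(mean(s_tt), 1 * r_m / 0.5, tolerance = 0.1 * r_m / 0.5)
})

test_that("quasi-static solve of an intact neo-Hookean-limit tube matches
           the incompressible closed-form inflation within 1%", {
  iso <- hgo_params(media$C10, 0, media$k2, media$kappa, 0, media$D)
  spec <- tube_spec(n_circ = 16, n_axial = 2, nr_inner = 2, nr_mid = 2,
                    nr_adv = 2, half_model = TRUE)
  infl <- semi_analytic_inflation(spec, lambda = 1.0, p = 1.5,
                                  materials = list(iso, iso))
  model <- build_tube_mesh(spec, tear = NULL, materials = list(iso, iso))
  traj <- solve_quasi_static(model, list(
    list(name = "p", pressures = c(TL = 1.5))))
  expect_equal(traj$status, "completed")
  disp <- matrix(traj$u, ncol = 3, byrow = TRUE)
  r0 <- sqrt(model$nodes[, 1]^2 + model$nodes[, 2]^2)
  inner <- which(abs(r0 - spec$Ri) < 1e-9)
  r_def <- sqrt((model$nodes[inner, 1] + disp[inner, 1])^2 +
                (model$nodes[inner, 2] + disp[inner, 2])^2)
  # faceted polygon sits slightly inside the true circle; compare means
  expect_equal(mean(r_def), infl$ri,
               tolerance = 0.01 * infl$ri)
})

test_that("peel strip at zero applied displacement has a zero force
           trajectory", {
  s <- specimen_spec("peel")
  s$max_displacement_mm <- 0
  b <- aortafem:::.build_peel_model(s, media, cohesive_media(),
                                    fem_controls(ds0 = 0.5))
  tr <- solve_quasi_static(b$model, list(list(name = "hold",
                                              dirichlet = b$model$dirichlet)))
  expect_equal(tr$status, "completed")
  # forces stay at the level of the adhesion-free contact backstop bias
  # (a fraction of a Pa), negligible against the mN-scale peel forces
  for (fr in tr$frames) expect_lt(max(abs(fr$reactions)), 1e-2)
})

test_that("critical event: schedule ending before initiation returns NULL;
           uniform interface failure is detected at the bilinear failure
           separation with deterministic multi-element reporting", {
  # uniform tension block with 2x2 interface elements; all fail together
  ys <- c(0, 0.3, 0.6)
  mb <- aortafem:::.mesh_block(c(0, 0.5, 1), ys, c(0, 0.5, 1),
                               iface_y = 0.3)
  fib <- aortafem:::.specimen_fibers(nrow(mb$hex), media$theta_deg)
  nn <- nrow(mb$nodes)
  top <- as.vector(mb$idxU[, dim(mb$idxU)[2], ])
  bot <- as.vector(mb$idxL[, 1, ])
  U <- 0.9
  dir <- rbind(
    data.frame(node = seq_len(nn), dof = 1L, value = 0),
    data.frame(node = seq_len(nn), dof = 3L, value = 0),
    data.frame(node = bot, dof = 2L, value = 0),
    data.frame(node = top, dof = 2L, value = U))
  m <- fe_model(mb$nodes, mb$hex, rep(1L, nrow(mb$hex)), list(media),
                fib$M, fib$N, coh = mb$coh,
                coh_torn = rep(FALSE, nrow(mb$coh)),
                dirichlet = dir,
                controls = fem_controls(ds0 = 0.05, ds_max = 0.1))

  # short schedule: no initiation, no critical event
  dir_short <- dir
  dir_short$value[dir_short$value == U] <- 0.05
  tr0 <- solve_quasi_static(m, list(list(name = "short",
                                         dirichlet = dir_short,
                                         critical = TRUE)))
  expect_equal(tr0$status, "completed")
  expect_null(detect_critical_event(tr0, m))

  # full schedule: failure at dn ~ St (plus a small bulk stretch)
  tr <- solve_quasi_static(m, list(list(name = "pull", dirichlet = dir,
                                        critical = TRUE,
                                        p_resolution = 1)))
  expect_equal(tr$status, "critical_failure")
  ev <- detect_critical_event(tr, m)
  expect_s3_class(ev, "critical_event")
  # all four elements fail in the same refined increment, reported in
  # deterministic element order
  expect_equal(ev$elements$id, sort(ev$elements$id))
  expect_equal(nrow(ev$elements), 4)
  # failure at the mode-I failure separation plus the elastic elongation
  # of the 0.6 mm bulk column at the peak traction
  St <- 2 * 49 / 131
  u_fail <- tr$frames[[length(tr$frames)]]$phi * U
  expect_gt(u_fail, St)
  expect_lt(u_fail, St + 0.15)
  # pure opening: mode mix ~ 0
  expect_lt(max(ev$elements$m), 0.01)
})

test_that("global energy balance: external work equals stored energy plus
           cohesive dissipation plus recoverable interface energy", {
  ys <- c(0, 0.3, 0.6)
  mb <- aortafem:::.mesh_block(c(0, 1), ys, c(0, 1), iface_y = 0.3)
  fib <- aortafem:::.specimen_fibers(nrow(mb$hex), media$theta_deg)
  nn <- nrow(mb$nodes)
  top <- as.vector(mb$idxU[, dim(mb$idxU)[2], ])
  bot <- as.vector(mb$idxL[, 1, ])
  dir <- rbind(
    data.frame(node = seq_len(nn), dof = 1L, value = 0),
    data.frame(node = seq_len(nn), dof = 3L, value = 0),
    data.frame(node = bot, dof = 2L, value = 0),
    data.frame(node = top, dof = 2L, value = 0.6))
  m <- fe_model(mb$nodes, mb$hex, rep(1L, nrow(mb$hex)), list(media),
                fib$M, fib$N, coh = mb$coh,
                coh_torn = rep(FALSE, nrow(mb$coh)),
                dirichlet = dir, controls = fem_controls(ds0 = 0.02,
                                                         ds_max = 0.04))
  tr <- solve_quasi_static(m, list(list(name = "pull", dirichlet = dir)))
  expect_equal(tr$status, "completed")
  areas <- aortafem:::.coh_areas(m)
  diss <- sum(areas * rowSums(tr$states[, 3:5, drop = FALSE]))
  W_bulk <- tr$frames[[length(tr$frames)]]$W_bulk
  # recoverable interface energy at the final state
  st <- tr$states
  p <- m$coh_params
  el <- 0.5 * (1 - st[, 1]) *
    (p$Kn * pmax(st[, 8], 0)^2 + p$Ks * st[, 9]^2 + p$Kt * st[, 10]^2)
  el[st[, 6] > 0.5] <- 0
  W_coh_el <- sum(areas * el)
  expect_equal(tr$W_ext, W_bulk + diss + W_coh_el,
               tolerance = 0.02 * max(tr$W_ext, 1))
})

test_that("no interpenetration beyond the penalty-consistent tolerance
           under interface compression", {
  ys <- c(0, 0.3, 0.6)
  mb <- aortafem:::.mesh_block(c(0, 1), ys, c(0, 1), iface_y = 0.3)
  fib <- aortafem:::.specimen_fibers(nrow(mb$hex), media$theta_deg)
  nn <- nrow(mb$nodes)
  top <- as.vector(mb$idxU[, dim(mb$idxU)[2], ])
  bot <- as.vector(mb$idxL[, 1, ])
  dir <- rbind(
    data.frame(node = seq_len(nn), dof = 1L, value = 0),
    data.frame(node = seq_len(nn), dof = 3L, value = 0),
    data.frame(node = bot, dof = 2L, value = 0),
    data.frame(node = top, dof = 2L, value = -0.05))  # compression
  m <- fe_model(mb$nodes, mb$hex, rep(1L, nrow(mb$hex)), list(media),
                fib$M, fib$N, coh = mb$coh,
                coh_torn = rep(TRUE, nrow(mb$coh)),  # torn: contact only
                dirichlet = dir, controls = fem_controls(ds0 = 0.1))
  tr <- solve_quasi_static(m, list(list(name = "push", dirichlet = dir)))
  expect_equal(tr$status, "completed")
  pen <- -min(tr$states[, 8])  # worst normal penetration, mm
  # contact pressure over penalty stiffness bounds the penetration
  p <- m$coh_params
  sig_n <- max(abs(tr$frames[[length(tr$frames)]]$reactions)) /
    aortafem:::.coh_areas(m)[1] / 4
  expect_lt(pen, sig_n / (p$contact_factor * p$Kn) + 2e-4)
  expect_gt(pen, 0)  # contact engaged
})
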