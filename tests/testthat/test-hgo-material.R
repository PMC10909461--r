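# HGO fiber-reinforced hyperelasticity: kinematics, energy, stress,
# consistent tangent.

media <- hgo_media()
advent <- hgo_adventitia()

test_that("bundled parameter tables load the published constants", {
  expect_equal(media$C10, 23.0097)
  expect_equal(media$k1, 127.0692)
  expect_equal(media$k2, 4.4952)
  expect_equal(media$kappa, 0.3201)
  expect_equal(media$theta_deg, 0.0008)
  expect_equal(media$D, 1e-6)
  expect_equal(advent$C10, 8.2649)
  expect_equal(advent$k1, 71.2311)
  expect_equal(advent$k2, 1.6901)
  expect_equal(advent$kappa, 0.3013)
  expect_equal(advent$theta_deg, 0.001)
  expect_equal(advent$D, 1e-6)
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(hgo_params(23, 127, -1, 0.3, 0, 1e-6), "k2")
  expect_error(hgo_params(23, 127, 4.5, 0.5, 0, 1e-6), "kappa")
  expect_error(hgo_params(23, 127, 4.5, 0.3, 0, -1), "D")
})

test_that("kinematics: identity, equibiaxial and simple shear closed forms", {
  st <- compute_kinematics(diag(3), 5)
  expect_equal(st$J, 1)
  expect_equal(st$I1bar, 3)
  expect_equal(st$I4bar, 1)
  expect_equal(st$I6bar, 1)

  # isochoric equibiaxial stretch in the fiber plane: I4bar = I6bar = lam^2
  lam <- 1.2
  st <- compute_kinematics(diag(c(lam, lam, lam^-2)), 37)
  expect_equal(st$J, 1, tolerance = 1e-12)
  expect_equal(st$I4bar, lam^2, tolerance = 1e-12)
  expect_equal(st$I6bar, lam^2, tolerance = 1e-12)

  # simple shear in the fiber plane: I1bar = 3 + gamma^2
  gam <- 0.31
  F <- diag(3); F[1, 2] <- gam
  st <- compute_kinematics(F, 11)
  expect_equal(st$I1bar, 3 + gam^2, tolerance = 1e-12)

  expect_error(compute_kinematics(diag(c(-1, 1, 1)), 0), "det F")
})

test_that("energy vanishes in the reference state for both layers", {
  for (p in list(media, advent)) {
    st <- compute_kinematics(diag(3), p$theta_deg)
    expect_equal(strain_energy_density(st, p), 0)
    expect_equal(max(abs(cauchy_stress(st, p))), 0)
  }
})

test_that("isochoric uniaxial stretch matches a direct scalar evaluation", {
  # independent step-by-step evaluation of the printed energy function for
  # the medial parameters at lambda = 1.1 along the circumferential axis
  lam <- 1.1
  F <- diag(c(lam, 1 / sqrt(lam), 1 / sqrt(lam)))
  th <- 0.0008 * pi / 180
  C <- t(F) %*% F                       # J = 1, Cbar = C
  I1 <- sum(diag(C))
  M <- c(cos(th), sin(th), 0); N <- c(cos(th), -sin(th), 0)
  I4 <- drop(M %*% C %*% M); I6 <- drop(N %*% C %*% N)
  e1 <- 0.3201 * (I1 - 3) + (1 - 3 * 0.3201) * (I4 - 1)
  e2 <- 0.3201 * (I1 - 3) + (1 - 3 * 0.3201) * (I6 - 1)
  W_expected <- 23.0097 * (I1 - 3) +
    127.0692 / (2 * 4.4952) * (exp(4.4952 * e1^2) - 1) +
    127.0692 / (2 * 4.4952) * (exp(4.4952 * e2^2) - 1)
  st <- compute_kinematics(F, media$theta_deg)
  expect_equal(strain_energy_density(st, media), W_expected,
               tolerance = 1e-12)
})

test_that("k1 = 0 reduces the energy to neo-Hookean plus volumetric", {
  p0 <- hgo_params(media$C10, 0, media$k2, media$kappa, media$theta_deg,
                   media$D)
  set.seed(4)
  for (i in 1:5) {
    F <- random_F()
    st <- compute_kinematics(F, p0$theta_deg)
    W_nh <- p0$C10 * (st$I1bar - 3) +
      (1 / p0$D) * ((st$J^2 - 1) / 2 - log(st$J))
    expect_equal(strain_energy_density(st, p0), W_nh, tolerance = 1e-12)
  }
})

test_that("kappa = 1/3 removes all dependence on the fiber invariants", {
  p13 <- hgo_params(media$C10, media$k1, media$k2, 1 / 3, 0, media$D)
  set.seed(5)
  for (i in 1:5) {
    F <- random_F()
    W0 <- strain_energy_density(compute_kinematics(F, 0), p13)
    W90 <- strain_energy_density(compute_kinematics(F, 90), p13)
    W37 <- strain_energy_density(compute_kinematics(F, 37), p13)
    expect_equal(W0, W90, tolerance = 1e-12)
    expect_equal(W0, W37, tolerance = 1e-12)
  }
})

test_that("energy is invariant under superposed rotations", {
  set.seed(6)
  for (i in 1:10) {
    F <- random_F()
    Q <- random_rotation()
    W1 <- strain_energy_density(compute_kinematics(F, media$theta_deg), media)
    W2 <- strain_energy_density(compute_kinematics(Q %*% F, media$theta_deg),
                                media)
    expect_equal(W1, W2, tolerance = 1e-9)
  }
})

test_that("Cauchy stress is objective: sigma(QF) = Q sigma(F) Q^T", {
  set.seed(7)
  for (i in 1:10) {
    F <- random_F()
    Q <- random_rotation()
    s1 <- cauchy_stress(compute_kinematics(F, media$theta_deg), media)
    s2 <- cauchy_stress(compute_kinematics(Q %*% F, media$theta_deg), media)
    expect_equal(s2, Q %*% s1 %*% t(Q), tolerance = 1e-6 * max(abs(s1), 1))
  }
})

test_that("first Piola stress matches finite differences of the energy", {
  set.seed(8)
  h <- 1e-6
  for (i in 1:20) {
    F <- random_F()
    st <- compute_kinematics(F, media$theta_deg)
    P <- pk1_stress(st, media)
    Pfd <- matrix(0, 3, 3)
    for (a in 1:3) for (b in 1:3) {
      Fp <- F; Fp[a, b] <- Fp[a, b] + h
      Fm <- F; Fm[a, b] <- Fm[a, b] - h
      Pfd[a, b] <-
        (strain_energy_density(compute_kinematics(Fp, media$theta_deg), media) -
         strain_energy_density(compute_kinematics(Fm, media$theta_deg), media)) /
        (2 * h)
    }
    expect_lt(max(abs(P - Pfd)) / max(abs(P)), 1e-5)
  }
})

test_that("material tangent has minor/major symmetries, is PD at identity,
           and is consistent with the stress by finite differences", {
  st0 <- compute_kinematics(diag(3), media$theta_deg)
  cc <- material_tangent(st0, media)
  # symmetries
  expect_equal(cc, aperm(cc, c(2, 1, 3, 4)), tolerance = 1e-6 * max(abs(cc)))
  expect_equal(cc, aperm(cc, c(1, 2, 4, 3)), tolerance = 1e-6 * max(abs(cc)))
  expect_equal(cc, aperm(cc, c(3, 4, 1, 2)), tolerance = 1e-6 * max(abs(cc)))
  # positive definite on symmetric perturbations at the reference state
  Cm <- matrix(0, 6, 6)
  idx <- rbind(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (a in 1:6) for (b in 1:6) {
    Cm[a, b] <- cc[idx[a, 1], idx[a, 2], idx[b, 1], idx[b, 2]]
  }
  expect_true(all(eigen(Cm, symmetric = TRUE)$values > 0))

  # consistency: 2 dS/dC from the analytic PK2 via the tangent push-forward
  # checked against finite differences of pk1_stress on random states
  set.seed(9)
  h <- 1e-6
  for (i in 1:3) {
    F <- random_F(0.1)
    st <- compute_kinematics(F, media$theta_deg)
    # FD of S(C) against pullback of material_tangent
    S0 <- solve(F) %*% pk1_stress(st, media)
    cc <- material_tangent(st, media)
    # pull the spatial tensor back: CC_ABCD = J Finv_Ai Finv_Bj ... cc_ijkl
    Fi <- solve(F)
    CC <- array(0, c(3, 3, 3, 3))
    for (A in 1:3) for (B in 1:3) for (Cc in 1:3) for (D in 1:3) {
      s <- 0
      for (ii in 1:3) for (jj in 1:3) for (kk in 1:3) for (ll in 1:3) {
        s <- s + Fi[A, ii] * Fi[B, jj] * Fi[Cc, kk] * Fi[D, ll] *
          cc[ii, jj, kk, ll]
      }
      CC[A, B, Cc, D] <- st$J * s
    }
    dC <- matrix(0, 3, 3); dC[1, 2] <- dC[2, 1] <- h; dC[1, 1] <- h
    Cp <- st$C + dC; Cm2 <- st$C - dC
    Sp <- aortafem:::.hgo_pk2(aortafem:::.state_from_C(Cp, media$theta_deg),
                              media)
    Sm <- aortafem:::.hgo_pk2(aortafem:::.state_from_C(Cm2, media$theta_deg),
                              media)
    dS_fd <- (Sp - Sm) / 2
    dS_cc <- matrix(0, 3, 3)
    for (A in 1:3) for (B in 1:3) {
      dS_cc[A, B] <- 0.5 * sum(CC[A, B, , ] * dC)
    }
    expect_lt(max(abs(dS_fd - dS_cc)) / max(abs(dS_fd)), 1e-4)
  }
})

test_that("swapping the fiber families leaves energy and tangent unchanged", {
  set.seed(10)
  F <- random_F(0.1)
  st1 <- compute_kinematics(F, 20)
  st2 <- compute_kinematics(F, -20)
  p <- hgo_params(media$C10, media$k1, media$k2, media$kappa, 20, media$D)
  expect_equal(strain_energy_density(st1, p), strain_energy_density(st2, p),
               tolerance = 1e-12)
  t1 <- material_tangent(st1, p)
  t2 <- material_tangent(st2, p)
  expect_equal(t1, t2, tolerance = 1e-6 * max(abs(t1)))
})
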