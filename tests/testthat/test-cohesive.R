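# Bilinear mixed-mode cohesive law: initiation, softening, failure,
# energy bookkeeping, mode mix.

cp <- cohesive_media()

test_that("bundled cohesive constants and derived separations", {
  expect_equal(cp$TnC, 131); expect_equal(cp$GIC, 49); expect_equal(cp$Kn, 1638)
  expect_equal(cp$TsC, 97); expect_equal(cp$GIIC, 200); expect_equal(cp$Ks, 35000)
  expect_equal(cp$TtC, 120); expect_equal(cp$GIIIC, 240); expect_equal(cp$Kt, 35000)
  expect_equal(cp$alpha, 1)
  expect_equal(unname(cp$S0["n"]), 131 / 1638)
  expect_equal(unname(cp$St["n"]), 2 * 49 / 131)
  expect_error(cohesive_params(TnC = 1000, GIC = 1, Kn = 10), "St")
  expect_error(cohesive_params(TnC = -5), "positive")
})

test_that("pure-mode monotonic loading: initiation separation, peak
           traction and dissipated energy reproduce the bilinear triangle", {
  modes <- list(
    list(sep = function(x) c(x, 0, 0), S0 = 131 / 1638, St = 2 * 49 / 131,
         TC = 131, GC = 49, gcomp = function(st) st$GI),
    list(sep = function(x) c(0, x, 0), S0 = 97 / 35000, St = 2 * 200 / 97,
         TC = 97, GC = 200, gcomp = function(st) st$GII),
    list(sep = function(x) c(0, 0, x), S0 = 120 / 35000, St = 2 * 240 / 120,
         TC = 120, GC = 240, gcomp = function(st) st$GIII))
  for (md in modes) {
    xs <- seq(0, md$St * 1.02, length.out = 3000)
    path <- t(vapply(xs, md$sep, numeric(3)))
    run <- drive_cohesive(path, cp)
    Tmax <- max(vapply(run$tractions, function(tr) max(tr$Tn, tr$Ts, tr$Tt),
                       1))
    expect_equal(Tmax, md$TC, tolerance = 2e-3)
    # dissipated energy at complete failure = area of the triangle
    expect_equal(md$gcomp(run$state), md$GC, tolerance = 1e-3 * md$GC)
    expect_true(run$state$failed)
    expect_gte(failure_criterion(run$state$GI, run$state$GII,
                                 run$state$GIII, cp), 1 - 1e-4)
  }
})

test_that("mode-I damage initiates at dn = TnC/Kn", {
  S0 <- 131 / 1638  # 0.0800 mm
  r1 <- traction_update(cohesive_state(), c(S0 * 0.999, 0, 0), cp)
  expect_equal(r1$state$d, 0)
  r2 <- traction_update(cohesive_state(), c(S0 * 1.01, 0, 0), cp)
  expect_gt(r2$state$d, 0)
})

test_that("secant unload/reload: no additional dissipation below the
           history separation, damage never decreases", {
  s <- cohesive_state()
  # load to roughly half damage
  St <- 2 * 49 / 131
  for (x in seq(0, 0.45 * St, length.out = 200)) {
    s <- traction_update(s, c(x, 0, 0), cp)$state
  }
  d_half <- s$d; GI_half <- s$GI
  expect_gt(d_half, 0.2)
  # unload to zero and reload to the same point
  for (x in seq(0.45 * St, 0, length.out = 200)) {
    s <- traction_update(s, c(x, 0, 0), cp)$state
  }
  expect_equal(s$d, d_half)
  expect_equal(s$GI, GI_half, tolerance = 1e-9)
  r <- traction_update(s, c(0.44 * St, 0, 0), cp)
  # reload traction retraces the secant (1-d) K dn
  expect_equal(r$traction$Tn, (1 - d_half) * cp$Kn * 0.44 * St,
               tolerance = 1e-6)
  expect_equal(r$state$GI, GI_half, tolerance = 1e-9)
})

test_that("quadratic stress initiation criterion worked identities", {
  expect_equal(initiation_criterion(131, 0, 0, p = cp), 1)
  expect_equal(initiation_criterion(-500, 0, 0, p = cp), 0)
  expect_equal(initiation_criterion(0, 97 / sqrt(2), 120 / sqrt(2), p = cp),
               1, tolerance = 1e-12)
})

test_that("power-law failure criterion worked identities", {
  expect_equal(failure_criterion(49, 0, 0, cp), 1)
  expect_equal(failure_criterion(24.5, 100, 0, cp), 1)
  cp2 <- cohesive_media(); cp2$alpha <- 2
  expect_equal(failure_criterion(0.5 * 49, 0.5 * 200, 0, cp2), 0.5)
})

test_that("mode mix ratio: pure opening 0, pure sliding 1, arithmetic", {
  expect_equal(mode_mix_ratio(5, 0, 0), 0)
  expect_equal(mode_mix_ratio(0, 3, 0), 1)
  expect_equal(mode_mix_ratio(1, 3, 0), 0.75)
  expect_true(is.na(mode_mix_ratio(0, 0, 0)))
})

test_that("compression produces contact reaction, no damage, no
           initiation contribution", {
  r <- traction_update(cohesive_state(), c(-0.01, 0, 0), cp)
  expect_lt(r$traction$Tn, 0)
  expect_equal(r$state$d, 0)
  expect_equal(r$traction$initiation_value, 0)
  expect_equal(r$state$GI, 0)
})

test_that("proportional mixed-mode path matches the brute-force
           incremental oracle", {
  # ds = dn proportional path, fine steps
  xs <- seq(0, 2.0, length.out = 20000)
  path <- cbind(xs, xs, 0)
  bf <- brute_force_cohesive(path, cp)
  run <- drive_cohesive(path, cp)
  expect_equal(run$state$GI, bf$G[1], tolerance = 5e-3 * max(bf$G[1], 1))
  expect_equal(run$state$GII, bf$G[2], tolerance = 5e-3 * max(bf$G[2], 1))
  expect_equal(run$state$d, bf$d, tolerance = 5e-3)
})

test_that("driver reproduces the oracle on random proportional and
           non-proportional paths", {
  set.seed(11)
  for (k in 1:20) {
    if (k <= 10) {
      dirv <- abs(stats::rnorm(3)); dirv <- dirv / sqrt(sum(dirv^2))
      xs <- seq(0, stats::runif(1, 0.5, 3), length.out = 1500)
      path <- outer(xs, dirv)
    } else {
      # piecewise-linear non-proportional path (monotone envelope)
      wp <- matrix(abs(stats::rnorm(9, sd = 0.8)), 3, 3)
      wp <- apply(wp, 2, cumsum)
      path <- NULL
      prev <- c(0, 0, 0)
      for (r in 1:3) {
        seg <- sapply(seq_len(500), function(i) prev + (wp[r, ] - prev) * i / 500)
        path <- rbind(path, t(seg))
        prev <- wp[r, ]
      }
    }
    bf <- brute_force_cohesive(path, cp, nsub = 4)
    run <- drive_cohesive(path, cp)
    GT_bf <- sum(bf$G); GT <- run$state$GI + run$state$GII + run$state$GIII
    expect_equal(GT, GT_bf, tolerance = 0.01 * max(GT_bf, 0.5))
    expect_equal(run$state$d, bf$d, tolerance = 0.01)
  }
})

test_that("damage and per-mode energies are non-decreasing along random
           admissible paths (irreversibility fuzzing)", {
  set.seed(12)
  for (k in 1:10) {
    s <- cohesive_state()
    prev <- c(d = 0, GI = 0, GII = 0, GIII = 0)
    x <- c(0, 0, 0)
    for (i in 1:300) {
      x <- x + stats::rnorm(3, sd = 0.02)
      s <- traction_update(s, x, cp)$state
      now <- c(d = s$d, GI = s$GI, GII = s$GII, GIII = s$GIII)
      expect_true(all(now >= prev - 1e-12))
      prev <- now
    }
  }
})

test_that("final failure separation is insensitive to alpha in {1, 2}
           under pure-mode loading", {
  for (mode in 1:3) {
    seps <- sapply(c(1, 2), function(al) {
      p <- cohesive_media(); p$alpha <- al
      xs <- seq(0, 5, length.out = 8000)
      path <- matrix(0, length(xs), 3); path[, mode] <- xs
      bf_state <- drive_cohesive(path, p)$state
      # failure separation = first separation with failed flag
      s <- cohesive_state()
      for (i in seq_along(xs)) {
        s <- traction_update(s, path[i, ], p)$state
        if (s$failed) return(xs[i])
      }
      NA
    })
    expect_lt(abs(seps[2] - seps[1]) / seps[1], 0.05)
  }
})

test_that("pure-mode dissipated energy is independent of the initial
           stiffness over a x10 range", {
  for (fac in c(1, 10)) {
    p <- cohesive_params(Kn = 1638 * fac, Ks = 35000 * fac, Kt = 35000 * fac)
    xs <- seq(0, 2 * 49 / 131 * 1.02, length.out = 4000)
    run <- drive_cohesive(cbind(xs, 0, 0), p)
    expect_equal(run$state$GI, 49, tolerance = 1e-3 * 49)
  }
})
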