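# Independent brute-force integrator for the bilinear mixed-mode cohesive
# law, used as the oracle for the point-level driver. Implements the law
# directly from its definition (linear rise, quadratic stress initiation,
# linear softening, power-law energy failure) with explicit tiny steps
# and trapezoidal work integration; shares no code with the package
# implementation.
brute_force_cohesive <- function(path, p, nsub = 1) {
  # path: matrix with columns dn, ds, dt (the prescribed separation path);
  # each row is subdivided into nsub equal increments
  Kv <- c(p$Kn, p$Ks, p$Kt)
  TC <- c(p$TnC, p$TsC, p$TtC)
  GC <- c(p$GIC, p$GIIC, p$GIIIC)
  al <- p$alpha
  d <- 0; delmax <- 0
  G <- c(0, 0, 0)
  sep_old <- c(0, 0, 0)
  T_old <- c(0, 0, 0)
  d_init <- NA; d_fail <- NA
  trac <- function(sep, d) {
    Tn <- if (sep[1] >= 0) (1 - d) * Kv[1] * sep[1] else 0
    c(Tn, (1 - d) * Kv[2] * sep[2], (1 - d) * Kv[3] * sep[3])
  }
  for (r in seq_len(nrow(path))) {
    for (ss in seq_len(nsub)) {
      sep <- sep_old + (path[r, ] - sep_old) / (nsub - ss + 1)
      dnp <- max(sep[1], 0)
      dm <- sqrt(dnp^2 + sep[2]^2 + sep[3]^2)
      if (dm > 0) {
        beta <- c(dnp, sep[2], sep[3]) / dm
        dm0 <- 1 / sqrt(sum((Kv * beta / TC)^2))
        dmf <- sum((0.5 * Kv * beta^2 * dm0 / GC)^al)^(-1 / al)
        delmax <- max(delmax, dm)
        if (delmax > dm0) {
          if (is.na(d_init)) d_init <- dm
          dt <- dmf * (delmax - dm0) / (delmax * (dmf - dm0))
          d <- max(d, min(dt, 1))
        }
      }
      T_new <- trac(sep, d)
      # dissipation increment: work minus change of recoverable energy
      for (i in 1:3) {
        s1 <- if (i == 1) max(sep[1], 0) else sep[i]
        s0 <- if (i == 1) max(sep_old[1], 0) else sep_old[i]
        t1 <- if (i == 1) max(T_new[1], 0) else T_new[i]
        t0 <- if (i == 1) max(T_old[1], 0) else T_old[i]
        dG <- 0.5 * (t0 + t1) * (s1 - s0) - (0.5 * t1 * s1 - 0.5 * t0 * s0)
        G[i] <- G[i] + max(dG, 0)
      }
      g <- sum((G / GC)^al)
      if (is.na(d_fail) && (g >= 1 - 1e-6 || d >= 1 - 1e-9)) d_fail <- dm
      sep_old <- sep
      T_old <- T_new
    }
  }
  list(d = d, G = G, d_init = d_init, d_fail = d_fail,
       g = sum((G / GC)^p$alpha))
}

# drive the package point law along a path (rows of separations)
drive_cohesive <- function(path, p, state = cohesive_state()) {
  trs <- vector("list", nrow(path))
  for (r in seq_len(nrow(path))) {
    res <- traction_update(state, path[r, ], p)
    state <- res$state
    trs[[r]] <- res$traction
  }
  list(state = state, tractions = trs)
}

# random rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; cc <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - cc^2 - d^2, 2 * (b * cc - a * d), 2 * (b * d + a * cc),
           2 * (b * cc + a * d), a^2 - b^2 + cc^2 - d^2, 2 * (cc * d - a * b),
           2 * (b * d - a * cc), 2 * (cc * d + a * b), a^2 - b^2 - cc^2 + d^2),
         3, 3, byrow = TRUE)
}

# random deformation gradient with positive determinant near J = 1
random_F <- function(spread = 0.15) {
  repeat {
    F <- diag(3) + matrix(stats::rnorm(9, sd = spread), 3, 3)
    if (det(F) > 0.3) return(F * det(F)^(-1 / 3))
  }
}
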