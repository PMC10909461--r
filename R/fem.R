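# Quasi-static nonlinear FEM: HGO bulk hexahedra (selective reduced
# integration for near-incompressibility), zero-thickness cohesive
# interface elements with penalty contact, follower pressure loads,
# Newton iteration with adaptive load stepping.

#' Solver controls
#'
#' @param rtol Relative residual tolerance (against the larger of the
#'   internal and external force scales).
#' @param atol Absolute residual tolerance, mN.
#' @param max_iter Newton iterations per step before the step is rejected.
#' @param ds0,ds_min,ds_max Initial / minimal / maximal load-factor step.
#' @param grow Step growth factor after quickly converging steps.
#' @param max_steps Safety cap on committed steps per stage.
#' @param line_search Use a backtracking line search in Newton.
#' @param ls_accept When every backtracked trial still raises the
#'   residual: `"strict"` rejects the load step (right for follower-
#'   pressure problems, whose unstable modes diverge), `"tolerant"`
#'   accepts the best trial and keeps iterating (right for
#'   displacement-controlled tests, which pass through local snaps as
#'   cohesive elements fail).
#' @param du_max Cap on the displacement increment per Newton iteration,
#'   mm (Inf disables); guards against wild excursions in bending-
#'   dominated problems.
#' @param stabilize Automatic viscous stabilization factor (0 = off): adds
#'   damping forces `c (u - u_n) ds0/ds` with `c = stabilize *` the mean
#'   diagonal stiffness of the stage, easing neutral/unstable modes
#'   (pressure-loaded flaps, softening). The dissipated stabilization
#'   energy is accumulated on the trajectory so its share of the external
#'   work can be verified to stay small.
#' @param verbose Print per-step convergence information.
#' @return A list of class `fem_controls`.
#' @export
fem_controls <- function(rtol = 1e-5, atol = 1e-6, max_iter = 30,
                         ds0 = 0.05, ds_min = 1e-6, ds_max = 0.2,
                         grow = 1.5, max_steps = 5000,
                         line_search = TRUE, ls_accept = c("strict",
                                                            "tolerant"),
                         du_max = Inf, stabilize = 0, verbose = FALSE) {
  ls_accept <- match.arg(ls_accept)
  structure(list(rtol = rtol, atol = atol, max_iter = max_iter, ds0 = ds0,
                 ds_min = ds_min, ds_max = ds_max, grow = grow,
                 max_steps = max_steps, line_search = line_search,
                 ls_accept = ls_accept, du_max = du_max,
                 stabilize = stabilize, verbose = verbose),
            class = "fem_controls")
}

#' Finite-element model container
#'
#' Assembles mesh, materials, cohesive interface, boundary conditions and
#' load surfaces into a model object for [solve_quasi_static()].
#'
#' @param nodes n x 3 matrix of reference coordinates, mm.
#' @param hex nhex x 8 integer matrix of hexahedral connectivities
#'   (1-based, standard counterclockwise bottom/top ordering).
#' @param hex_mat Integer vector: material index per hexahedron.
#' @param materials List of [hgo_params()] objects.
#' @param fib_M,fib_N nhex x 3 matrices of unit fiber direction vectors in
#'   global coordinates (first and second family).
#' @param coh ncoh x 8 integer matrix of cohesive connectivities (4 bottom
#'   nodes then the 4 coincident top nodes; the bottom quad is ordered so
#'   its normal points bottom-to-top, and its first parametric direction
#'   is the mode-II sliding direction).
#' @param coh_torn Logical vector: pre-torn elements carry no cohesive
#'   stiffness but keep the contact contract.
#' @param coh_params A [cohesive_params()] object.
#' @param dirichlet data.frame with columns `node`, `dof` (1=x,2=y,3=z),
#'   `value` (target displacement, mm); values are ramped by the stage
#'   schedule.
#' @param pressure_sets Named list of nf x 4 integer face matrices
#'   (oriented: the follower force acts along the face normal given by the
#'   right-hand rule).
#' @param prestrain Optional (nhex*8) x 9 matrix of per-Gauss-point
#'   prestrain deformation gradients (row-major), e.g. from
#'   [apply_residual_prestrain()].
#' @param coh_meta Optional data.frame of per-cohesive-element metadata
#'   (e.g. centroid angle and axial position, used for propagation
#'   direction labels).
#' @param controls A [fem_controls()] object.
#' @return An object of class `fe_model`.
#' @export
fe_model <- function(nodes, hex, hex_mat, materials, fib_M, fib_N,
                     coh = NULL, coh_torn = NULL,
                     coh_params = cohesive_media(),
                     dirichlet = NULL, pressure_sets = list(),
                     prestrain = NULL, coh_meta = NULL,
                     controls = fem_controls()) {
  nodes <- as.matrix(nodes)
  hex <- as.matrix(hex)
  storage.mode(hex) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(hex) == 8,
            length(hex_mat) == nrow(hex),
            nrow(hex) == 0 || length(materials) >= max(hex_mat))
  if (is.null(coh)) {
    coh <- matrix(integer(0), 0, 8)
    coh_torn <- logical(0)
  }
  coh <- as.matrix(coh)
  storage.mode(coh) <- "integer"
  if (is.null(coh_torn)) coh_torn <- rep(FALSE, nrow(coh))
  stopifnot(length(coh_torn) == nrow(coh))
  # interface elements must pair coincident faces in the reference mesh
  if (nrow(coh) > 0) {
    gap <- max(abs(nodes[coh[, 1:4], ] - nodes[coh[, 5:8], ]))
    if (gap > 1e-9) stop("cohesive elements must pair coincident faces")
  }
  if (is.null(dirichlet)) {
    dirichlet <- data.frame(node = integer(0), dof = integer(0),
                            value = numeric(0))
  }
  structure(list(nodes = nodes, hex = hex, hex_mat = as.integer(hex_mat),
                 materials = materials,
                 fib_M = as.matrix(fib_M), fib_N = as.matrix(fib_N),
                 coh = coh, coh_torn = coh_torn, coh_params = coh_params,
                 dirichlet = dirichlet, pressure_sets = pressure_sets,
                 prestrain = prestrain, coh_meta = coh_meta,
                 controls = controls,
                 cache = new.env(parent = emptyenv()),
                 ndof = 3L * nrow(nodes)),
            class = "fe_model")
}

#' @export
print.fe_model <- function(x, ...) {
  cat(sprintf("fe_model: %d nodes, %d hexahedra, %d cohesive elements\n",
              nrow(x$nodes), nrow(x$hex), nrow(x$coh)))
  cat(sprintf("  %d prescribed dofs; pressure sets: %s\n",
              nrow(x$dirichlet),
              if (length(x$pressure_sets)) {
                paste(names(x$pressure_sets), collapse = ", ")
              } else "none"))
  invisible(x)
}

.matpar_matrix <- function(materials) {
  t(vapply(materials,
           function(m) c(m$C10, m$k1, m$k2, m$kappa, m$D), numeric(5)))
}

.pressure_stack <- function(model, pressures) {
  sets <- model$pressure_sets
  if (length(sets) == 0) {
    return(list(faces = matrix(integer(0), 0, 4), vals = numeric(0)))
  }
  faces <- do.call(rbind, sets)
  storage.mode(faces) <- "integer"
  vals <- unlist(lapply(names(sets), function(nm) {
    p <- if (nm %in% names(pressures)) pressures[[nm]] else 0
    rep(p, nrow(sets[[nm]]))
  }))
  list(faces = faces, vals = vals)
}

.empty_states <- function(model) {
  matrix(0, nrow = 4L * nrow(model$coh), ncol = 10L)
}

.prestrain_matrix <- function(model) {
  if (is.null(model$prestrain)) matrix(0, 0, 9) else model$prestrain
}

#' Assemble residual and tangent
#'
#' Computes the out-of-balance force vector (internal minus external) and,
#' optionally, the consistent tangent stiffness for a displacement state.
#' The residual includes bulk stress divergence, cohesive tractions,
#' penalty contact reactions across the interface and follower pressures.
#'
#' @param model An [fe_model()].
#' @param u Displacement vector (length `3 * nrow(nodes)`); defaults to
#'   zero.
#' @param states Committed cohesive state matrix (`4*ncoh x 10`); defaults
#'   to pristine.
#' @param pressures Named vector/list of pressures (kPa) per pressure set.
#' @param want_matrix Assemble the sparse tangent as well.
#' @param dtime Pseudo-time increment handed to the viscous regularization.
#' @return List with `residual`, `fint`, `fext`, trial cohesive `states`,
#'   diagnostics (`minJ`, `max_f`, `max_g`, `n_failed`, `W_bulk`, `bad`)
#'   and, if requested, the tangent `K` (dgCMatrix).
#' @export
assemble <- function(model, u = NULL, states = NULL, pressures = NULL,
                     want_matrix = TRUE, dtime = 1) {
  if (is.null(u)) u <- numeric(model$ndof)
  if (is.null(states)) states <- .empty_states(model)
  ps <- .pressure_stack(model, pressures)
  model$cache$n_asm <- c(model$cache$n_asm, 0)[1] + 1
  r <- .assemble_cpp(model$nodes, u, model$hex, model$hex_mat,
                     .matpar_matrix(model$materials),
                     model$fib_M, model$fib_N, .prestrain_matrix(model),
                     model$coh, model$coh_torn, states,
                     .cohpar_vec(model$coh_params),
                     ps$faces, ps$vals, dtime, want_matrix)
  out <- list(residual = r$fint - r$fext, fint = r$fint, fext = r$fext,
              states = r$cohstate, minJ = r$minJ, W_bulk = r$W_bulk,
              max_f = r$max_f, max_g = r$max_g, max_d = r$max_d,
              n_failed = r$n_failed, bad = r$bad)
  if (want_matrix && !r$bad) {
    # the triplet pattern is fixed for a given mesh/load topology, so the
    # CSC structure is computed once and subsequent assemblies only
    # aggregate values into the cached slots
    cache <- model$cache
    if (is.null(cache$ord) || !identical(cache$ntrip, length(r$Tx))) {
      K <- Matrix::sparseMatrix(i = r$Ti + 1L, j = r$Tj + 1L, x = r$Tx,
                                dims = c(model$ndof, model$ndof))
      kj <- rep(seq_len(ncol(K)), diff(K@p))
      key <- as.numeric(r$Ti) * model$ndof + as.numeric(r$Tj)
      kkey <- as.numeric(K@i) * model$ndof + as.numeric(kj - 1L)
      slot <- match(key, kkey)
      ord <- order(slot, method = "radix")
      ends <- cumsum(tabulate(slot, nbins = length(kkey)))
      cache$ord <- ord
      cache$ends <- ends
      cache$i <- K@i
      cache$p <- K@p
      cache$dims <- K@Dim
      cache$ntrip <- length(r$Tx)
      out$K <- K
    } else {
      cs <- cumsum(r$Tx[cache$ord])
      x <- diff(c(0, cs[cache$ends]))
      out$K <- methods::new("dgCMatrix", i = cache$i, p = cache$p, x = x,
                            Dim = cache$dims)
    }
  }
  out
}

#' Follower pressure nodal forces
#'
#' Consistent nodal forces of a uniform pressure acting on an oriented
#' quadrilateral surface set in the deformed configuration (force along
#' the deformed face normal, magnitude pressure times current area).
#'
#' @param model An [fe_model()] whose `pressure_sets` contains `set`.
#' @param set Name of the pressure set.
#' @param p Pressure, kPa.
#' @param u Displacement vector (default zero: reference configuration).
#' @return Nodal force vector of length `ndof`, mN.
#' @export
apply_pressure <- function(model, set, p, u = NULL) {
  stopifnot(set %in% names(model$pressure_sets))
  faces <- model$pressure_sets[[set]]
  if (any(faces < 1 | faces > nrow(model$nodes))) stop("degenerate face set")
  if (is.null(u)) u <- numeric(model$ndof)
  pr <- stats::setNames(list(p), set)
  empty <- fe_model(model$nodes, matrix(integer(0), 0, 8), integer(0),
                    model$materials[1], matrix(0, 0, 3), matrix(0, 0, 3),
                    pressure_sets = model$pressure_sets[set])
  a <- assemble(empty, u = u, pressures = pr, want_matrix = FALSE)
  a$fext
}

# tributary corner areas of every cohesive integration point (reference)
.coh_areas <- function(model) {
  ncoh <- nrow(model$coh)
  if (ncoh == 0) return(numeric(0))
  xc <- c(-1, 1, 1, -1); ec <- c(-1, -1, 1, 1)
  areas <- numeric(4 * ncoh)
  for (e in seq_len(ncoh)) {
    Xm <- (model$nodes[model$coh[e, 1:4], , drop = FALSE] +
           model$nodes[model$coh[e, 5:8], , drop = FALSE]) / 2
    for (k in 1:4) {
      t1 <- colSums(0.25 * xc * (1 + ec * ec[k]) * Xm)
      t2 <- colSums(0.25 * ec * (1 + xc * xc[k]) * Xm)
      cr <- c(t1[2] * t2[3] - t1[3] * t2[2],
              t1[3] * t2[1] - t1[1] * t2[3],
              t1[1] * t2[2] - t1[2] * t2[1])
      areas[4 * (e - 1) + k] <- sqrt(sum(cr^2))
    }
  }
  areas
}

# element-level complete-damage flags from a state matrix
.coh_elements_failed <- function(model, states) {
  ncoh <- nrow(model$coh)
  if (ncoh == 0) return(logical(0))
  f <- states[, 6] > 0.5
  el <- matrix(f, nrow = 4)
  as.logical(colSums(el) == 4) & !model$coh_torn
}

#' Solve a staged quasi-static problem
#'
#' Ramps each stage's Dirichlet targets and set pressures by a load factor
#' from the state left by the previous stage, committing converged Newton
#' steps and halving the load-factor step on divergence. A stage marked
#' `critical = TRUE` refines the load factor by bisection until the first
#' complete cohesive-element failure is bracketed to `p_resolution` (kPa)
#' and stops there.
#'
#' @param model An [fe_model()].
#' @param stages List of stages; each a list with optional entries
#'   `name`, `dirichlet` (data.frame node/dof/value with stage-end
#'   targets), `pressures` (named vector of stage-end pressures, kPa),
#'   `critical` (logical), `p_resolution` (kPa, default 1).
#' @param u0,states0 Initial displacements / committed cohesive states
#'   (defaults: zero / pristine).
#' @param controls A [fem_controls()]; defaults to the model's.
#' @return An object of class `fe_trajectory`: committed `frames` (load
#'   factor, pressures, reactions, diagnostics, element failure flags),
#'   final displacement `u`, final committed cohesive `states`, energy
#'   accumulators, and a `status` string (`"completed"`,
#'   `"critical_failure"` or `"not_converged"`).
#' @export
solve_quasi_static <- function(model, stages, u0 = NULL, states0 = NULL,
                               controls = NULL) {
  ctrl <- if (is.null(controls)) model$controls else controls
  u <- if (is.null(u0)) numeric(model$ndof) else u0
  states <- if (is.null(states0)) .empty_states(model) else states0
  pdof <- 3L * (model$dirichlet$node - 1L) + model$dirichlet$dof
  frames <- list()
  Wext <- 0
  E_stab <- 0
  fext_prev <- numeric(model$ndof)
  react_prev <- numeric(length(pdof))
  pressures_prev <- numeric(0)
  status <- "completed"
  crit <- NULL

  for (si in seq_along(stages)) {
    st <- stages[[si]]
    nm <- if (!is.null(st$name)) st$name else sprintf("stage%d", si)
    critical <- isTRUE(st$critical)
    pres_res <- if (!is.null(st$p_resolution)) st$p_resolution else 1
    # stage-start and stage-end values
    u_presc0 <- u[pdof]
    presc1 <- u_presc0
    if (!is.null(st$dirichlet)) {
      key <- paste(model$dirichlet$node, model$dirichlet$dof)
      tkey <- paste(st$dirichlet$node, st$dirichlet$dof)
      mi <- match(tkey, key)
      if (anyNA(mi)) stop("stage prescribes a dof absent from the model")
      presc1[mi] <- st$dirichlet$value
    }
    allsets <- names(model$pressure_sets)
    p0 <- stats::setNames(rep(0, length(allsets)), allsets)
    p0[names(pressures_prev)] <- pressures_prev
    p1 <- p0
    if (!is.null(st$pressures)) p1[names(st$pressures)] <- unlist(st$pressures)
    pmeas <- max(abs(p1 - p0), 0)

    phi <- 0
    ds <- ctrl$ds0
    nsteps <- 0
    n_ok <- 0
    max_f_prev <- 0
    du_last <- NULL
    dphi_last <- NA
    stab_c <- 0
    if (ctrl$stabilize > 0) {
      a0 <- assemble(model, u, states, as.list(p0), want_matrix = TRUE,
                     dtime = ctrl$ds0)
      if (!a0$bad) {
        free0 <- setdiff(seq_len(model$ndof), pdof)
        stab_c <- ctrl$stabilize * mean(abs(Matrix::diag(a0$K)[free0]))
      }
    }
    el_failed <- .coh_elements_failed(model, states)
    repeat {
      if (phi >= 1 - 1e-12) break
      if (nsteps >= ctrl$max_steps) { status <- "not_converged"; break }
      phi_t <- min(1, phi + ds)
      dphi <- phi_t - phi
      ut <- u
      # secant predictor: extrapolate the last converged increment
      if (!is.null(du_last) && is.finite(dphi_last) && dphi_last > 0) {
        ut <- u + (dphi / dphi_last) * du_last
      }
      ut[pdof] <- u_presc0 + phi_t * (presc1 - u_presc0)
      pt <- p0 + phi_t * (p1 - p0)
      mstep <- model
      if (isTRUE(st$prestrain_ramp) && !is.null(model$prestrain)) {
        eye <- matrix(rep(as.vector(diag(3)), nrow(model$prestrain)),
                      ncol = 9, byrow = TRUE)
        mstep$prestrain <- (1 - phi_t) * eye + phi_t * model$prestrain
      }
      stab <- if (stab_c > 0) {
        list(c = stab_c * ctrl$ds0 / dphi, uref = u)
      } else NULL
      ns <- .newton(mstep, ut, states, pt, pdof, ctrl, dtime = dphi,
                    stab = stab)
      if (!ns$converged) {
        model$cache$n_rej <- c(model$cache$n_rej, 0)[1] + 1
        n_ok <- 0
        du_last <- NULL
        ds <- ds / 2
        if (ds < ctrl$ds_min) { status <- "not_converged"; break }
        next
      }
      new_fail <- .coh_elements_failed(model, ns$states) & !el_failed
      if (critical && any(new_fail) && dphi * pmeas > pres_res &&
          ds / 2 >= ctrl$ds_min) {
        ds <- ds / 2  # bracket the first complete failure
        next
      }
      if (isTRUE(st$refine_initiation) && ns$max_d > 1e-8 &&
          max_f_prev <= 1e-8 && dphi > 2e-3 && ds / 2 >= ctrl$ds_min) {
        ds <- ds / 2  # resolve the damage-initiation peak
        next
      }
      # commit
      nsteps <- nsteps + 1
      Wext <- Wext +
        sum(0.5 * (fext_prev + ns$fext) * (ns$u - u)) +
        sum(0.5 * (react_prev + ns$react) * (ns$u[pdof] - u[pdof]))
      du_last <- ns$u - u
      dphi_last <- dphi
      if (!is.null(stab)) {
        E_stab <- E_stab + stab$c * sum((ns$u - u)^2)
      }
      u <- ns$u
      states <- ns$states
      fext_prev <- ns$fext
      react_prev <- ns$react
      el_failed <- .coh_elements_failed(model, states)
      max_f_prev <- max(max_f_prev, ns$max_d)
      phi <- phi_t
      frames[[length(frames) + 1L]] <- list(
        stage = nm, phi = phi, pressures = pt,
        prescribed = ut[pdof], reactions = ns$react,
        minJ = ns$minJ, max_f = ns$max_f, max_g = ns$max_g,
        n_failed_points = ns$n_failed, W_bulk = ns$W_bulk,
        el_failed = el_failed, iters = ns$iters)
      if (ctrl$verbose) {
        cat(sprintf("[%s] phi=%.4f iters=%d max_g=%.3f failed=%d\n",
                    nm, phi, ns$iters, ns$max_g, sum(el_failed)))
      }
      if (critical && any(new_fail)) {
        crit <- list(stage = nm, frame = length(frames),
                     elements = which(new_fail), pressures = pt)
        status <- "critical_failure"
        break
      }
      if (!is.null(st$stop_frac_failed) && sum(!model$coh_torn) > 0 &&
          sum(el_failed) / sum(!model$coh_torn) >= st$stop_frac_failed) {
        break
      }
      n_ok <- n_ok + 1
      if (ns$iters <= 8 && n_ok >= 3) ds <- min(ds * ctrl$grow, ctrl$ds_max)
    }
    pressures_prev <- p0 + phi * (p1 - p0)
    if (status != "completed") break
  }

  structure(list(frames = frames, u = u, states = states,
                 W_ext = Wext, E_stab = E_stab, status = status,
                 critical = crit, dirichlet_dofs = pdof),
            class = "fe_trajectory")
}

# cached extraction of the free-dof submatrix (the CSC positions of the
# free block are fixed for a given mesh and constraint set)
.submatrix_ff <- function(model, K, free) {
  cache <- model$cache
  if (!identical(cache$ff_free, free) ||
      !identical(cache$ff_nnz, length(K@x))) {
    freemask <- logical(model$ndof)
    freemask[free] <- TRUE
    cols <- rep(seq_len(model$ndof), diff(K@p))
    sel <- which(freemask[K@i + 1L] & freemask[cols])
    Kff <- K[free, free, drop = FALSE]
    cache$ff_free <- free
    cache$ff_nnz <- length(K@x)
    cache$ff_sel <- sel
    cache$ff_i <- Kff@i
    cache$ff_p <- Kff@p
    cache$ff_dims <- Kff@Dim
    return(Kff)
  }
  methods::new("dgCMatrix", i = cache$ff_i, p = cache$ff_p,
               x = K@x[cache$ff_sel], Dim = cache$ff_dims)
}

# Newton iteration at fixed prescribed values/pressures.
# Returns converged flag, displacement, trial-committed states, forces.
.newton <- function(model, u, states, pressures, pdof, ctrl, dtime,
                    stab = NULL) {
  free <- setdiff(seq_len(model$ndof), pdof)
  rmod <- function(a, u) {
    r <- a$residual
    if (!is.null(stab)) {
      r[free] <- r[free] + stab$c * (u[free] - stab$uref[free])
    }
    r
  }
  a <- assemble(model, u, states, as.list(pressures),
                want_matrix = TRUE, dtime = dtime)
  K <- a$K
  for (it in seq_len(ctrl$max_iter)) {
    if (a$bad || any(!is.finite(a$residual))) {
      return(list(converged = FALSE, iters = it))
    }
    rv <- rmod(a, u)
    rn <- max(abs(rv[free]))
    ref <- max(abs(a$fint), abs(a$fext), 1)
    if (isTRUE(ctrl$verbose > 1)) {
      cat(sprintf("    it %d rn %.3e ref %.3e ming %.3f\n", it, rn, ref, a$minJ))
    }
    if (rn <= ctrl$rtol * ref + ctrl$atol) {
      return(list(converged = TRUE, u = u, states = a$states,
                  fext = a$fext, react = a$residual[pdof],
                  minJ = a$minJ, max_f = a$max_f, max_g = a$max_g,
                  max_d = a$max_d, n_failed = a$n_failed,
                  W_bulk = a$W_bulk, iters = it))
    }
    Kff <- .submatrix_ff(model, K, free)
    if (!is.null(stab)) {
      Kff <- Kff + stab$c * Matrix::Diagonal(length(free))
    }
    du <- tryCatch(
      as.numeric(Matrix::solve(Kff, -rv[free])),
      error = function(e) NULL)
    if (is.null(du) || any(!is.finite(du))) {
      return(list(converged = FALSE, iters = it))
    }
    if (is.finite(ctrl$du_max)) {
      mx <- max(abs(du))
      if (mx > ctrl$du_max) du <- du * (ctrl$du_max / mx)
    }
    # full Newton step with backtracking (residual-only trials); a step
    # that cannot at least roughly hold the residual is rejected so the
    # load increment is cut
    step <- 1
    u_try <- u
    accepted <- FALSE
    best <- NULL
    for (ls in 1:5) {
      u_try[free] <- u[free] + step * du
      a_try <- assemble(model, u_try, states, as.list(pressures),
                        want_matrix = FALSE, dtime = dtime)
      ok <- !a_try$bad && all(is.finite(a_try$residual))
      if (ok) {
        rt <- max(abs(rmod(a_try, u_try)[free]))
        if (!ctrl$line_search || rt < 2 * rn) {
          accepted <- TRUE
          break
        }
        if (is.null(best) || rt < best$rt) best <- list(u = u_try, rt = rt)
      }
      step <- step / 2
    }
    if (!accepted) {
      if (identical(ctrl$ls_accept, "tolerant") && !is.null(best)) {
        u_try <- best$u
      } else {
        return(list(converged = FALSE, iters = it))
      }
    }
    u <- u_try
    a <- assemble(model, u, states, as.list(pressures),
                  want_matrix = TRUE, dtime = dtime)
    K <- a$K
  }
  list(converged = FALSE, iters = ctrl$max_iter)
}

#' Detect the critical propagation event of a pressure-ramp trajectory
#'
#' Returns the lowest pressure at which a cohesive element was completely
#' damaged (all of its integration points satisfy the power-law energy
#' criterion), together with the element(s) involved, their propagation
#' direction label, mode mix ratio and tractions at criticality.
#' Simultaneous failures within the refined increment are all reported,
#' ordered deterministically by (direction, element index).
#'
#' @param traj An `fe_trajectory` from [solve_quasi_static()].
#' @param model The [fe_model()] that produced it (its `coh_meta` supplies
#'   tear-front geometry for the direction labels).
#' @param pressure_set Name of the pressure set whose value is reported as
#'   the critical pressure (default `"TL"`, falling back to the first).
#' @return A `critical_event` (list with `Pc` kPa, data.frame `elements`
#'   with `id`, `direction`, `m`, `Tn`, `Ts`, `Tt`), or `NULL` when the
#'   schedule ended without complete failure.
#' @export
detect_critical_event <- function(traj, model, pressure_set = "TL") {
  if (is.null(traj$critical)) return(NULL)
  cr <- traj$critical
  pt <- cr$pressures
  if (!pressure_set %in% names(pt)) pressure_set <- names(pt)[1]
  Pc <- if (length(pt) == 0 || is.null(pressure_set) ||
            is.na(pressure_set)) NA_real_ else unname(pt[[pressure_set]])
  ids <- cr$elements
  meta <- model$coh_meta
  rows <- lapply(ids, function(e) {
    idx <- 4 * (e - 1) + 1:4
    stc <- traj$states[idx, , drop = FALSE]
    GI <- sum(stc[, 3]); GII <- sum(stc[, 4]); GIII <- sum(stc[, 5])
    # traction state just before removal, from the point with largest
    # energy criterion: secant tractions at its last separations
    g <- stc[, 3] / model$coh_params$GIC + stc[, 4] / model$coh_params$GIIC +
      stc[, 5] / model$coh_params$GIIIC
    k <- which.max(g)
    d <- stc[k, 1]; sep <- stc[k, 8:10]
    p <- model$coh_params
    Tn <- if (sep[1] >= 0) (1 - d) * p$Kn * sep[1] else 0
    dirn <- .propagation_direction(model, e)
    data.frame(id = e, direction = dirn,
               m = mode_mix_ratio(GI, GII, GIII),
               Tn = Tn, Ts = (1 - d) * p$Ks * sep[2],
               Tt = (1 - d) * p$Kt * sep[3])
  })
  el <- do.call(rbind, rows)
  el <- el[order(el$direction, el$id), , drop = FALSE]
  rownames(el) <- NULL
  structure(list(Pc = Pc, elements = el,
                 pressures = pt, frame = cr$frame),
            class = "critical_event")
}

.propagation_direction <- function(model, e) {
  meta <- model$coh_meta
  if (is.null(meta)) return(NA_character_)
  exc_th <- (abs(meta$theta_deg[e]) - meta$eta_half[e]) / max(meta$eta_half[e], 1)
  exc_z <- (abs(meta$z[e] - meta$z_center[e]) - meta$s_half[e]) /
    max(meta$s_half[e], 1e-9)
  if (exc_z > 0 && exc_z >= exc_th) "axial"
  else if (exc_th > 0) "circumferential"
  else "axial"
}

#' @export
print.critical_event <- function(x, ...) {
  cat(sprintf("Critical event: Pc = %g kPa\n", x$Pc))
  print(x$elements)
  invisible(x)
}

#' Per-element centroid Cauchy stresses
#'
#' @param model An [fe_model()].
#' @param u Displacement vector.
#' @return data.frame: deformed centroid `x,y,z` (mm), Cauchy components
#'   `sxx, syy, szz, sxy, sxz, syz` (kPa) and volume ratio `J`.
#' @export
bulk_stress <- function(model, u = NULL) {
  if (is.null(u)) u <- numeric(model$ndof)
  m <- .hex_stress_cpp(model$nodes, u, model$hex, model$hex_mat,
                       .matpar_matrix(model$materials),
                       model$fib_M, model$fib_N, .prestrain_matrix(model))
  out <- as.data.frame(m)
  names(out) <- c("x", "y", "z", "sxx", "syy", "szz", "sxy", "sxz", "syz", "J")
  out
}

#' Interface summary of a trajectory
#'
#' Aggregates the committed cohesive states per element: damage, per-mode
#' dissipated energies (area-weighted, mN/mm), mode mix and failure flag.
#'
#' @param traj An `fe_trajectory`.
#' @param model The corresponding [fe_model()].
#' @return data.frame, one row per cohesive element.
#' @export
interface_summary <- function(traj, model) {
  ncoh <- nrow(model$coh)
  if (ncoh == 0) return(data.frame())
  st <- traj$states
  idx <- rep(seq_len(ncoh), each = 4)
  agg <- function(col) as.numeric(tapply(st[, col], idx, mean))
  GI <- agg(3); GII <- agg(4); GIII <- agg(5)
  data.frame(element = seq_len(ncoh),
             damage = agg(1), GI = GI, GII = GII, GIII = GIII,
             m = ifelse(GI + GII + GIII > 0, 1 - GI / (GI + GII + GIII), NA),
             failed = .coh_elements_failed(model, st),
             torn = model$coh_torn)
}
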