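# Expensive simulation results shared across test files, computed once
# per test session.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# default-resolution peel with the bundled parameters
peel_baseline <- function() cached("peel_baseline", run_peel_test())

# coarse, fast peel specimen for sweeps/calibration round trips
peel_cheap_spec <- function() {
  s <- specimen_spec("peel")
  s$nx <- 32
  s$max_displacement_mm <- 3.2
  s
}

peel_cheap_forward <- function() {
  cached("peel_cheap_forward", run_peel_test(spec = peel_cheap_spec()))
}

tension_baseline <- function() cached("tension", run_direct_tension())
shear_rtheta_baseline <- function() cached("shear_rtheta",
                                           run_shear_test(direction = "rtheta"))
shear_rz_baseline <- function() cached("shear_rz",
                                       run_shear_test(direction = "rz"))

# coarse desk-scale tube discretization with refined tear fronts
desk_tube_spec <- function() {
  tube_spec(n_circ = 6, n_axial = 3, nr_inner = 2, nr_mid = 1, nr_adv = 1,
            half_model = TRUE, half_axial = TRUE, n_fine_circ = 2,
            n_fine_axial = 2)
}

desk_tube_controls <- function() {
  fem_controls(rtol = 1e-4, atol = 1e-4, max_iter = 16, ds0 = 0.05,
               ds_max = 0.1, grow = 2)
}

# pressurize a tear case to a fixed sub-critical pressure and report the
# interface state (used for desk-scale trend surrogates on the failure
# criterion)
tube_g_probe <- function(t_ratio = 0.4, lambda = 1.02, p_TL = 8,
                         p_FL = 8, opening = 0) {
  key <- paste("probe", t_ratio, lambda, p_TL, p_FL, opening)
  cached(key, {
    model <- build_tube_mesh(desk_tube_spec(),
                             tear_geometry(150, 10, t_ratio),
                             controls = desk_tube_controls())
    res <- run_pressurization(model, load_case(lambda, p_TL, p_FL, opening))
    list(res = res, model = model,
         max_g = max(vapply(res$trajectory$frames,
                            function(f) f$max_g, 1)))
  })
}

# very small, fast pressurization (stops at a low cap) for export tests
tube_smoke <- function() {
  cached("tube_smoke", {
    spec <- tube_spec(n_circ = 6, n_axial = 3, nr_inner = 1, nr_mid = 1,
                      nr_adv = 1, half_model = TRUE, half_axial = TRUE,
                      n_fine_circ = 2, n_fine_axial = 2)
    model <- build_tube_mesh(spec, tear_geometry(150, 10, 0.4),
                             controls = desk_tube_controls())
    res <- run_pressurization(model, load_case(1.02, 5, 5, 0))
    list(res = res, model = model)
  })
}
tube_smoke_result <- function() tube_smoke()$res
tube_smoke_model <- function() tube_smoke()$model
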