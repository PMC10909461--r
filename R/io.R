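# Configuration files, result export (legacy-ASCII VTK + CSV) and the
# command-line entry points.
#
# All physical quantities in config keys carry unit suffixes (kPa, mm,
# deg, ...) to prevent unit drift; defaults are the baseline tear case
# (eta = 150 deg, t = 0.4, s = 10 mm, lambda = 1.02, equal lumen
# pressures, no residual stress) with the bundled material tables.

#' Baseline run configuration
#'
#' @return Nested list (class `run_config`) holding geometry, mesh,
#'   material, cohesive, load, solver and output blocks with the baseline
#'   defaults.
#' @export
default_config <- function() {
  bulk <- .load_bulk_constants()
  cohp <- cohesive_media()
  cfg <- list(
    geometry = list(
      Ri_mm = 7.5, Ro_mm = 9.0, media_fraction = 5 / 8,
      tear = list(eta_deg = 150, s_mm = 10, t_ratio = 0.4)),
    mesh = list(n_circ = 18, n_axial = 6, nr_inner = 2, nr_mid = 2,
                nr_adv = 1, half_model = TRUE),
    material = list(media = bulk$media, adventitia = bulk$adventitia),
    cohesive = list(TnC_kPa = cohp$TnC, TsC_kPa = cohp$TsC,
                    TtC_kPa = cohp$TtC, GIC_mN_per_mm = cohp$GIC,
                    GIIC_mN_per_mm = cohp$GIIC, GIIIC_mN_per_mm = cohp$GIIIC,
                    Kn_mN_per_mm3 = cohp$Kn, Ks_mN_per_mm3 = cohp$Ks,
                    Kt_mN_per_mm3 = cohp$Kt, alpha = cohp$alpha,
                    mu_visc = 0),
    load = list(lambda_axial = 1.02, p_TL_kPa = 500, p_FL_kPa = 500,
                opening_angle_deg = 0),
    solver = list(rtol = 1e-5, atol_mN = 1e-6, max_iter = 30, ds0 = 0.05,
                  ds_min = 1e-6, ds_max = 0.2, p_resolution_kPa = 1),
    output = list(directory = "aortafem_out",
                  formats = c("csv", "vtk")))
  class(cfg) <- "run_config"
  cfg
}

.validate_against <- function(x, template, path = "") {
  for (nm in names(x)) {
    if (!nm %in% names(template)) {
      stop("unknown configuration key: ", paste0(path, nm))
    }
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      if (!is.list(x[[nm]])) {
        stop("configuration key ", paste0(path, nm), " must be a block")
      }
      .validate_against(x[[nm]], template[[nm]], paste0(path, nm, "$"))
    }
  }
  invisible(TRUE)
}

#' Parse a run configuration file
#'
#' Reads a YAML configuration, fills unset keys with the baseline
#' defaults, and rejects unknown keys. Ranges are validated through the
#' domain constructors ([tear_geometry()], [load_case()],
#' [cohesive_params()], [hgo_params()]).
#'
#' @param path Path to a YAML file; an empty file yields the full
#'   baseline defaults.
#' @return A validated `run_config`.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  def <- default_config()
  .validate_against(user, def)
  cfg <- modifyList(unclass(def), user)
  class(cfg) <- "run_config"
  # range validation via the domain constructors
  invisible(config_objects(cfg))
  cfg
}

#' Serialize a configuration to YAML
#'
#' `parse_config(write_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param cfg A `run_config`. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Instantiate model-building objects from a configuration
#'
#' @param cfg A `run_config`.
#' @return List: `spec` ([tube_spec()]), `tear` ([tear_geometry()]),
#'   `materials`, `coh_params`, `case` ([load_case()]), `controls`,
#'   `p_resolution`.
#' @export
config_objects <- function(cfg) {
  g <- cfg$geometry; m <- cfg$mesh; s <- cfg$solver
  mat <- function(b) hgo_params(b$C10_kPa, b$k1_kPa, b$k2, b$kappa,
                                b$theta_deg, b$D_per_kPa)
  co <- cfg$cohesive
  list(
    spec = tube_spec(g$Ri_mm, g$Ro_mm, g$media_fraction, m$n_circ,
                     m$n_axial, m$nr_inner, m$nr_mid, m$nr_adv,
                     m$half_model),
    tear = tear_geometry(g$tear$eta_deg, g$tear$s_mm, g$tear$t_ratio),
    materials = list(mat(cfg$material$media), mat(cfg$material$adventitia)),
    coh_params = cohesive_params(co$TnC_kPa, co$TsC_kPa, co$TtC_kPa,
                                 co$GIC_mN_per_mm, co$GIIC_mN_per_mm,
                                 co$GIIIC_mN_per_mm, co$Kn_mN_per_mm3,
                                 co$Ks_mN_per_mm3, co$Kt_mN_per_mm3,
                                 co$alpha, mu_visc = co$mu_visc),
    case = load_case(cfg$load$lambda_axial, cfg$load$p_TL_kPa,
                     cfg$load$p_FL_kPa, cfg$load$opening_angle_deg),
    controls = fem_controls(rtol = s$rtol, atol = s$atol_mN,
                            max_iter = s$max_iter, ds0 = s$ds0,
                            ds_min = s$ds_min, ds_max = s$ds_max),
    p_resolution = s$p_resolution_kPa)
}

# ---------------------------------------------------------------------------
# legacy-ASCII VTK unstructured grid writer
# ---------------------------------------------------------------------------

#' Write an unstructured grid as a legacy-ASCII VTK file
#'
#' @param path Output file.
#' @param nodes n x 3 coordinates.
#' @param cells List of integer vectors (1-based connectivities).
#' @param cell_types Integer VTK cell type per cell (12 = hexahedron,
#'   9 = quad).
#' @param point_data,cell_data Named lists of numeric vectors/matrices
#'   (matrices are written as 3-vectors).
#' @return `path`, invisibly.
#' @export
write_vtk <- function(path, nodes, cells, cell_types,
                      point_data = list(), cell_data = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  num <- function(x) formatC(x, format = "g", digits = 9)
  wl("# vtk DataFile Version 3.0")
  wl("aortafem state")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", nrow(nodes)))
  wl(apply(nodes, 1, function(r) paste(num(r), collapse = " ")))
  ntot <- sum(vapply(cells, length, 1L)) + length(cells)
  wl(sprintf("CELLS %d %d", length(cells), ntot))
  wl(vapply(cells, function(cc)
    paste(c(length(cc), cc - 1L), collapse = " "), ""))
  wl(sprintf("CELL_TYPES %d", length(cells)))
  wl(as.character(cell_types))
  wdata <- function(dat, n, kind) {
    if (!length(dat)) return()
    wl(sprintf("%s %d", kind, n))
    for (nm in names(dat)) {
      v <- dat[[nm]]
      if (is.matrix(v)) {
        wl(sprintf("VECTORS %s double", nm))
        wl(apply(v, 1, function(r) paste(num(r), collapse = " ")))
      } else {
        wl(sprintf("SCALARS %s double 1", nm))
        wl("LOOKUP_TABLE default")
        wl(num(v))
      }
    }
  }
  wdata(point_data, nrow(nodes), "POINT_DATA")
  wdata(cell_data, length(cells), "CELL_DATA")
  invisible(path)
}

#' Export results to VTK and CSV files
#'
#' For a `tube_result`: writes `summary.csv` (one row: tear parameters,
#' loading, critical pressure, direction, mode mix and tractions),
#' `trajectory.csv` (one row per converged step: stage, load factor,
#' pressures, damage diagnostics) and, for the final state,
#' `state_bulk.vtk` (hexahedra + displacement vectors) and
#' `state_interface.vtk` (interface quads + damage, per-mode energies and
#' mode mix). For a sweep table or test curve: writes it as `<name>.csv`.
#'
#' @param result A `tube_result`, sweep data.frame or `test_curve`.
#' @param model The [fe_model()] (required for `tube_result` exports).
#' @param dir Output directory (created if missing).
#' @param formats Subset of `c("csv", "vtk")`.
#' @param name Base name for plain-table exports.
#' @return Character vector of files written, invisibly.
#' @export
export_results <- function(result, model = NULL, dir = "aortafem_out",
                           formats = c("csv", "vtk"), name = "results") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  written <- character(0)
  wcsv <- function(df, f) {
    p <- file.path(dir, f)
    write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  if (inherits(result, "tube_result")) {
    if ("csv" %in% formats) {
      ev <- result$event
      tear <- model$tube$tear
      row <- data.frame(
        eta_deg = tear$eta_deg, s_mm = tear$s_mm, t_ratio = tear$t_ratio,
        lambda = result$case$lambda_axial,
        opening_angle_deg = result$case$opening_angle_deg,
        LPD_kPa = result$case$LPD,
        Pc_kPa = if (is.null(ev)) NA else ev$Pc,
        direction = if (is.null(ev)) NA else ev$elements$direction[1],
        m = if (is.null(ev)) NA else ev$elements$m[1],
        Tn_kPa = if (is.null(ev)) NA else ev$elements$Tn[1],
        Ts_kPa = if (is.null(ev)) NA else ev$elements$Ts[1],
        Tt_kPa = if (is.null(ev)) NA else ev$elements$Tt[1],
        status = result$status)
      wcsv(row, "summary.csv")
      tr <- do.call(rbind, lapply(result$trajectory$frames, function(fr) {
        data.frame(stage = fr$stage, phi = fr$phi,
                   p_TL_kPa = if ("TL" %in% names(fr$pressures))
                     fr$pressures[["TL"]] else 0,
                   p_FL_kPa = if ("FL" %in% names(fr$pressures))
                     fr$pressures[["FL"]] else 0,
                   max_f = fr$max_f, max_g = fr$max_g,
                   n_failed_points = fr$n_failed_points,
                   n_failed_elements = sum(fr$el_failed), iters = fr$iters)
      }))
      wcsv(tr, "trajectory.csv")
    }
    if ("vtk" %in% formats && !is.null(model)) {
      u <- matrix(result$trajectory$u, ncol = 3, byrow = TRUE)
      p1 <- file.path(dir, "state_bulk.vtk")
      write_vtk(p1, model$nodes,
                lapply(seq_len(nrow(model$hex)), function(i) model$hex[i, ]),
                rep(12L, nrow(model$hex)),
                point_data = list(displacement = u))
      isum <- result$interface
      p2 <- file.path(dir, "state_interface.vtk")
      write_vtk(p2, model$nodes,
                lapply(seq_len(nrow(model$coh)),
                       function(i) model$coh[i, 1:4]),
                rep(9L, nrow(model$coh)),
                point_data = list(displacement = u),
                cell_data = list(damage = isum$damage, GI = isum$GI,
                                 GII = isum$GII, GIII = isum$GIII,
                                 mode_mix = ifelse(is.na(isum$m), -1, isum$m),
                                 torn = as.numeric(isum$torn),
                                 failed = as.numeric(isum$failed)))
      written <- c(written, p1, p2)
    }
  } else if (is.data.frame(result)) {
    wcsv(as.data.frame(result), paste0(name, ".csv"))
  } else {
    stop("unsupported result type")
  }
  invisible(written)
}
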