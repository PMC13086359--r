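# Explicit time stepping for the nonlinear axisymmetric heat equation:
# stage orchestration, stability control, and conservation diagnostics.
# The per-step arithmetic lives in src/stepper.cpp; everything here prepares
# masks and material tables, chooses the time step, and samples isotherm
# traces / snapshots while the kernel advances the field in chunks.

# Dense property lookup tables for the kernel: conductivity k(T) and the
# reciprocal volumetric effective capacity 1/(rho(T) Cp_eff(T)) sampled on a
# uniform temperature grid over the material's tabulated range and evaluated
# by clamped linear interpolation.  The tables are computed from the exact
# piecewise property formulas, so the kernel and the R material library share
# one source of truth; the 0.01 degC resolution keeps interpolation error far
# below the uncertainty of the property data (see the methods vignette).
# The list order defines the integer coding and must match grid$materials.
kernel_materials <- function(library, step = 0.01) {
  lapply(library, function(m) {
    lo <- m$valid_range[1]; hi <- m$valid_range[2]
    n <- ceiling((hi - lo) / step) + 1
    Tg <- lo + (seq_len(n) - 1) * step
    # Latent term: bin-averaged from the exact closed-form cumulative weight,
    # so the table releases exactly the right latent heat over the mushy
    # range no matter how the grid aligns with the sharp 1/T^2 spike at T_f
    # (the apparent-heat-capacity regularization of enthalpy methods).
    cp <- mat_cp(m, Tg)
    pc <- m$phase_change
    if (!is.null(pc) && !isTRUE(pc$latent_embedded)) {
      g_bin <- (mushy_weight_cumulative(pc, Tg + step / 2, m$mushy_weight) -
                mushy_weight_cumulative(pc, Tg - step / 2, m$mushy_weight)) /
               step
      cp <- cp + pc$L_eff * g_bin
    }
    list(lut_lo = lo, lut_inv_step = 1 / step,
         k_lut = mat_conductivity(m, Tg),
         invC_lut = 1 / (mat_density(m, Tg) * cp))
  })
}

# R mirror of the kernel's lookup-table interpolation (bit-identical
# arithmetic; verified against lut_eval_cpp in the tests)
lut_eval <- function(values, lo, inv_step, T) {
  x <- (T - lo) * inv_step
  x[!is.finite(x) | x < 0] <- 0
  x <- pmin(x, length(values) - 1)
  i <- pmin(trunc(x), length(values) - 2)
  frac <- pmin(x - i, 1)
  values[i + 1L] + (values[i + 2L] - values[i + 1L]) * frac
}

check_library_matches_grid <- function(grid, materials) {
  if (!identical(names(materials), grid$materials))
    stop("material library does not match the one the grid was built with")
}

#' Harmonic-mean interface conductivity
#'
#' Effective conductivity between two adjacent nodes treated as consecutive
#' half-cell layers (the parallel-resistor analogy): `2 k1 k2 / (k1 + k2)`.
#' Returns 0 when either side is 0, which is how the zero-conductivity ghost
#' contour blocks flux.
#'
#' @param k1,k2 node conductivities, W/(m K), `>= 0`.
#' @return effective pair conductivity, W/(m K) (vectorized).
#' @export
interface_conductivity <- function(k1, k2) {
  if (any(k1 < 0 | k2 < 0)) stop("conductivities must be non-negative")
  s <- k1 + k2
  ifelse(s > 0, 2 * k1 * k2 / s, 0)
}

#' Per-direction effective diffusivity fields
#'
#' For each node, the four effective thermal diffusivities towards its
#' neighbours: the pair conductivity (harmonic mean) divided by the node's
#' own volumetric effective heat capacity.  Directions blocked by the ghost
#' contour get 0 via the zero-conductivity convention.
#'
#' @param field temperature storage matrix, degrees C.
#' @param grid a `cryo_grid`.
#' @param materials material registry matching the grid.
#' @return list of four storage matrices `alpha_pz` (towards deeper z),
#'   `alpha_mz`, `alpha_pr`, `alpha_mr`, in m^2/s.
#' @export
directional_diffusivities <- function(field, grid,
                                      materials = material_library()) {
  check_library_matches_grid(grid, materials)
  nz <- nrow(field); nr <- ncol(field)
  K <- matrix(0, nz, nr)
  C <- matrix(1, nz, nr)
  for (code in setdiff(unique(as.vector(grid$mat)), 0L)) {
    sel <- grid$mat == code
    id <- grid$materials[code]
    K[sel] <- mat_conductivity(id, field[sel], materials)
    C[sel] <- mat_rho_cp_eff(id, field[sel], materials)
  }
  shift <- function(m, di, dj) {
    out <- matrix(0, nz, nr)
    out[(1 + max(0, -di)):(nz - max(0, di)),
        (1 + max(0, -dj)):(nr - max(0, dj))] <-
      m[(1 + max(0, di)):(nz - max(0, -di)),
        (1 + max(0, dj)):(nr - max(0, -dj))]
    out
  }
  pair <- function(di, dj) interface_conductivity(K, shift(K, di, dj)) / C
  list(alpha_pz = pair(1, 0), alpha_mz = pair(-1, 0),
       alpha_pr = pair(0, 1), alpha_mr = pair(0, -1))
}

#' Largest stable explicit time step
#'
#' Stability bound of the forward-Euler five-point scheme:
#' `safety * min over nodes of [ (a+z + a-z)/dz^2 +
#' (a+r r+ + a-r r-)/(r_j dr^2) ]^-1`, evaluated with every diffusivity at
#' the worst case `alpha_max = max_T k/(rho Cp_eff)` over the materials
#' present.  The temperature search samples the tabulated range on a 0.05
#' degC grid plus a finer 0.005 degC grid inside the mushy range, where the
#' effective capacity has a sharp peak.
#'
#' @param grid a `cryo_grid`.
#' @param materials material registry matching the grid.
#' @param safety fraction of the bound to use, in (0, 1].
#' @return time step in seconds.
#' @export
stable_timestep <- function(grid, materials = material_library(),
                            safety = 0.5) {
  stopifnot(safety > 0, safety <= 1)
  check_library_matches_grid(grid, materials)
  codes <- setdiff(unique(as.vector(grid$mat)), 0L)
  alpha_max <- 0
  for (code in codes) {
    m <- materials[[grid$materials[code]]]
    Ts <- seq(m$valid_range[1], m$valid_range[2], by = 0.05)
    if (!is.null(m$phase_change))
      Ts <- c(Ts, seq(m$phase_change$T_m, m$phase_change$T_f, by = 0.005))
    a <- mat_conductivity(m, Ts) / mat_rho_cp_eff(m, Ts)
    alpha_max <- max(alpha_max, max(a))
  }
  jj <- 2:(ncol(grid$mat) - 1)
  denom <- 2 * alpha_max / grid$dz^2 +
    alpha_max * (grid$r_plus[jj] + grid$r_minus[jj]) /
      (grid$r_storage[jj] * grid$dr^2)
  safety / max(denom)
}

#' Advance the temperature field
#'
#' Runs `nsteps` explicit updates of the five-point stencil.  Fixed nodes
#' (ghost contour, bath row, and any in `fixed`) keep their temperature but
#' conduct into their neighbours.
#'
#' @param field temperature storage matrix.
#' @param grid a `cryo_grid`.
#' @param materials material registry matching the grid.
#' @param dt time step, s (must satisfy the stability bound).
#' @param nsteps number of steps.
#' @param fixed logical storage matrix of non-updated nodes; by default the
#'   grid's boundary mask plus the applicator.
#' @param mat optional material mask override (stage-dependent voids).
#' @return the updated temperature matrix (input is not modified).
#' @export
step_field <- function(field, grid, materials = material_library(), dt,
                       nsteps = 1L,
                       fixed = grid$fixed | grid$applicator,
                       mat = grid$mat) {
  check_library_matches_grid(grid, materials)
  T <- matrix(as.numeric(field), nrow(field), ncol(field))
  step_chunk_cpp(T, mat, fixed, grid$r_storage, grid$r_plus, grid$r_minus,
                 grid$dz, grid$dr, dt, as.integer(nsteps),
                 kernel_materials(materials))
  T
}

instability_stop <- function(field, grid, mat, t_now, dt) {
  bad <- which(!is.finite(field) & mat > 0L, arr.ind = TRUE)
  if (nrow(bad) == 0) return(invisible(NULL))
  i <- bad[1, 1]; j <- bad[1, 2]
  stop(sprintf(paste0("numerical instability: non-finite temperature at ",
                      "node (i = %d, j = %d; z = %.3f mm, r = %.3f mm) ",
                      "near t = %.4g s with dt = %.3g s; reduce dt (or the ",
                      "safety fraction) and rerun"),
               i, j, 1000 * grid$z[i - 1], 1000 * grid$r_storage[j],
               t_now, dt), call. = FALSE)
}

#' Run one stage of a cryoapplication
#'
#' Applies the stage's boundary conditions and advances the field over the
#' stage duration, sampling isotherm traces every `trace_interval` seconds
#' and storing full-field snapshots every `snapshot_interval` seconds.
#'
#' Freezing: the applicator nodes are held at `T_N` (conducting one way into
#' the sample), the deep bath row at `T_b`, all other boundaries no-flux.
#' Thawing: the applicator volume is removed (a no-flux void, like the air
#' above the surface), the bath row is retained.
#'
#' @param config a `cryo_config`.
#' @param stage `"freeze"` or `"thaw"`.
#' @param init initial temperature storage matrix; defaults to the pressed
#'   applicator state for freezing.  A thaw stage normally starts from the
#'   freeze stage's final field.
#' @param grid the domain; built from `config` when `NULL`.
#' @param materials material registry.  When the air layer is enabled the
#'   `air_effective` entry is rebuilt from the configured air parameters.
#' @param duration stage length, s; defaults to the configured duration.
#' @return a `cryo_result`: isotherm trace (`time_s`, `level_C`, `R_mm`,
#'   `D_mm`, `present`), snapshots, final field, the grid as seen by the
#'   stage, the time step used and step count.
#' @export
run_stage <- function(config, stage = c("freeze", "thaw"), init = NULL,
                      grid = NULL, materials = material_library(),
                      duration = NULL) {
  stage <- match.arg(stage)
  validate_config(config)
  if (isTRUE(config$air_layer$enabled))
    materials[["air_effective"]] <-
      air_material(k = config$air_layer$k,
                   multiplier = config$air_layer$multiplier,
                   rho_cp = config$air_layer$rho_cp)
  if (is.null(grid)) grid <- build_domain(config, materials)
  pressed <- press_applicator(grid, config)
  grid <- pressed$grid
  field <- if (is.null(init)) pressed$field else init
  field <- matrix(as.numeric(field), nrow(field), ncol(field))
  if (is.null(duration))
    duration <- if (stage == "freeze") config$freeze_duration
                else config$thaw_duration

  mat <- grid$mat
  if (stage == "freeze") {
    fixed <- grid$fixed | grid$applicator
    grid_stage <- grid
  } else {
    # applicator removed: its volume becomes a no-flux void; the whole
    # sample-air interface is insulated, so air rows become void too
    void <- grid$applicator
    air_code <- match("air_effective", grid$materials)
    if (!is.na(air_code)) void <- void | (mat == air_code)
    mat[void] <- 0L
    fixed <- grid$fixed
    grid_stage <- grid
    grid_stage$mat <- mat
    grid_stage$applicator <- matrix(FALSE, nrow(mat), ncol(mat))
  }

  dt <- config$dt
  if (identical(dt, "auto")) {
    dt <- stable_timestep(grid, materials, config$safety)
  } else if (dt > stable_timestep(grid, materials, 1)) {
    warning("configured dt exceeds the estimated stability bound; ",
            "the run may diverge", call. = FALSE)
  }

  levels <- config$isotherm_levels
  trace_one <- function(t_now) {
    data.frame(time_s = t_now, level_C = levels,
               R_mm = vapply(levels, function(l)
                 isotherm_radius(field, grid_stage, l), 0),
               D_mm = vapply(levels, function(l)
                 isotherm_depth(field, grid_stage, l), 0))
  }

  events <- sort(unique(c(
    seq_min(config$trace_interval, duration, config$trace_interval),
    seq_min(config$snapshot_interval, duration, config$snapshot_interval),
    if (duration > 0) duration)))
  snap_at <- unique(c(seq_min(config$snapshot_interval, duration,
                              config$snapshot_interval), duration))
  km <- kernel_materials(materials)

  traces <- list(trace_one(0))
  snapshots <- list()
  t_now <- 0
  n_steps <- 0L
  for (ev in events) {
    delta <- ev - t_now
    n <- max(1L, as.integer(ceiling(delta / dt - 1e-9)))
    dt_seg <- delta / n
    step_chunk_cpp(field, mat, fixed, grid$r_storage, grid$r_plus,
                   grid$r_minus, grid$dz, grid$dr, dt_seg, n, km)
    t_now <- ev
    n_steps <- n_steps + n
    if (any(!is.finite(field[mat > 0L])))
      instability_stop(field, grid, mat, t_now, dt_seg)
    traces[[length(traces) + 1L]] <- trace_one(t_now)
    if (any(abs(ev - snap_at) < 1e-9))
      snapshots[[sprintf("%.6g", ev)]] <- field + 0
  }
  trace <- do.call(rbind, traces)
  trace$present <- is.finite(trace$R_mm) | is.finite(trace$D_mm)
  structure(list(stage = stage, config = config, grid = grid_stage,
                 grid_pristine = grid, trace = trace,
                 snapshot_times = as.numeric(names(snapshots)),
                 snapshots = snapshots,
                 final_field = field, final_time = t_now,
                 dt = dt, n_steps = n_steps),
            class = "cryo_result")
}

seq_min <- function(by, to, interval) {
  if (!is.finite(interval) || interval > to) return(numeric(0))
  seq(interval, to, by = interval)
}

#' @export
print.cryo_result <- function(x, ...) {
  cat(sprintf("<cryo_result> %s stage, %g s in %d steps (dt ~ %.3g s)\n",
              x$stage, x$final_time, x$n_steps, x$dt))
  cat(sprintf("  %d trace samples, %d snapshots, levels: %s degC\n",
              length(unique(x$trace$time_s)), length(x$snapshots),
              paste(unique(x$trace$level_C), collapse = ", ")))
  invisible(x)
}

#' Run a full freeze (and optional thaw) simulation
#'
#' Runs the freezing stage and, when `thaw_duration > 0`, continues with the
#' thawing stage from the final frozen field.  Thaw trace times are offset by
#' the freeze duration so the combined trace is a single timeline.
#'
#' @param config a `cryo_config`.
#' @param materials material registry.
#' @return a `cryo_simulation`: list with `freeze`, `thaw` (or `NULL`) and
#'   the combined `trace`.
#' @export
run_simulation <- function(config, materials = material_library()) {
  fr <- run_stage(config, "freeze", materials = materials)
  th <- NULL
  trace <- fr$trace
  if (config$thaw_duration > 0) {
    th <- run_stage(config, "thaw", init = fr$final_field,
                    grid = fr$grid_pristine, materials = materials)
    t2 <- th$trace[th$trace$time_s > 0, ]
    t2$time_s <- t2$time_s + config$freeze_duration
    trace <- rbind(trace, t2)
  }
  structure(list(freeze = fr, thaw = th, trace = trace, config = config),
            class = "cryo_simulation")
}

#' Total enthalpy of the field
#'
#' Conservation diagnostic: `sum over nodes of rho(T) H(T) 2 pi r_j dr dz`
#' with `H(T)` the specific enthalpy (integral of the effective capacity
#' from `T_ref`).  With all-insulated boundaries and no fixed nodes the
#' explicit scheme conserves this to round-off for constant properties.
#'
#' @param field temperature storage matrix.
#' @param grid a `cryo_grid`.
#' @param materials material registry matching the grid.
#' @param T_ref reference temperature for the enthalpy zero, degrees C.
#' @return total enthalpy, J.
#' @export
total_enthalpy <- function(field, grid, materials = material_library(),
                           T_ref = 0) {
  check_library_matches_grid(grid, materials)
  vol <- matrix(rep(2 * pi * grid$r_storage * grid$dr * grid$dz,
                    each = nrow(field)), nrow(field), ncol(field))
  total <- 0
  for (code in setdiff(unique(as.vector(grid$mat)), 0L)) {
    sel <- grid$mat == code
    id <- grid$materials[code]
    Tn <- field[sel]
    total <- total + sum(mat_density(id, Tn, materials) *
                         mat_enthalpy(id, Tn, T_ref, materials) * vol[sel])
  }
  total
}
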