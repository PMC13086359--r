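# Temperature-dependent thermophysical property models and the
# effective-heat-capacity treatment of the water phase change.
#
# Every property (density, thermal conductivity, sensible heat capacity) is a
# piecewise function of temperature stored as a branch coefficient table.  A
# branch covers a half-open interval [lo, hi) (the topmost branch is closed
# at hi) and evaluates
#
#   v(T) = p0 + p1*T + p2*T^2 + p3*T^3
#        + apow*(-T)^epow + ainv/T + aisq/(T0-T)^2 + atisq*T/(T0-T)^2
#
# which covers all functional forms used by the hydrogel and tissue property
# formulas (cubic polynomials, the (-T)^1.156 frozen-skin conductivity, the
# 1/T terms of fat and muscle conductivity, and the 1/(0.46-T)^2 muscle
# capacity).  The same tables are handed to the compiled stepper so the R
# evaluators and the kernel share one source of truth.

.cryo_state <- new.env(parent = emptyenv())

BRANCH_COLS <- c("lo", "hi", "p0", "p1", "p2", "p3",
                 "apow", "epow", "ainv", "aisq", "atisq", "T0")

#' Define one property branch
#'
#' Builds a single row of a piecewise property table.  See the package
#' vignette for the functional form.
#'
#' @param lo,hi temperature interval covered by the branch, degrees C.  The
#'   branch applies on `[lo, hi)`; the topmost branch of a table is treated
#'   as closed at `hi`.
#' @param poly numeric vector of up to 4 polynomial coefficients
#'   `c(p0, p1, p2, p3)` (constant first).
#' @param pow_term optional `c(a, e)` adding `a * (-T)^e`.
#' @param inv optional scalar `a` adding `a / T`.
#' @param isq optional `c(a, T0)` adding `a / (T0 - T)^2`.
#' @param tisq optional `c(a, T0)` adding `a * T / (T0 - T)^2`.
#' @return a named numeric vector (one branch-table row).
#' @export
property_branch <- function(lo, hi, poly = 0, pow_term = NULL, inv = 0,
                            isq = NULL, tisq = NULL) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi, length(poly) <= 4)
  p <- c(poly, rep(0, 4 - length(poly)))
  if (is.null(pow_term)) pow_term <- c(0, 1)
  T0 <- 0
  a_isq <- 0
  a_tisq <- 0
  if (!is.null(isq))  { a_isq  <- isq[1];  T0 <- isq[2] }
  if (!is.null(tisq)) { a_tisq <- tisq[1]; T0 <- tisq[2] }
  if (!is.null(isq) && !is.null(tisq) && isq[2] != tisq[2])
    stop("isq and tisq must share the same pole T0")
  out <- c(lo, hi, p, pow_term[1], pow_term[2], inv, a_isq, a_tisq, T0)
  names(out) <- BRANCH_COLS
  out
}

branch_table <- function(...) {
  tab <- do.call(rbind, list(...))
  tab <- tab[order(tab[, "lo"]), , drop = FALSE]
  # branches must tile the valid range with no gaps
  if (nrow(tab) > 1 &&
      any(abs(tab[-nrow(tab), "hi"] - tab[-1, "lo"]) > 1e-9))
    stop("property branches leave gaps in the valid range")
  tab
}

eval_branch_row <- function(row, T) {
  v <- row[["p0"]] + row[["p1"]] * T + row[["p2"]] * T^2 + row[["p3"]] * T^3
  if (row[["apow"]] != 0) v <- v + row[["apow"]] * (-T)^row[["epow"]]
  if (row[["ainv"]] != 0) v <- v + row[["ainv"]] / T
  if (row[["aisq"]] != 0) v <- v + row[["aisq"]] / (row[["T0"]] - T)^2
  if (row[["atisq"]] != 0) v <- v + row[["atisq"]] * T / (row[["T0"]] - T)^2
  v
}

# Evaluate a branch table at (already clamped) temperatures.  Branch choice
# is half-open on the low side, [lo, hi); the last branch is closed at hi.
eval_branch_table <- function(tab, T) {
  idx <- findInterval(T, tab[, "lo"], rightmost.closed = FALSE)
  idx[idx < 1] <- 1L
  idx[idx > nrow(tab)] <- nrow(tab)
  out <- numeric(length(T))
  for (b in unique(idx)) {
    sel <- idx == b
    out[sel] <- eval_branch_row(tab[b, ], T[sel])
  }
  out
}

#' Construct a material model
#'
#' Bundles the piecewise temperature-dependent density, thermal conductivity
#' and sensible heat capacity of one medium together with its phase-change
#' constants.  All properties are strict SI: kg/m^3, W/(m K), J/(kg K);
#' temperatures are in degrees Celsius because every published property
#' polynomial uses Celsius.
#'
#' @param name material identifier.
#' @param density,conductivity,heat_capacity branch tables built from
#'   [property_branch()] rows via `rbind`.
#' @param phase_change `NULL` for media without a phase change (air), else a
#'   list with `T_f` (cryoscopic temperature, upper bound of the mushy range,
#'   degrees C), `T_m` (initial melting temperature, lower bound), `L_eff`
#'   (effective latent heat, J/kg) and `latent_embedded` (logical; `TRUE`
#'   when the tabulated heat capacity already contains the latent
#'   contribution, as for muscle).
#' @param valid_range temperature range of the source data, degrees C.
#'   Outside it properties are clamped to the boundary value (with a
#'   once-per-session warning from the R evaluators).
#' @param mushy_weight how the latent heat is distributed over
#'   `[T_m, T_f]`: `"reciprocal_sq"` (default; weight proportional to
#'   `|T_f|/T^2`, normalized to integrate to exactly 1), `"uniform"`, or
#'   `"linear"` (rising towards `T_f`).
#' @return an object of class `cryo_material`.
#' @export
cryo_material <- function(name, density, conductivity, heat_capacity,
                          phase_change = NULL,
                          valid_range = c(min(density[, "lo"]),
                                          max(density[, "hi"])),
                          mushy_weight = c("reciprocal_sq", "uniform",
                                           "linear")) {
  mushy_weight <- match.arg(mushy_weight)
  if (!is.null(phase_change)) {
    pc <- phase_change
    stopifnot(is.numeric(pc$T_f), is.numeric(pc$T_m))
    if (!isTRUE(pc$T_m < pc$T_f) || pc$T_f > 0)
      stop("phase change requires T_m < T_f <= 0 degrees C")
    if (is.null(pc$latent_embedded)) pc$latent_embedded <- FALSE
    if (!pc$latent_embedded && !(pc$L_eff > 0))
      stop("L_eff must be positive unless the latent heat is embedded")
    if (mushy_weight == "reciprocal_sq" && pc$T_f == 0)
      stop("reciprocal_sq mushy weight needs T_f < 0")
    phase_change <- pc
  }
  structure(list(name = name,
                 density = density,
                 conductivity = conductivity,
                 heat_capacity = heat_capacity,
                 phase_change = phase_change,
                 valid_range = valid_range,
                 mushy_weight = mushy_weight),
            class = "cryo_material")
}

#' @export
print.cryo_material <- function(x, ...) {
  cat("<cryo_material>", x$name, "\n")
  cat("  valid range:", x$valid_range[1], "to", x$valid_range[2], "degC\n")
  if (is.null(x$phase_change)) {
    cat("  no phase change\n")
  } else {
    pc <- x$phase_change
    cat(sprintf("  mushy range [%g, %g] degC, L_eff = %g J/kg%s\n",
                pc$T_m, pc$T_f, if (pc$latent_embedded) NA else pc$L_eff,
                if (pc$latent_embedded) " (embedded in Cp table)" else ""))
  }
  invisible(x)
}

#' Constant-property material
#'
#' Convenience constructor for test media and simple phantoms: constant
#' density, conductivity and heat capacity, optionally with distinct frozen /
#' unfrozen constants and a (possibly narrow) mushy interval.
#'
#' @param name identifier.
#' @param k,rho,cp unfrozen constants (W/(m K), kg/m^3, J/(kg K)).
#' @param k_s,rho_s,cp_s frozen-phase constants; default to the unfrozen
#'   values.
#' @param T_f,T_m,L_eff phase-change constants; all `NULL` for a single-phase
#'   medium.
#' @param valid_range,mushy_weight see [cryo_material()].
#' @return a `cryo_material`.
#' @export
constant_material <- function(name, k, rho, cp,
                              k_s = k, rho_s = rho, cp_s = cp,
                              T_f = NULL, T_m = NULL, L_eff = NULL,
                              valid_range = c(-200, 50),
                              mushy_weight = "uniform") {
  lo <- valid_range[1]; hi <- valid_range[2]
  if (is.null(T_f)) {
    one <- function(v) branch_table(property_branch(lo, hi, v))
    return(cryo_material(name, one(rho), one(k), one(cp),
                         valid_range = valid_range))
  }
  two <- function(vs, vl) branch_table(property_branch(lo, T_f, vs),
                                       property_branch(T_f, hi, vl))
  cryo_material(name,
                density = two(rho_s, rho),
                conductivity = two(k_s, k),
                heat_capacity = two(cp_s, cp),
                phase_change = list(T_f = T_f, T_m = T_m, L_eff = L_eff,
                                    latent_embedded = FALSE),
                valid_range = valid_range,
                mushy_weight = mushy_weight)
}

# ---------------------------------------------------------------------------
# Built-in library

hydrogel_material <- function(mushy_weight = "reciprocal_sq") {
  T_f <- -0.1; T_m <- -14
  L <- 334e3; f_FW <- 0.93; w <- 0.95
  outer_rho <- c(935.79, 8.715e-2, 1.7428e-4)
  cryo_material(
    "hydrogel_5pct",
    density = branch_table(
      property_branch(-160, T_m, outer_rho),
      # mushy-range branch as printed; discontinuous with the outer branches
      # at T_f (~1016 vs ~935.8 kg/m^3) -- a known transcription artifact in
      # the source data, reproduced verbatim.
      property_branch(T_m, T_f, c(1018.2, 16.927, 1.2044, 2.925e-2)),
      property_branch(T_f, 40, outer_rho)),
    conductivity = branch_table(
      property_branch(-160, -2.8, c(2.191, -0.0118, -6.57e-5)),
      property_branch(-2.8, 40, c(0.615, 0.00181))),
    # published in kJ/(kg K); normalized here to J/(kg K)
    heat_capacity = branch_table(
      property_branch(-160, T_f, c(2100, 7.9, 7.1e-3)),
      property_branch(T_f, 40, c(3950, 1.25))),
    phase_change = list(T_f = T_f, T_m = T_m, L_eff = L * f_FW * w,
                        latent_embedded = FALSE),
    valid_range = c(-160, 40),
    mushy_weight = mushy_weight)
}

skin_material <- function(mushy_weight = "reciprocal_sq") {
  T_f <- -0.53; T_m <- -9.15
  cryo_material(
    "skin",
    density = branch_table(
      property_branch(-50, T_f, 1039),
      property_branch(T_f, 45, 1100)),
    conductivity = branch_table(
      property_branch(-50, T_f, 1.72, pow_term = c(0.0046, 1.156)),
      property_branch(T_f, 45, 0.424)),
    # mushy formula 5.51*(T+273)+143 also applies below T_m ("same")
    heat_capacity = branch_table(
      property_branch(-50, T_f, c(5.51 * 273 + 143, 5.51)),
      property_branch(T_f, 45, c(2742.87, 13.166))),
    phase_change = list(T_f = T_f, T_m = T_m, L_eff = 230e3,
                        latent_embedded = FALSE),
    valid_range = c(-50, 45),
    mushy_weight = mushy_weight)
}

fat_material <- function(mushy_weight = "reciprocal_sq") {
  T_f <- -5; T_m <- -10
  cryo_material(
    "subcutaneous_fat",
    density = branch_table(
      property_branch(-50, T_f, 978.6),
      property_branch(T_f, 45, c(986.47, -0.44503))),
    conductivity = branch_table(
      # 0.223 - 3.06e-4*(T - T_f) + 0.051*(1/T - 1/T_f), constants folded
      property_branch(-50, T_f,
                      c(0.223 + 3.06e-4 * T_f - 0.051 / T_f, -3.06e-4),
                      inv = 0.051),
      # 0.223 - 5.1e-5*(T - T_f)
      property_branch(T_f, 45, c(0.223 + 5.1e-5 * T_f, -5.1e-5))),
    heat_capacity = branch_table(
      property_branch(-50, T_f, c(6.51 * 273 + 153, 6.51)),
      property_branch(T_f, 45, c(2100, 4))),
    phase_change = list(T_f = T_f, T_m = T_m, L_eff = 100e3,
                        latent_embedded = FALSE),
    valid_range = c(-50, 45),
    mushy_weight = mushy_weight)
}

muscle_material <- function(mushy_weight = "reciprocal_sq") {
  T_f <- -0.91; T_m <- -10
  cryo_material(
    "muscle",
    density = branch_table(
      property_branch(-50, T_f, 988.3),
      property_branch(T_f, 45, 1047)),
    conductivity = branch_table(
      # 0.46791 - 6.55e-3*(T + T_f) + 0.71175*(1/T - 1/T_f), as printed
      # ("+T_f" where "-T_f" would be conventional), constants folded
      property_branch(-50, T_f,
                      c(0.46791 - 6.55e-3 * T_f - 0.71175 / T_f, -6.55e-3),
                      inv = 0.71175),
      property_branch(T_f, 45, c(0.4838, 9.24e-4))),
    # the tabulated capacity is already effective: the latent heat is
    # embedded in the two sub-freezing branches
    heat_capacity = branch_table(
      property_branch(-50, T_m, 0, tisq = c(-47624.4, 0.46)),
      property_branch(T_m, T_f, 0, isq = c(380402.7, 0.46)),
      property_branch(T_f, 45, c(3347.8, 4.1124))),
    phase_change = list(T_f = T_f, T_m = T_m, L_eff = 250e3,
                        latent_embedded = TRUE),
    valid_range = c(-50, 45),
    mushy_weight = mushy_weight)
}

#' Effective air medium
#'
#' Constant-property stand-in for the thin layer of air above the sample
#' surface.  The published model calibrates effective air parameters (lumping
#' conduction, convection and vapor condensation) rather than printing them,
#' so both the conductivity scale factor and the volumetric heat capacity are
#' configurable.  Density is fixed at 1 so that `rho_cp` is the volumetric
#' heat capacity in J/(m^3 K) directly.
#'
#' @param k base thermal conductivity, W/(m K) (still air: 0.026).
#' @param multiplier calibration factor applied to `k`.
#' @param rho_cp volumetric heat capacity, J/(m^3 K) (still air: ~1206).
#' @return a `cryo_material` named `"air_effective"`.
#' @export
air_material <- function(k = 0.026, multiplier = 1, rho_cp = 1206) {
  lo <- -200; hi <- 50
  one <- function(v) branch_table(property_branch(lo, hi, v))
  cryo_material("air_effective",
                density = one(1),
                conductivity = one(k * multiplier),
                heat_capacity = one(rho_cp),
                valid_range = c(lo, hi))
}

#' Built-in material library
#'
#' Returns the registry of built-in materials: 5% gelatin hydrogel, skin,
#' subcutaneous fat, muscle, and the effective air medium.
#'
#' @param mushy_weight latent-heat weighting passed to every phase-changing
#'   material; see [cryo_material()].
#' @param air an `"air_effective"` material, by default [air_material()] with
#'   its defaults.
#' @return a named list of `cryo_material` objects
#'   (class `cryo_material_library`).
#' @export
material_library <- function(mushy_weight = "reciprocal_sq",
                             air = air_material()) {
  lib <- list(hydrogel_5pct = hydrogel_material(mushy_weight),
              skin = skin_material(mushy_weight),
              subcutaneous_fat = fat_material(mushy_weight),
              muscle = muscle_material(mushy_weight),
              air_effective = air)
  class(lib) <- "cryo_material_library"
  lib
}

#' Add or replace a material in a library
#'
#' @param library a `cryo_material_library`.
#' @param material a `cryo_material`; registered under its own name.
#' @return the updated library.
#' @export
library_add <- function(library, material) {
  stopifnot(inherits(material, "cryo_material"))
  library[[material$name]] <- material
  class(library) <- "cryo_material_library"
  library
}

resolve_material <- function(material, library = material_library()) {
  if (inherits(material, "cryo_material")) return(material)
  if (!is.character(material) || length(material) != 1)
    stop("material must be a cryo_material or a single id string")
  m <- library[[material]]
  if (is.null(m)) stop("unknown material id: ", material)
  m
}

clamp_T <- function(mat, T) {
  if (!all(is.finite(T))) stop("non-finite temperature passed to a material model")
  lo <- mat$valid_range[1]; hi <- mat$valid_range[2]
  if (any(T < lo | T > hi)) {
    key <- paste0("clamp_", mat$name)
    if (is.null(.cryo_state[[key]])) {
      .cryo_state[[key]] <- TRUE
      warning(sprintf(paste0("temperature outside the tabulated range ",
                             "[%g, %g] degC for '%s'; properties clamped to ",
                             "the boundary value (reported once per session)"),
                      lo, hi, mat$name), call. = FALSE)
    }
    T <- pmin(pmax(T, lo), hi)
  }
  T
}

# ---------------------------------------------------------------------------
# Property evaluation

#' Material density
#'
#' @param material material id (in `library`) or a `cryo_material`.
#' @param T temperature(s), degrees C.
#' @param library material registry, by default [material_library()].
#' @return density in kg/m^3 (vectorized over `T`).
#' @export
mat_density <- function(material, T, library = material_library()) {
  m <- resolve_material(material, library)
  eval_branch_table(m$density, clamp_T(m, T))
}

#' Material thermal conductivity
#'
#' @inheritParams mat_density
#' @return thermal conductivity in W/(m K).
#' @export
mat_conductivity <- function(material, T, library = material_library()) {
  m <- resolve_material(material, library)
  eval_branch_table(m$conductivity, clamp_T(m, T))
}

#' Sensible heat capacity
#'
#' For muscle the tabulated capacity below the cryoscopic temperature already
#' contains the latent contribution, so the "sensible" value equals the
#' effective one there.
#'
#' @inheritParams mat_density
#' @return heat capacity in J/(kg K).
#' @export
mat_cp <- function(material, T, library = material_library()) {
  m <- resolve_material(material, library)
  eval_branch_table(m$heat_capacity, clamp_T(m, T))
}

# Normalized latent-heat weight g(T) on [T_m, T_f]; integral over the mushy
# range is exactly 1 for every mode.
mushy_weight_value <- function(pc, T, mode) {
  T_f <- pc$T_f; T_m <- pc$T_m
  g <- numeric(length(T))
  inside <- T >= T_m & T <= T_f
  if (any(inside)) {
    Ti <- T[inside]
    g[inside] <- switch(mode,
      reciprocal_sq = (abs(T_f) / Ti^2) / (1 - T_f / T_m),
      uniform = 1 / (T_f - T_m),
      linear = 2 * (Ti - T_m) / (T_f - T_m)^2,
      stop("unknown mushy weight mode"))
  }
  g
}

# Cumulative latent fraction: integral of g from T_m to T (0 below, 1 above).
mushy_weight_cumulative <- function(pc, T, mode) {
  T_f <- pc$T_f; T_m <- pc$T_m
  Tc <- pmin(pmax(T, T_m), T_f)
  G <- switch(mode,
    reciprocal_sq = abs(T_f) * (1 / T_m - 1 / Tc) / (1 - T_f / T_m),
    uniform = (Tc - T_m) / (T_f - T_m),
    linear = (Tc - T_m)^2 / (T_f - T_m)^2,
    stop("unknown mushy weight mode"))
  G
}

#' Effective heat capacity
#'
#' Sensible heat capacity augmented, inside the mushy range `[T_m, T_f]`, by
#' the latent heat released per degree: `Cp_eff(T) = Cp(T) + L_eff * g(T)`
#' where the weight `g` integrates to 1 over the mushy range.  Materials with
#' the latent heat already embedded in their capacity table (muscle) and
#' materials without a phase change (air) return the tabulated value
#' unchanged.
#'
#' @inheritParams mat_density
#' @return effective heat capacity in J/(kg K).
#' @export
mat_cp_eff <- function(material, T, library = material_library()) {
  m <- resolve_material(material, library)
  Tc <- clamp_T(m, T)
  cp <- eval_branch_table(m$heat_capacity, Tc)
  pc <- m$phase_change
  if (is.null(pc) || isTRUE(pc$latent_embedded)) return(cp)
  cp + pc$L_eff * mushy_weight_value(pc, Tc, m$mushy_weight)
}

#' Volumetric effective heat capacity
#'
#' The product `rho(T) * Cp_eff(T)` used by the solver.
#'
#' @inheritParams mat_density
#' @return volumetric heat capacity in J/(m^3 K).
#' @export
mat_rho_cp_eff <- function(material, T, library = material_library()) {
  mat_density(material, T, library) * mat_cp_eff(material, T, library)
}

#' Specific enthalpy relative to a reference temperature
#'
#' `H(T) = integral of Cp_eff from T_ref to T`, J/kg.  The sensible part is
#' integrated numerically on a fine grid (exact for the piecewise-linear
#' capacity branches used in conservation tests); the latent part uses the
#' closed-form cumulative of the mushy weight.
#'
#' @inheritParams mat_density
#' @param T_ref reference temperature, degrees C.
#' @return enthalpy in J/kg.
#' @export
mat_enthalpy <- function(material, T, T_ref = 0,
                         library = material_library()) {
  m <- resolve_material(material, library)
  Tc <- clamp_T(m, T)
  h <- sensible_enthalpy_fn(m)
  out <- h(Tc) - h(T_ref)
  # clamping freezes the property at the boundary value; extend linearly
  below <- T < m$valid_range[1]
  above <- T > m$valid_range[2]
  if (any(below))
    out[below] <- out[below] +
      (T[below] - m$valid_range[1]) * eval_branch_table(m$heat_capacity,
                                                        m$valid_range[1])
  if (any(above))
    out[above] <- out[above] +
      (T[above] - m$valid_range[2]) * eval_branch_table(m$heat_capacity,
                                                        m$valid_range[2])
  pc <- m$phase_change
  if (!is.null(pc) && !isTRUE(pc$latent_embedded)) {
    out <- out + pc$L_eff * (mushy_weight_cumulative(pc, Tc, m$mushy_weight) -
                             mushy_weight_cumulative(pc, T_ref, m$mushy_weight))
  }
  out
}

# memoised cumulative-trapezoid integral of the sensible capacity
sensible_enthalpy_fn <- function(m) {
  key <- paste0("H_", m$name, "_", paste(m$valid_range, collapse = "_"))
  f <- .cryo_state[[key]]
  if (!is.null(f)) return(f)
  lo <- m$valid_range[1]; hi <- m$valid_range[2]
  grid <- sort(unique(c(seq(lo, hi, by = 0.02), as.vector(m$heat_capacity[, c("lo", "hi")]), hi)))
  grid <- grid[grid >= lo & grid <= hi]
  cp <- eval_branch_table(m$heat_capacity, grid)
  Hc <- c(0, cumsum(diff(grid) * (cp[-1] + cp[-length(cp)]) / 2))
  f <- stats::approxfun(grid, Hc, rule = 2)
  .cryo_state[[key]] <- f
  f
}

# ---------------------------------------------------------------------------
# JSON serialization

#' Write a material library to JSON
#'
#' The schema stores, per material, the branch coefficient tables, the
#' phase-change constants, the valid range and the mushy weighting mode.
#' Users can edit the file (or write their own in the same schema) and load
#' it back with [read_material_library()].
#'
#' @param library a `cryo_material_library`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_material_library <- function(library, path) {
  ser <- lapply(library, function(m) {
    list(name = m$name,
         valid_range = m$valid_range,
         mushy_weight = m$mushy_weight,
         phase_change = m$phase_change,
         density = as.data.frame(m$density),
         conductivity = as.data.frame(m$conductivity),
         heat_capacity = as.data.frame(m$heat_capacity))
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a material library from JSON
#'
#' @param path file written by [write_material_library()] or following the
#'   same schema.
#' @return a `cryo_material_library`.
#' @export
read_material_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lib <- lapply(raw, function(m) {
    tab <- function(df) {
      x <- as.matrix(df[BRANCH_COLS])
      dimnames(x) <- list(NULL, BRANCH_COLS)
      x
    }
    pc <- m$phase_change
    if (!is.null(pc) && length(pc) == 0) pc <- NULL
    cryo_material(m$name, tab(m$density), tab(m$conductivity),
                  tab(m$heat_capacity), phase_change = pc,
                  valid_range = as.numeric(m$valid_range),
                  mushy_weight = m$mushy_weight)
  })
  names(lib) <- vapply(lib, `[[`, "", "name")
  class(lib) <- "cryo_material_library"
  lib
}
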