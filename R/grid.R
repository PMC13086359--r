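# Axisymmetric (z, r) computational domain: node coordinates, half-shifted
# radii, material masks for layer stacks and the pressed-in applicator,
# boundary masks, and the zero-conductivity ghost contour.
#
# Conventions (see the methods vignette):
#   * z is depth, positive downward, 0 at the undisturbed sample surface;
#   * nodes are cell-centered in both directions: r_j = (j + 1/2) dr,
#     z_i = (i + 1/2) dz (0-based), so the radial weight 1/r_j is never
#     singular on the axis and the innermost cell's inward flux vanishes
#     identically (r_minus of the first ring is 0);
#   * layers own nodes by cell center, with half-open bands [lo, hi);
#   * storage is (N_z + n_air + 2) x (N_r + 2): a one-node ghost contour of
#     zero-conductivity nodes implements every no-flux boundary, and the
#     optional effective-air rows sit above the surface at z < 0.

#' Simulation configuration
#'
#' Collects geometry, grid, stage schedule, material set and boundary
#' temperatures.  Lengths are in millimetres at this interface (the solver
#' core is strict SI), times in seconds, temperatures in degrees Celsius.
#'
#' @param material_set `"hydrogel"` (uniform 5% gelatin hydrogel) or
#'   `"tissue"` (skin / subcutaneous fat / muscle stack).
#' @param r_max,z_max domain extents, mm.  Choose them at least ~1.3 times
#'   the expected frozen radius/depth so the no-flux sides emulate a
#'   semi-infinite medium.
#' @param N_r,N_z node counts along r and z.
#' @param r_ap applicator radius, mm (flat liquid-nitrogen-cooled disk).
#' @param z_ap press-in depth of the applicator, mm.
#' @param T_N applicator temperature, degrees C (boiling liquid nitrogen).
#' @param T_b bath / initial temperature, degrees C (34 for tissue work;
#'   hydrogel bench experiments use 20).
#' @param freeze_duration,thaw_duration stage durations, s.
#' @param dt time step, s, or `"auto"` to use [stable_timestep()] with the
#'   given `safety`.
#' @param safety stability safety fraction in (0, 1] used when `dt = "auto"`.
#' @param skin,fat layer thicknesses for the tissue stack, mm (`fat = 0`
#'   gives a two-layer skin/muscle stack).
#' @param air_layer list controlling the effective air rows above the
#'   surface: `enabled`, `n_rows`, `k` (W/(m K)), `multiplier`, `rho_cp`
#'   (J/(m^3 K)), `T_air` (initial air temperature, defaults to `T_b`).
#' @param isotherm_levels isotherm temperatures to track, degrees C.
#' @param trace_interval interval between isotherm trace samples, s.
#' @param snapshot_interval interval between stored full-field snapshots, s
#'   (`Inf` keeps only the final field).
#' @param bottom_bc `"fixed"` (deep thermal bath at `T_b`, the default) or
#'   `"insulated"`.
#' @return a validated list of class `cryo_config`.
#' @export
simulation_config <- function(material_set = c("hydrogel", "tissue"),
                              r_max = 12.8, z_max = 12.8,
                              N_r = 256, N_z = 256,
                              r_ap = 4, z_ap = 1,
                              T_N = -196, T_b = 34,
                              freeze_duration = 30, thaw_duration = 0,
                              dt = "auto", safety = 0.5,
                              skin = 0.6, fat = 0.3,
                              air_layer = list(enabled = FALSE),
                              isotherm_levels = c(0, -40),
                              trace_interval = 1,
                              snapshot_interval = Inf,
                              bottom_bc = c("fixed", "insulated")) {
  material_set <- match.arg(material_set)
  bottom_bc <- match.arg(bottom_bc)
  air_def <- list(enabled = FALSE, n_rows = 2L, k = 0.026, multiplier = 1,
                  rho_cp = 1206, T_air = T_b)
  air_layer <- utils::modifyList(air_def, as.list(air_layer))
  cfg <- list(material_set = material_set,
              r_max = r_max, z_max = z_max, N_r = as.integer(N_r),
              N_z = as.integer(N_z), r_ap = r_ap, z_ap = z_ap,
              T_N = T_N, T_b = T_b,
              freeze_duration = freeze_duration,
              thaw_duration = thaw_duration,
              dt = dt, safety = safety,
              skin = skin, fat = fat,
              air_layer = air_layer,
              isotherm_levels = isotherm_levels,
              trace_interval = trace_interval,
              snapshot_interval = snapshot_interval,
              bottom_bc = bottom_bc)
  class(cfg) <- "cryo_config"
  validate_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks every invariant and reports all problems at once.
#'
#' @param config a `cryo_config` (or plain list with the same fields).
#' @return `config`, invisibly; errors listing each violated constraint.
#' @export
validate_config <- function(config) {
  p <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) p <<- c(p, msg)
  chk(is.numeric(config$r_max) && config$r_max > 0, "r_max must be positive")
  chk(is.numeric(config$z_max) && config$z_max > 0, "z_max must be positive")
  chk(config$N_r >= 2 && config$N_z >= 2, "N_r and N_z must be >= 2")
  chk(config$r_ap > 0 && config$r_ap < config$r_max,
      "applicator radius must satisfy 0 < r_ap < r_max")
  chk(config$z_ap >= 0 && config$z_ap < config$z_max,
      "press-in depth must satisfy 0 <= z_ap < z_max")
  chk(config$freeze_duration >= 0, "freeze_duration must be >= 0")
  chk(config$thaw_duration >= 0, "thaw_duration must be >= 0")
  chk(identical(config$dt, "auto") ||
        (is.numeric(config$dt) && config$dt > 0),
      "dt must be \"auto\" or a positive number of seconds")
  chk(is.numeric(config$safety) && config$safety > 0 && config$safety <= 1,
      "safety must be in (0, 1]")
  chk(config$skin >= 0 && config$fat >= 0, "layer thicknesses must be >= 0")
  chk(config$skin + config$fat < config$z_max,
      "skin + fat must be thinner than the domain depth")
  chk(config$trace_interval > 0, "trace_interval must be positive")
  if (length(p)) stop("invalid configuration:\n  - ",
                      paste(p, collapse = "\n  - "), call. = FALSE)
  invisible(config)
}

#' @export
print.cryo_config <- function(x, ...) {
  cat("<cryo_config>", x$material_set, "\n")
  cat(sprintf("  domain %g x %g mm, grid %d x %d (dz %.4g mm, dr %.4g mm)\n",
              x$z_max, x$r_max, x$N_z, x$N_r, x$z_max / x$N_z,
              x$r_max / x$N_r))
  cat(sprintf("  applicator r_ap %g mm, z_ap %g mm at %g degC; bath %g degC\n",
              x$r_ap, x$z_ap, x$T_N, x$T_b))
  cat(sprintf("  freeze %g s, thaw %g s, dt %s, air layer %s\n",
              x$freeze_duration, x$thaw_duration,
              if (identical(x$dt, "auto")) "auto" else format(x$dt),
              if (isTRUE(x$air_layer$enabled)) "on" else "off"))
  invisible(x)
}

mm <- function(x) x / 1000  # interface mm -> SI meters

#' Material mask for the layer stack
#'
#' Assigns a material id to every interior node: a uniform hydrogel block, or
#' depth-ordered bands skin `[0, t_skin)`, fat `[t_skin, t_skin + t_fat)` and
#' muscle below, plus effective-air rows above the surface when enabled.
#' Node ownership is by cell center.
#'
#' @param config a `cryo_config`.
#' @param library material registry (its names define the integer coding).
#' @return integer storage matrix (`0` = ghost contour) with attribute
#'   `"materials"` giving the id of each positive integer.
#' @export
layer_stack <- function(config, library = material_library()) {
  n_air <- if (isTRUE(config$air_layer$enabled))
    as.integer(config$air_layer$n_rows) else 0L
  nz <- config$N_z + n_air + 2L
  nr <- config$N_r + 2L
  dz <- mm(config$z_max) / config$N_z
  z <- ((seq_len(config$N_z + n_air) - n_air) - 0.5) * dz  # air rows: z < 0
  ids <- names(library)
  code <- function(id) {
    i <- match(id, ids)
    if (is.na(i)) stop("material id not in library: ", id)
    i
  }
  row_mat <- integer(length(z))
  if (config$material_set == "hydrogel") {
    row_mat[z >= 0] <- code("hydrogel_5pct")
  } else {
    t_skin <- mm(config$skin); t_fat <- mm(config$fat)
    for (nm in c("skin", "fat")) {
      th <- config[[nm]]
      if (th > 0 && mm(th) < dz - 1e-12)
        stop(sprintf(paste0("the %s layer (%g mm) is thinner than the grid ",
                            "step dz = %g mm; refine the grid so every ",
                            "layer spans at least one node"),
                     nm, th, dz * 1000))
    }
    row_mat[z >= 0 & z < t_skin] <- code("skin")
    row_mat[z >= t_skin & z < t_skin + t_fat] <- code("subcutaneous_fat")
    row_mat[z >= t_skin + t_fat] <- code("muscle")
  }
  if (n_air > 0) row_mat[z < 0] <- code("air_effective")
  mask <- matrix(0L, nz, nr)
  mask[2:(nz - 1), 2:(nr - 1)] <- row_mat
  attr(mask, "materials") <- ids
  mask
}

#' Build the computational domain
#'
#' Constructs the cell-centered axisymmetric grid with ghost contour,
#' half-shifted radii, material mask and base boundary masks.  The applicator
#' is added by [press_applicator()].
#'
#' @param config a `cryo_config`.
#' @param library material registry.
#' @return an object of class `cryo_grid`.
#' @export
build_domain <- function(config, library = material_library()) {
  validate_config(config)
  n_air <- if (isTRUE(config$air_layer$enabled))
    as.integer(config$air_layer$n_rows) else 0L
  dz <- mm(config$z_max) / config$N_z
  dr <- mm(config$r_max) / config$N_r
  nz <- config$N_z + n_air + 2L
  nr <- config$N_r + 2L
  z <- ((seq_len(config$N_z + n_air) - n_air) - 0.5) * dz
  r <- (seq_len(config$N_r) - 0.5) * dr
  # storage-aligned radius vectors (ghost entries inert)
  r_s <- c(r[1], r, r[config$N_r])
  rp_s <- c(0, r + dr / 2, 0)
  rm_s <- c(0, r - dr / 2, 0)
  rm_s[2] <- 0  # innermost ring: inward flux identically zero (axis)
  mat <- layer_stack(config, library)
  fixed <- matrix(FALSE, nz, nr)
  fixed[mat == 0L] <- TRUE  # ghost contour
  if (config$bottom_bc == "fixed") fixed[nz - 1L, 2:(nr - 1)] <- TRUE
  grid <- list(config = config,
               n_air = n_air, N_z = config$N_z, N_r = config$N_r,
               dz = dz, dr = dr, z = z, r = r,
               r_storage = r_s, r_plus = rp_s, r_minus = rm_s,
               mat = mat, materials = attr(mat, "materials"),
               fixed = fixed,
               applicator = matrix(FALSE, nz, nr))
  class(grid) <- "cryo_grid"
  grid
}

#' @export
print.cryo_grid <- function(x, ...) {
  cat(sprintf("<cryo_grid> %d x %d interior nodes (+%d air rows, ghost contour)\n",
              x$N_z, x$N_r, x$n_air))
  cat(sprintf("  dz = %.4g mm, dr = %.4g mm; materials: %s\n",
              x$dz * 1000, x$dr * 1000,
              paste(sort(unique(x$materials[x$mat[x$mat > 0]])),
                    collapse = ", ")))
  invisible(x)
}

#' Press the cryoapplicator into the sample
#'
#' Marks every node inside the applicator footprint (radius at most `r_ap`
#' and depth less than `z_ap`, by cell center) as
#' applicator, held at `T_N` during the freezing stage but conducting into
#' the sample; where air rows exist the cold column continues above the
#' surface so the non-insulated side wall cools the surrounding air.  Builds
#' the initial temperature field: `T_N` on the applicator, `T_b` elsewhere
#' (air rows start at `T_air`).
#'
#' @param grid a `cryo_grid` from [build_domain()].
#' @param config the same `cryo_config`.
#' @return list with elements `grid` (applicator mask set) and `field`
#'   (initial temperature storage matrix, class `cryo_field`).
#' @export
press_applicator <- function(grid, config = grid$config) {
  nz <- nrow(grid$mat); nr <- ncol(grid$mat)
  r_ap <- mm(config$r_ap); z_ap <- mm(config$z_ap)
  in_r <- grid$r <= r_ap + 1e-12
  in_z <- grid$z < z_ap - 1e-12 | grid$z < 0  # plug + cold column in air rows
  ap <- matrix(FALSE, nz, nr)
  ap[2:(nz - 1), 2:(nr - 1)] <- outer(in_z, in_r, `&`)
  ap[grid$mat == 0L] <- FALSE
  grid$applicator <- ap
  field <- matrix(config$T_b, nz, nr)
  if (grid$n_air > 0) {
    air_code <- match("air_effective", grid$materials)
    field[grid$mat == air_code] <- config$air_layer$T_air
  }
  field[ap] <- config$T_N
  class(field) <- c("cryo_field", class(field))
  list(grid = grid, field = field)
}

#' Add effective-air surface rows to a domain
#'
#' Returns a domain rebuilt with the configuration's air layer enabled:
#' surface rows above the sample (outside the applicator footprint) become
#' the `air_effective` medium, producing the thin surface frozen ring seen in
#' thermograms when the calibrated conduction is strong enough.  With the
#' multiplier at 0 the layer is inert (no-flux limit).
#'
#' @param grid a `cryo_grid`.
#' @param config configuration whose `air_layer` settings to apply.
#' @param library material registry used for the rebuild; the air medium is
#'   replaced by one built from the `air_layer` settings.
#' @return a new `cryo_grid` with air rows.
#' @export
configure_air_layer <- function(grid, config = grid$config,
                                library = material_library()) {
  config$air_layer$enabled <- TRUE
  library[["air_effective"]] <-
    air_material(k = config$air_layer$k,
                 multiplier = config$air_layer$multiplier,
                 rho_cp = config$air_layer$rho_cp)
  build_domain(config, library)
}

# node categories: "ghost", "air", "applicator", "sample" -- a disjoint
# cover of the storage array
node_category <- function(grid) {
  cat <- matrix("ghost", nrow(grid$mat), ncol(grid$mat))
  air_code <- match("air_effective", grid$materials)
  cat[grid$mat > 0L] <- "sample"
  if (!is.na(air_code)) cat[grid$mat == air_code] <- "air"
  cat[grid$applicator] <- "applicator"
  cat
}

# logical matrix of nodes whose temperature belongs to the sample proper
# (used by the isotherm extractors): material nodes that are not air and not
# ghost/void; applicator nodes count during freezing (they are the frozen
# plug) via `include_applicator`.
sample_mask <- function(grid, include_applicator = TRUE) {
  m <- grid$mat > 0L
  air_code <- match("air_effective", grid$materials)
  if (!is.na(air_code)) m[grid$mat == air_code] <- FALSE
  if (!include_applicator) m[grid$applicator] <- FALSE
  m
}
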