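# Shared fixtures: small domains, constant-property test media, and a
# memoised cache for the few expensive simulation runs reused across tests.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- force(expr)
  .run_cache[[key]]
}

# small hydrogel freeze configuration (fast; ~0.15 mm resolution)
small_config <- function(...) {
  args <- utils::modifyList(list(N_r = 64, N_z = 64, r_max = 9.6,
                                 z_max = 9.6, freeze_duration = 5),
                            list(...))
  do.call(simulation_config, args)
}

# single-phase constant-property medium and a library containing it
const_lib <- function(k = 0.5, rho = 1000, cp = 3500, ...) {
  m <- constant_material("test_const", k = k, rho = rho, cp = cp, ...)
  lib <- material_library()
  lib[["test_const"]] <- NULL
  structure(list(test_const = m), class = "cryo_material_library")
}

# a grid filled entirely with one custom material, all-insulated unless
# bottom_bc = "fixed"; no applicator
uniform_grid <- function(material, N_z = 24, N_r = 24, z_max = 12,
                         r_max = 12, bottom_bc = "insulated") {
  lib <- structure(stats::setNames(list(material), material$name),
                   class = "cryo_material_library")
  cfg <- simulation_config(N_z = N_z, N_r = N_r, z_max = z_max,
                           r_max = r_max, r_ap = r_max / 4, z_ap = 0,
                           bottom_bc = bottom_bc)
  g <- build_domain(cfg)
  g$mat[g$mat > 0L] <- 1L
  g$materials <- material$name
  list(grid = g, lib = lib, cfg = cfg)
}

# quasi-1D axial column: a few radial cells, uniform in r, with the first
# interior row held at T_wall (Dirichlet) -- used by the erf and Stefan
# limit tests.  Returns grid, library, initial field and the wall plane
# position (the fixed node's center).
axial_column <- function(material, T_wall, T_init, N_z = 240, z_max = 12,
                         N_r = 4, r_max = 4) {
  u <- uniform_grid(material, N_z = N_z, N_r = N_r, z_max = z_max,
                    r_max = r_max, bottom_bc = "insulated")
  g <- u$grid
  field <- matrix(T_init, nrow(g$mat), ncol(g$mat))
  fixed <- g$fixed
  fixed[2, ] <- TRUE
  field[2, g$mat[2, ] > 0L] <- T_wall
  list(grid = g, lib = u$lib, field = field, fixed = fixed,
       z_wall = g$z[1])
}

expect_rel_equal <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol * abs(expected)),
              label = sprintf("%s vs %s (rel tol %g)",
                              paste(signif(object, 6), collapse = ","),
                              paste(signif(expected, 6), collapse = ","),
                              tol))
}
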