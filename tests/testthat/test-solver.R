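# The explicit stepper: interface conductivities, stability bound,
# conservation, maximum principle, stage orchestration, air layer.

test_that("interface conductivity is the harmonic mean with a zero gate", {
  expect_equal(interface_conductivity(0.7, 0.7), 0.7)
  expect_equal(interface_conductivity(1, 3), 1.5)
  expect_equal(interface_conductivity(0, 5), 0)
  expect_equal(interface_conductivity(5, 0), 0)
  expect_error(interface_conductivity(-1, 2), "non-negative")
  # skin/fat pair at their unfrozen table values
  expect_equal(interface_conductivity(0.424, 0.223),
               2 * 0.424 * 0.223 / (0.424 + 0.223))
})

test_that("directional diffusivities reduce to k/(rho cp) in a uniform medium", {
  u <- uniform_grid(constant_material("test_const", k = 0.5, rho = 1000,
                                      cp = 3500), N_z = 12, N_r = 12)
  field <- matrix(20, nrow(u$grid$mat), ncol(u$grid$mat))
  a <- directional_diffusivities(field, u$grid, u$lib)
  alpha <- 0.5 / (1000 * 3500)
  interior <- u$grid$mat > 0L
  interior[c(2, nrow(interior) - 1), ] <- FALSE
  interior[, c(2, ncol(interior) - 1)] <- FALSE
  for (f in a) expect_equal(f[interior], rep(alpha, sum(interior)))
  # next to the ghost contour the blocked direction vanishes
  expect_equal(a$alpha_mz[2, 5], 0)
  expect_equal(a$alpha_pr[5, ncol(interior) - 1], 0)
  expect_equal(a$alpha_mr[5, 2], 0)  # axis: zero-k ghost inside r = 0
})

test_that("stable timestep matches the classical bound and scales as h^2", {
  m <- constant_material("test_const", k = 0.5, rho = 1000, cp = 3500)
  alpha <- 0.5 / (1000 * 3500)
  u1 <- uniform_grid(m, N_z = 16, N_r = 16, z_max = 8, r_max = 8)
  h <- u1$grid$dz
  expect_equal(stable_timestep(u1$grid, u1$lib, safety = 0.5),
               0.5 * h^2 / (4 * alpha), tolerance = 1e-10)
  u2 <- uniform_grid(m, N_z = 16, N_r = 16, z_max = 16, r_max = 16)
  expect_equal(stable_timestep(u2$grid, u2$lib, safety = 0.5),
               4 * stable_timestep(u1$grid, u1$lib, safety = 0.5),
               tolerance = 1e-10)
  expect_error(stable_timestep(u1$grid, u1$lib, safety = 0), "safety")
})

test_that("uniform field in a closed domain is a fixed point", {
  u <- uniform_grid(material_library()$hydrogel_5pct)
  field <- matrix(25, nrow(u$grid$mat), ncol(u$grid$mat))
  out <- step_field(field, u$grid, u$lib, dt = 1e-3, nsteps = 25)
  expect_identical(out[u$grid$mat > 0L], field[u$grid$mat > 0L])
})

test_that("1D axial update reproduces the explicit heat-equation stencil", {
  m <- constant_material("test_const", k = 0.6, rho = 950, cp = 4000)
  u <- uniform_grid(m, N_z = 30, N_r = 6, z_max = 15, r_max = 3)
  g <- u$grid
  nz <- nrow(g$mat)
  Tz <- 20 + 10 * sin(seq(0, 3, length.out = nz))   # varies in z only
  field <- matrix(Tz, nz, ncol(g$mat))
  out <- step_field(field, g, u$lib, dt = 5e-3, nsteps = 1)
  alpha <- 0.6 / (950 * 4000)
  i <- 3:(nz - 2)
  expected <- Tz[i] + alpha * 5e-3 *
    (Tz[i + 1] - 2 * Tz[i] + Tz[i - 1]) / g$dz^2
  expect_equal(out[i, 4], expected, tolerance = 1e-12)
})

test_that("enthalpy is conserved on closed domains", {
  # constant properties: conservation to round-off over 1000 steps
  m <- constant_material("test_const", k = 0.5, rho = 1000, cp = 3500)
  u <- uniform_grid(m, N_z = 24, N_r = 24, z_max = 12, r_max = 12)
  g <- u$grid
  zc <- outer(c(0, g$z, 0), rep(1, ncol(g$mat)))
  rc <- outer(rep(1, nrow(g$mat)), g$r_storage)
  # gentle gradients: the explicit apparent-capacity update carries an
  # O(dT_step^2 * dCp/dT) enthalpy error per step (see methods vignette)
  field <- 20 + 5 * exp(-((zc - 6e-3)^2 + (rc - 4e-3)^2) / (2e-3)^2)
  dt <- 0.9 * stable_timestep(g, u$lib, safety = 1)
  E0 <- total_enthalpy(field, g, u$lib, T_ref = 0)
  out <- step_field(field, g, u$lib, dt = dt, nsteps = 1000)
  E1 <- total_enthalpy(out, g, u$lib, T_ref = 0)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-9)

  # temperature-dependent conductivity and capacity (constant density, so
  # the rho*H bookkeeping matches the scheme's rho*Cp updates)
  lo <- -200; hi <- 50
  tb <- function(p) rbind(property_branch(lo, hi, p))
  mt <- cryo_material("test_tdep",
                      density = tb(1000),
                      conductivity = tb(c(0.6, 0.004)),
                      heat_capacity = tb(c(3600, 12)),
                      valid_range = c(lo, hi))
  ut <- uniform_grid(mt, N_z = 24, N_r = 24, z_max = 12, r_max = 12)
  dt2 <- 0.9 * stable_timestep(ut$grid, ut$lib, safety = 1)
  E0 <- total_enthalpy(field, ut$grid, ut$lib, T_ref = 0)
  out <- step_field(field, ut$grid, ut$lib, dt = dt2, nsteps = 1000)
  E1 <- total_enthalpy(out, ut$grid, ut$lib, T_ref = 0)
  expect_lt(abs(E1 - E0) / abs(E0), 1e-6)
})

test_that("discrete maximum principle holds at 0.9x the stability bound", {
  m <- constant_material("test_const", k = 0.5, rho = 1000, cp = 3500)
  u <- uniform_grid(m, N_z = 20, N_r = 20, z_max = 10, r_max = 10)
  set.seed(42)
  field <- matrix(0, nrow(u$grid$mat), ncol(u$grid$mat))
  interior <- u$grid$mat > 0L
  field[interior] <- stats::runif(sum(interior), -30, 40)
  dt <- 0.9 * stable_timestep(u$grid, u$lib, safety = 1)
  out <- step_field(field, u$grid, u$lib, dt = dt, nsteps = 400)
  expect_gte(min(out[interior]), min(field[interior]) - 1e-12)
  expect_lte(max(out[interior]), max(field[interior]) + 1e-12)
})

test_that("compiled stepper equals the dense reference oracle", {
  # constant-property random fields
  m <- constant_material("test_const", k = 0.8, rho = 1100, cp = 3000)
  u <- uniform_grid(m, N_z = 16, N_r = 16, z_max = 8, r_max = 8)
  g <- u$grid
  dt <- 0.5 * stable_timestep(g, u$lib, safety = 1)
  set.seed(1)
  interior <- g$mat > 0L
  for (rep in 1:25) {
    field <- matrix(15, nrow(g$mat), ncol(g$mat))
    field[interior] <- stats::runif(sum(interior), -50, 40)
    got <- step_field(field, g, u$lib, dt = dt, nsteps = 1)
    ref <- reference_step_dense(field, g, u$lib, dt = dt, nsteps = 1)
    expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-12)
  }
  # full nonlinear hydrogel configuration with applicator and bath masks
  cfg <- simulation_config(N_r = 32, N_z = 32, r_max = 8, z_max = 8,
                           freeze_duration = 1)
  gh <- build_domain(cfg)
  pf <- press_applicator(gh, cfg)
  dt <- stable_timestep(gh, material_library(), 0.5)
  got <- step_field(pf$field, pf$grid, dt = dt, nsteps = 3)
  ref <- reference_step_dense(pf$field, pf$grid, dt = dt, nsteps = 3)
  expect_lt(max(abs(got - ref)) / max(abs(ref)), 1e-12)
  # a single-node perturbation spreads only to its 4-neighbourhood
  field <- matrix(15, nrow(g$mat), ncol(g$mat))
  field[8, 8] <- 30
  one <- reference_step_dense(field, g, u$lib, dt = dt, nsteps = 1)
  moved <- which(one != field, arr.ind = TRUE)
  expect_true(all(abs(moved[, 1] - 8) + abs(moved[, 2] - 8) <= 1))
})

test_that("total enthalpy is a volume-weighted integral of Cp_eff", {
  m <- constant_material("test_const", k = 0.5, rho = 1000, cp = 3500)
  u1 <- uniform_grid(m, N_z = 10, N_r = 10, z_max = 5, r_max = 5)
  field <- matrix(18, nrow(u1$grid$mat), ncol(u1$grid$mat))
  # uniform field at the reference temperature has zero enthalpy
  expect_equal(total_enthalpy(field, u1$grid, u1$lib, T_ref = 18), 0)
  # doubling dz doubles the cell volumes, hence the enthalpy
  u2 <- uniform_grid(m, N_z = 10, N_r = 10, z_max = 10, r_max = 5)
  f2 <- matrix(18, nrow(u2$grid$mat), ncol(u2$grid$mat))
  expect_equal(total_enthalpy(f2, u2$grid, u2$lib, T_ref = 0),
               2 * total_enthalpy(field, u1$grid, u1$lib, T_ref = 0),
               tolerance = 1e-12)
  # analytic value: rho * cp * (T - Tref) * pi r_max^2 z_max
  expect_equal(total_enthalpy(field, u1$grid, u1$lib, T_ref = 0),
               1000 * 3500 * 18 * pi * (5e-3)^2 * 5e-3, tolerance = 1e-10)
})

test_that("zero-duration stages return the initial field unchanged", {
  cfg <- small_config(freeze_duration = 0)
  res <- run_stage(cfg, "freeze")
  pf <- press_applicator(build_domain(cfg), cfg)
  expect_identical(res$final_field, unclass(pf$field))
  expect_equal(res$n_steps, 0L)
})

test_that("freeze-stage isotherms grow monotonically; thaw shrinks them", {
  cfg <- small_config(freeze_duration = 12, thaw_duration = 40,
                      trace_interval = 2)
  sim <- cached("small_freeze_thaw", run_simulation(cfg))
  for (l in c(0, -40)) {
    fr <- sim$freeze$trace[sim$freeze$trace$level_C == l, ]
    expect_true(all(diff(fr$R_mm) >= -1e-9), label = paste("R freeze", l))
    expect_true(all(diff(fr$D_mm) >= -1e-9), label = paste("D freeze", l))
  }
  th <- sim$thaw$trace[sim$thaw$trace$level_C == 0 & sim$thaw$trace$time_s > 0, ]
  shr <- th$R_mm[is.finite(th$R_mm)]
  expect_gt(length(shr), 3)
  # right after applicator removal the deep-frozen core still conducts
  # outward and the 0 degC isotherm may expand briefly; once that cold
  # reservoir is spent the radius shrinks monotonically
  peak <- which.max(shr)
  expect_lt(peak, length(shr) / 3)
  expect_true(all(diff(shr[peak:length(shr)]) <= 1e-6))
  expect_lt(shr[length(shr)], shr[1])
})

test_that("instability is diagnosed with the offending node", {
  cfg <- small_config(dt = 0.05, freeze_duration = 30)  # far above the bound
  expect_error(suppressWarnings(run_stage(cfg, "freeze")),
               "numerical instability.*reduce dt")
})

test_that("calibrated air layer freezes a surface ring beyond the bulk spot", {
  run10 <- function(air) {
    cfg <- simulation_config(N_r = 80, N_z = 64, r_max = 16, z_max = 12.8,
                             freeze_duration = 10, air_layer = air)
    res <- run_stage(cfg, "freeze")
    tg <- surface_thermogram(res$final_field, res$grid)
    max(c(-Inf, tg$profile$r_mm[tg$profile$T_C < 0]))
  }
  surf_off <- run10(list(enabled = FALSE))
  # effective medium lumping convection and condensation: conductivity and
  # thermal mass scaled together (diffusivity preserved)
  surf_on <- run10(list(enabled = TRUE, n_rows = 4, multiplier = 200,
                        rho_cp = 1206 * 200))
  expect_gt(surf_off, 0)
  # sub-zero surface annulus extends beyond the conduction-only frozen spot
  expect_gt(surf_on, surf_off + 0.4)  # > 2 radial cells
})

test_that("air layer: zero multiplier recovers the insulated surface", {
  base <- small_config(freeze_duration = 2)
  off <- run_stage(base, "freeze")
  on0 <- run_stage(small_config(freeze_duration = 2,
                                air_layer = list(enabled = TRUE, n_rows = 2,
                                                 multiplier = 0)),
                   "freeze")
  # sample rows coincide exactly: a zero-conductivity air layer is the
  # no-flux ghost in disguise.  The air grid carries 2 extra rows on top.
  nz <- base$N_z
  expect_identical(on0$final_field[4:(3 + nz), ],
                   off$final_field[2:(1 + nz), ])
})
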