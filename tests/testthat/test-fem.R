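test_that("assembled operators reproduce constants, volume and area", {
  fem <- coarse_fem()
  va <- lens_volume_area(lens_geometry())
  # gradients of constants vanish
  K <- seedwave:::fem_stiffness(fem, rep(2.5, fem$n))
  expect_lt(max(abs(as.matrix(K) %*% rep(3.7, fem$n))), 1e-10)
  # r-weighted lumped mass totals the revolved volume
  meas <- axisymmetric_measures(fem$mesh)
  expect_equal(sum(fem$vol_w), meas$volume, tolerance = 1e-12)
  expect_equal(sum(fem$vol_w), va$volume, tolerance = 0.02)
  # Robin operator applied to a unit field totals the revolved convective area
  rob <- seedwave:::fem_robin_diag(fem, rep(1, nrow(fem$edge_nodes)))
  expect_equal(sum(rob), meas$area, tolerance = 1e-12)
  expect_equal(sum(rob), va$area, tolerance = 0.02)
})

test_that("insulated moisture step conserves the revolved moisture mass", {
  fem <- coarse_fem()
  dm <- flat_diffusivity(1e-7)
  bc <- boundary_model(0, 0)
  bc$L <- characteristic_length(lens_geometry())
  T_K <- rep(300, fem$n)
  M <- 0.4 + 0.05 * sin(fem$mesh$nodes[, 1] * 1e3)   # non-uniform start
  for (i in 1:10) {
    mass_before <- sum(fem$vol_w * M)
    M <- fem_step_moisture(fem, T_K, M, 0.5, dm, bc)
    expect_lt(abs(sum(fem$vol_w * M) - mass_before) / mass_before, 1e-8)
  }
})

test_that("small-Biot moisture decay tracks the lumped-capacitance oracle", {
  fem <- coarse_fem()
  dm <- flat_diffusivity(1e-7)
  bc <- boundary_model(0, 0.01)
  L <- characteristic_length(lens_geometry())
  cfg <- simulation_config(T0_C = 26.85, M0 = 0.4, t_end = 3000, dt = 1,
                           include_evaporation = FALSE)
  src <- microwave_source(e_field = 0, e_field_mode = "direct")
  sol <- run_forward(fem, cfg, zero_loss(), dm, src, bc)
  hm <- 0.01 * diffusivity(300, 0.4, dm) / L
  expect_gt(3000 * hm / L, 5)    # at least five time constants covered
  M_lump <- 0.4 * exp(-hm / L * sol$summary$time_s)
  expect_lt(max(abs(sol$summary$mean_M_db - M_lump)) / 0.4, 0.01)
  # outward flux only: strictly decreasing mean moisture
  expect_true(all(diff(sol$summary$mean_M_db) < 0))
})

test_that("ambient equilibrium is a fixed point without microwave power", {
  fem <- coarse_fem()
  bc <- boundary_model(0.043, 0)
  cfg <- simulation_config(T0_C = 23, M0 = 0.3, t_end = 60, dt = 1,
                           include_evaporation = FALSE)
  src <- microwave_source(e_field = 0, e_field_mode = "direct")
  sol <- run_forward(fem, cfg, zero_loss(), flat_diffusivity(), src, bc)
  expect_lt(max(abs(sol$summary$mean_T_C - 23)), 1e-9)
  # fully insulated, zero power: both fields constant in time
  sol2 <- run_forward(fem, simulation_config(40, 0.3, 60, 1),
                      zero_loss(), flat_diffusivity(), src, boundary_model(0, 0))
  expect_lt(max(abs(sol2$summary$mean_T_C - 40)), 1e-9)
  expect_lt(max(abs(sol2$summary$mean_M_db - 0.3)), 1e-12)
})

test_that("small-Biot heating tracks a lumped ODE oracle to 2 % of the rise", {
  fem <- coarse_fem()
  bc <- boundary_model(0.01, 0)
  L <- characteristic_length(lens_geometry())
  src <- microwave_source(e_field = 2000, e_field_mode = "direct")
  lossc <- loss_factor_model(c(2.5, rep(0, 7)), ash_db = 0)
  cfg <- simulation_config(T0_C = 23, M0 = 0.3, t_end = 2000, dt = 1,
                           include_evaporation = FALSE)
  sol <- run_forward(fem, cfg, lossc, flat_diffusivity(), src, bc)
  rhs <- function(t, y, p) {
    rho <- lentil_density(0.3)
    cp <- lentil_specific_heat(y, 0.3)
    k <- lentil_thermal_conductivity(y, 0.3)
    list((volumetric_heating(2000, 2.5, src) - 0.01 * k / L^2 * (y - 296.15)) /
           (rho * cp))
  }
  oracle <- deSolve::ode(c(T = 296.15), sol$summary$time_s, rhs, NULL)[, "T"] - 273.15
  rise <- sol$summary$mean_T_C - 23
  upto <- rise <= 0.9 * max(rise)
  expect_lt(max(abs(sol$summary$mean_T_C - oracle)[upto] / (oracle[upto] - 23 + 1)),
            0.02)
})

test_that("the evaporative sink lowers the temperature at every instant", {
  fem <- coarse_fem()
  tm <- table_average_models()
  bc <- boundary_model(0.043, 0.015)
  cfg_on <- simulation_config(T0_C = 4.5, M0 = 0.35, t_end = 120, dt = 1)
  cfg_off <- simulation_config(T0_C = 4.5, M0 = 0.35, t_end = 120, dt = 1,
                               include_evaporation = FALSE)
  sol_on <- run_forward(fem, cfg_on, tm$loss, tm$diff, tm$source, bc)
  sol_off <- run_forward(fem, cfg_off, tm$loss, tm$diff, tm$source, bc)
  expect_true(all(sol_on$summary$mean_T_C[-1] < sol_off$summary$mean_T_C[-1]))
})

test_that("insulated, evaporation-free energy bookkeeping closes to 1 %", {
  fem <- coarse_fem()
  bc <- boundary_model(0, 0)
  src <- microwave_source(e_field = 2000, e_field_mode = "direct")
  lossc <- loss_factor_model(c(2.5, rep(0, 7)), ash_db = 0)
  cfg <- simulation_config(T0_C = 10, M0 = 0.3, t_end = 200, dt = 0.5,
                           include_evaporation = FALSE,
                           output_times = c(0, 200))
  sol <- run_forward(fem, cfg, lossc, flat_diffusivity(), src, bc)
  absorbed <- volumetric_heating(2000, 2.5, src) * sum(fem$vol_w) * 200
  # enthalpy gain with temperature-dependent Cp, fine trapezoid in T
  T0 <- 283.15; T1 <- mean(sol$final_T_K)
  Ts <- seq(T0, T1, length.out = 200)
  enthalpy <- sum(fem$vol_w) * lentil_density(0.3) *
    sum((lentil_specific_heat(Ts[-1], 0.3) + lentil_specific_heat(Ts[-200], 0.3)) / 2 *
          diff(Ts))
  expect_lt(abs(absorbed - enthalpy) / absorbed, 0.01)
})

test_that("summary series stay between the nodal extremes and near-uniform at low Biot", {
  fem <- coarse_fem()
  tm <- table_average_models()
  bc <- boundary_model(0.043, 0.015)
  cfg <- simulation_config(T0_C = 4.5, M0 = 0.35, t_end = 200, dt = 1,
                           output_times = c(100, 200))
  sol <- run_forward(fem, cfg, tm$loss, tm$diff, tm$source, bc)
  s <- sol$summary
  for (tt in names(sol$snapshots)) {
    snap <- sol$snapshots[[tt]]
    row <- s[s$time_s == as.numeric(tt), ]
    expect_gte(row$mean_T_C, min(snap$T_K) - 273.15)
    expect_lte(row$mean_T_C, max(snap$T_K) - 273.15)
    expect_gte(row$mean_M_db, min(snap$M))
    expect_lte(row$mean_M_db, max(snap$M))
  }
  i <- nrow(s) %/% 2
  # Biot numbers well under 0.1 keep internal gradients a small fraction of
  # the body-to-ambient temperature difference
  gap <- abs(s$center_T_C[i] - s$surface_T_C[i])
  expect_lt(gap / (s$mean_T_C[i] - 23), 0.10)
})

test_that("summaries interpolate linearly and refuse extrapolation", {
  fem <- coarse_fem()
  tm <- table_average_models()
  bc <- boundary_model(0.043, 0.015)
  sol <- run_forward(fem, simulation_config(4.5, 0.35, 30, 1),
                     tm$loss, tm$diff, tm$source, bc)
  s <- sol$summary
  at <- summaries(sol, c(10, 10.5))
  expect_equal(at$mean_T_C[1], s$mean_T_C[s$time_s == 10])
  expect_equal(at$mean_T_C[2],
               mean(s$mean_T_C[s$time_s %in% c(10, 11)]))
  expect_error(summaries(sol, 31), "outside")
  # monotone series stay monotone after interpolation
  interp <- summaries(sol, seq(0, 30, by = 0.25))$mean_M_db
  expect_true(all(diff(interp) <= 1e-15))
})

test_that("runaway states abort with step diagnostics", {
  fem <- coarse_fem()
  tm <- table_average_models()
  bc <- boundary_model(0.043, 0.015)
  src <- microwave_source(e_field = 5e4, e_field_mode = "direct")
  cfg <- simulation_config(T0_C = 23, M0 = 0.35, t_end = 600, dt = 1,
                           include_evaporation = FALSE)
  expect_error(run_forward(fem, cfg, tm$loss, tm$diff, src, bc), "blew up")
})
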