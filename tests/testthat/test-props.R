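test_that("density correlation matches hand-evaluated values and rejects bad input", {
  expect_equal(lentil_density(0), 1472.9)
  expect_equal(lentil_density(0.5), 1365.65)
  expect_equal(lentil_density(0.2), 1418.42)
  expect_error(lentil_density(-0.1), "non-negative")
})

test_that("specific heat uses Celsius temperature and wet-basis moisture", {
  expect_equal(lentil_specific_heat(273.15, 0), 577.3)
  # hand evaluation: w = 0.35/1.35, T' = 80
  w <- 0.35 / 1.35
  expect_equal(lentil_specific_heat(353.15, 0.35),
               (0.5773 + 0.00709 * 80 + 6.22 * w - 9.14 * w^2) * 1e3)
  expect_equal(lentil_specific_heat(353.15, 0.35), 2142.7442, tolerance = 1e-7)
  expect_equal(lentil_specific_heat(373.15, 0), 1286.3)
})

test_that("thermal conductivity matches hand-evaluated values", {
  expect_equal(lentil_thermal_conductivity(273.15, 0), 0.193)
  expect_equal(lentil_thermal_conductivity(323.15, 0.5), 0.193 + 0.005 + 0.152 / 3)
  expect_equal(lentil_thermal_conductivity(323.15, 0.5), 0.2486667, tolerance = 1e-6)
  expect_equal(lentil_thermal_conductivity(373.15, 0.2), 0.2283333, tolerance = 1e-6)
})

test_that("latent heat is anchored at freezing point and strictly decreasing", {
  expect_equal(latent_heat(273.15), 2503000)
  expect_equal(latent_heat(373.15), 2503000 - 2386 * 100)
  T_grid <- seq(274, 400, by = 1)
  expect_true(all(diff(latent_heat(T_grid)) < 0))
})

test_that("loss factor reduces to g0 when every state variable vanishes", {
  m <- loss_factor_model(c(2.123, -0.102, 1.68e-4, -8.56e-3, 5.08e-4,
                           2.876, -1.566, 0.0479), ash_db = 0)
  expect_equal(loss_factor(273.15, 0, m), 2.123)
})

test_that("loss factor equals an independent term-by-term hand sum", {
  g <- c(2.123, -0.102, 1.68e-4, -8.56e-3, 5.08e-4, 2.876, -1.566, 0.0479)
  m <- loss_factor_model(g, ash_db = 2.6)
  Tc <- 111; M <- 0.1
  A <- 2.6 / (1 + M)
  hand <- g[1] + g[2] * Tc + g[3] * Tc^2 + 100 * g[4] * M +
    100 * g[5] * M * Tc + g[6] * A + g[7] * A^2 + g[8] * A * Tc
  expect_equal(loss_factor(Tc + 273.15, M, m), hand, tolerance = 1e-12)
  expect_equal(hand, 3.96535, tolerance = 1e-5)
})

test_that("doubling ash changes only the ash terms of the loss factor", {
  g <- c(2.1, -0.1, 2e-4, -1e-2, 5e-4, 2.9, -1.6, 0.05)
  m1 <- loss_factor_model(g, ash_db = 1.3)
  m2 <- loss_factor_model(g, ash_db = 2.6)
  Tc <- 60; M <- 0.3
  A1 <- 1.3 / (1 + M); A2 <- 2.6 / (1 + M)
  delta_hand <- g[6] * (A2 - A1) + g[7] * (A2^2 - A1^2) + g[8] * (A2 - A1) * Tc
  expect_equal(loss_factor(Tc + 273.15, M, m2) - loss_factor(Tc + 273.15, M, m1),
               delta_hand, tolerance = 1e-12)
})

test_that("loss factor polynomial is restructuring-invariant", {
  # Horner-style nested evaluation must equal the naive term sum
  g <- c(2.119, -0.040, 5.07e-5, -1.99e-2, 4.58e-4, 2.853, -1.709, 0.0300)
  m <- loss_factor_model(g, ash_db = 2.6)
  set.seed(42)
  Tc <- runif(50, 0, 120); M <- runif(50, 0, 0.6)
  A <- 2.6 / (1 + M)
  horner <- (g[1] + A * (g[6] + g[7] * A)) +
    Tc * ((g[2] + g[8] * A + g[3] * Tc) + 100 * g[5] * M) + 100 * g[4] * M
  expect_equal(loss_factor(Tc + 273.15, M, m), horner, tolerance = 1e-12)
})

test_that("diffusivity reproduces the fitted-row hand evaluation", {
  m <- diffusivity_model(D0 = 2.36e-3, Ea = 29.026, a0 = 1e-6, a1 = 0.5)
  # independent hand evaluation of the two exponentials
  hand <- 2.36e-3 * exp(-29026 / (8.3143 * 384.15)) *
    exp((1e-6 * 384.15 - 0.5) * 0.10)
  expect_equal(diffusivity(384.15, 0.10, m), hand, tolerance = 1e-12)
  expect_equal(hand, 2.5394e-7, tolerance = 1e-4)
})

test_that("diffusivity has the Arrhenius limit at zero moisture and grows with T", {
  m <- diffusivity_model(D0 = 2.36e-3, Ea = 29.026, a0 = 1e-6, a1 = 0.5)
  T_grid <- seq(280, 380, by = 5)
  expect_equal(diffusivity(T_grid, 0, m),
               2.36e-3 * exp(-29.026e3 / (8.3143 * T_grid)))
  expect_true(all(diff(diffusivity(T_grid, 0.3, m)) > 0))
  expect_error(diffusivity_model(-1, 29, 0, 0), "positive")
  expect_error(diffusivity_model(2e-3, -1, 0, 0), "positive")
})

test_that("every fitted diffusivity row stays in a physical envelope on the drying domain", {
  df <- lentil_coefficients("diffusivity")
  grid <- expand.grid(T_K = seq(276, 385, length.out = 23),
                      M = seq(0.10, 0.50, length.out = 9))
  for (i in seq_len(nrow(df))) {
    m <- diffusivity_model(df$D0[i], df$Ea[i], df$a0[i], df$a1[i])
    D <- diffusivity(grid$T_K, grid$M, m)
    expect_true(all(D >= 1e-9 & D <= 1e-6), label = df$treatment[i])
  }
})

test_that("field strength calibration variants and direct mode behave as specified", {
  # hand evaluation: sqrt(2*616/(1 - 0.421^2)) V/cm -> V/m
  src <- microwave_source(pav_watts = 616, s11 = 0.421)
  expect_equal(field_strength(src), sqrt(1232 / (1 - 0.421^2)) * 100)
  expect_equal(field_strength(src), 3869.6, tolerance = 1e-4)
  # reflection-free limit
  expect_equal(field_strength(microwave_source(500, 0)), sqrt(1000) * 100)
  # alternative rendering
  src2 <- microwave_source(616, 0.421, e_field_mode = "sqrt_times")
  expect_equal(field_strength(src2), sqrt(1232 * (1 - 0.421^2)) * 100)
  # direct passthrough
  src3 <- microwave_source(e_field = 5000, e_field_mode = "direct")
  expect_equal(field_strength(src3), 5000)
  expect_error(microwave_source(616, 1), "s11")
  expect_error(microwave_source(-5, 0.4), "positive")
})

test_that("volumetric heating is linear in loss factor and quadratic in field", {
  src <- microwave_source(e_field = 3870, e_field_mode = "direct")
  expect_equal(volumetric_heating(3870, 0, src), 0)
  hand <- 2 * pi * 2.45e9 * 8.854e-12 * 2.5 * 3870^2
  expect_equal(volumetric_heating(3870, 2.5, src), hand)
  expect_equal(hand / 1e6, 5.104, tolerance = 1e-3)
  expect_equal(volumetric_heating(3870, 5, src), 2 * volumetric_heating(3870, 2.5, src))
  expect_equal(volumetric_heating(2 * 3870, 2.5, src),
               4 * volumetric_heating(3870, 2.5, src))
})
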