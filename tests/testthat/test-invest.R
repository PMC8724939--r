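test_that("coupled objective is at its floor for the generating coefficients", {
  nf <- noisefree_record()
  scn <- nf$scenario
  # record re-generated with the same discretisation the objective uses
  rec <- generate_record(scn, target_h = 4e-4, dt = 1)
  ctrl <- estimation_control(dt = 1)
  fem <- coarse_fem()
  truth <- c(stats::setNames(unname(scn$loss$g), paste0("g", 0:7)),
             D0 = scn$diff$D0, Ea = scn$diff$Ea,
             a0 = scn$diff$a0, a1 = scn$diff$a1)
  op <- objective_pair(truth, rec, fem, scn$source, ctrl,
                       bi_heat = scn$bi_heat, bi_mass = scn$bi_mass,
                       T0_C = scn$T0_C)
  expect_lt(op$sse_T, 1e-4)
  expect_lt(op$sse_M, 1e-4)
  expect_gt(op$min_eps, 0)
  # sensitivity: inflating D0 by 50 % must strictly worsen the moisture fit
  bumped <- truth; bumped[["D0"]] <- 1.5 * truth[["D0"]]
  op2 <- objective_pair(bumped, rec, fem, scn$source, ctrl,
                        bi_heat = scn$bi_heat, bi_mass = scn$bi_mass,
                        T0_C = scn$T0_C)
  expect_gt(op2$sse_M, op$sse_M + 1e-6)
})

test_that("stage-1 diffusivity recovers the generating model from a lumped record", {
  # independent oracle: integrate the lumped mass balance with deSolve
  true_d <- diffusivity_model(D0 = 2.8e-3, Ea = 29.5, a0 = 5e-4, a1 = 0.35)
  bi_mass <- 0.015
  L <- characteristic_length(lens_geometry())
  T_of <- function(t) 273.15 + 20 + 55 * (1 - exp(-t / 120))
  times <- seq(0, 420, by = 15)
  rhs <- function(t, y, p)
    list(-bi_mass * diffusivity(T_of(t), max(y, 0), true_d) / L^2 * y)
  M <- deSolve::ode(c(M = 0.5), times, rhs, NULL)[, "M"]
  rec <- drying_record(times, T_of(times) - 273.15, moisture_db = M)

  s1 <- stage1_diffusivity(rec, control = estimation_control(),
                           bi_mass = bi_mass, L = L)
  T_K <- T_of(times); Mm <- M
  rel <- abs(diffusivity(T_K, Mm, s1$diff) / diffusivity(T_K, Mm, true_d) - 1)
  expect_lt(max(rel), 0.05)
  expect_length(s1$flags, 0)

  # descent: the returned fit beats the spec's nominal mid-bounds start
  b <- default_bounds()
  mid <- (b$lb + b$ub) / 2
  names(mid) <- b$name
  mid_d <- diffusivity_model(mid[["D0"]], mid[["Ea"]], mid[["a0"]], mid[["a1"]])
  M_mid <- deSolve::ode(c(M = 0.5), times, function(t, y, p)
    list(-bi_mass * diffusivity(T_of(t), max(y, 0), mid_d) / L^2 * y), NULL)[, "M"]
  expect_lte(s1$sse_M, sum((M - M_mid)^2))
})

test_that("a record without moisture decay is flagged unidentifiable", {
  times <- seq(0, 300, by = 15)
  rec <- drying_record(times, rep(23, length(times)),
                       moisture_db = rep(0.3, length(times)))
  s1 <- stage1_diffusivity(rec, control = estimation_control(),
                           bi_mass = 0.015)
  expect_match(s1$flags, "unidentifiable")
  expect_equal(s1$diff$D0, default_bounds()$lb[default_bounds()$name == "D0"])
})

test_that("stage-1 loss factor recovers the generating trajectory from a lumped record", {
  true_l <- loss_factor_model(c(2.123, -0.102, 1.68e-4, -8.56e-3, 5.08e-4,
                                2.876, -1.566, 0.0479), ash_db = 2.6)
  bi_heat <- 0.043
  L <- characteristic_length(lens_geometry())
  src <- microwave_source(pav_watts = 616, s11 = 0.421)
  M_of <- function(t) 0.1 + 0.4 * exp(-t / 180)
  dM_of <- function(t) -0.4 / 180 * exp(-t / 180)
  times <- seq(0, 420, by = 15)
  rhs <- function(t, y, p) {
    M <- M_of(t); rho <- lentil_density(M)
    q <- volumetric_heating(src$E, loss_factor(y, M, true_l), src)
    conv <- bi_heat * lentil_thermal_conductivity(y, M) / L^2 * (y - 296.15)
    list((q - conv + latent_heat(y) * rho * dM_of(t)) /
           (rho * lentil_specific_heat(y, M)))
  }
  T_K <- deSolve::ode(c(T = 277.65), times, rhs, NULL)[, "T"]
  rec <- drying_record(times, T_K - 273.15, moisture_db = M_of(times))

  s1 <- stage1_lossfactor(rec, control = estimation_control(), source = src,
                          bi_heat = bi_heat, L = L)
  rel <- abs(loss_factor(T_K, M_of(times), s1$loss) /
               loss_factor(T_K, M_of(times), true_l) - 1)
  expect_lt(max(rel), 0.10)
  expect_length(s1$flags, 0)
})

test_that("a zero-power record is reported unidentifiable without crashing", {
  times <- seq(0, 300, by = 15)
  rec <- drying_record(times, rep(23, length(times)),
                       moisture_db = 0.1 + 0.3 * exp(-times / 200))
  src0 <- microwave_source(e_field = 0, e_field_mode = "direct")
  s1 <- stage1_lossfactor(rec, control = estimation_control(), source = src0,
                          bi_heat = 0.043)
  expect_match(s1$flags, "unidentifiable")
  expect_s3_class(s1$loss, "loss_factor_model")
})

test_that("goal attainment started at the optimum keeps a non-positive attainment level", {
  nf <- noisefree_record()
  scn <- nf$scenario; rec <- nf$record
  ctrl <- estimation_control(stage2_maxit = 60)
  fem <- coarse_fem()
  truth <- c(stats::setNames(unname(scn$loss$g), paste0("g", 0:7)),
             D0 = scn$diff$D0, Ea = scn$diff$Ea,
             a0 = scn$diff$a0, a1 = scn$diff$a1)
  b <- default_bounds()
  sM <- (diff(range(rec$surface_T_C)) / diff(range(rec$moisture_db)))^2
  problem <- list(goals = c(10, 1e-4), weights = c(1, 1),
                  lb = stats::setNames(b$lb, b$name),
                  ub = stats::setNames(b$ub, b$name),
                  scale_M = sM, tol_step = 1e-6, maxit = 60)
  ga <- goal_attainment(rec, truth, problem, fem, scn$source, ctrl,
                        bi_heat = scn$bi_heat, bi_mass = scn$bi_mass,
                        T0_C = scn$T0_C)
  expect_lte(ga$gamma, 0)
  expect_lte(ga$sse_T, 10)
  expect_lte(ga$sse_M, 1e-4)
  # monotone attainment across accepted iterations
  expect_true(all(diff(ga$trace$gamma) <= 1e-12))
  # positivity constraint satisfied along the final trajectory
  expect_gt(ga$min_eps, 0)
})

test_that("estimation validates its inputs and is rerun-deterministic", {
  nf <- noisefree_record()
  rec <- nf$record
  broken <- rec
  broken$surface_T_C <- NULL
  expect_error(estimate_treatment(broken), "surface_T_C")

  ctrl <- estimation_control(stage1_maxit = 60, stage2_maxit = 30)
  f1 <- estimate_treatment(rec, control = ctrl)
  f2 <- estimate_treatment(rec, control = ctrl)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$gamma, f2$gamma)

  # reported errors are reproducible from the stored coefficients
  fem <- coarse_fem()
  op <- objective_pair(f1$coefficients, rec, fem, f1$source, ctrl,
                       bi_heat = f1$bi_heat, bi_mass = f1$bi_mass,
                       T0_C = f1$T0_C)
  expect_equal(op$sse_T, f1$sse_T, tolerance = 1e-10)
  expect_equal(op$sse_M, f1$sse_M, tolerance = 1e-10)
  expect_equal(f1$stats_T$sse, f1$sse_T, tolerance = 1e-10)
  expect_equal(f1$stats_T$rmse, sqrt(f1$sse_T / nrow(rec)), tolerance = 1e-10)

  # tidiers expose the table-shaped views
  td <- tidy(f1)
  expect_true(all(c("g0", "D0", "Ea") %in% td$term))
  gl <- glance(f1)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("gamma", "sse_T", "r2_M", "mrpe_T") %in% names(gl)))
})
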