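#' Define a synthetic drying scenario
#'
#' A scenario bundles the "true" material models, transfer coefficients,
#' microwave source and sampling schedule from which a synthetic drying
#' record is generated, together with the measurement-noise levels and RNG
#' seed. Generated records emulate the structure of the bench experiments:
#' mass/moisture and surface temperature sampled at 15 s intervals while a
#' tempered seed dries back down to its pre-tempering moisture content.
#'
#' @param loss True [loss_factor_model()].
#' @param diff True [diffusivity_model()].
#' @param source [microwave_source()].
#' @param bi_heat,bi_mass True Biot numbers.
#' @param T0_C Initial seed temperature (degC).
#' @param M0 Initial (tempered) moisture content (d.b. decimal).
#' @param sample_dt Sampling interval (s), default 15 as in the weighing
#'   schedule the record emulates.
#' @param t_max Hard cap on process duration (s), default 1800.
#' @param stop_M Moisture content at which drying stops (d.b.), default 0.10,
#'   the pre-tempering moisture the seeds are dried back to.
#' @param sigma_T Gaussian noise s.d. on temperature (degC), default 0.5
#'   (infrared camera sensitivity 0.1 degC plus handling error).
#' @param sigma_M Gaussian noise s.d. on moisture (d.b.), default 0.003
#'   (0.01 g balance on ~50 g samples, with margin).
#' @param seed RNG seed for the noise draws.
#' @param treatment_id Label.
#' @return An object of class `drying_scenario`.
#' @export
drying_scenario <- function(loss, diff, source, bi_heat, bi_mass,
                            T0_C, M0, sample_dt = 15, t_max = 1800,
                            stop_M = 0.10, sigma_T = 0.5, sigma_M = 0.003,
                            seed = 1L, treatment_id = "synthetic") {
  stopifnot(inherits(loss, "loss_factor_model"),
            inherits(diff, "diffusivity_model"),
            inherits(source, "microwave_source"))
  if (sigma_T < 0 || sigma_M < 0) stop("noise levels must be >= 0")
  if (sample_dt <= 0) stop("`sample_dt` must be positive")
  structure(list(loss = loss, diff = diff, source = source,
                 bi_heat = bi_heat, bi_mass = bi_mass,
                 T0_C = T0_C, M0 = M0, sample_dt = sample_dt, t_max = t_max,
                 stop_M = stop_M, sigma_T = sigma_T, sigma_M = sigma_M,
                 seed = as.integer(seed), treatment_id = treatment_id),
            class = "drying_scenario")
}

#' @export
print.drying_scenario <- function(x, ...) {
  cat(sprintf(paste0("<drying_scenario> '%s': M0 = %.2f d.b., T0 = %.1f degC, ",
                     "Bi = (%.3f, %.3f), noise = (%.2g degC, %.2g d.b.), seed %d\n"),
              x$treatment_id, x$M0, x$T0_C, x$bi_heat, x$bi_mass,
              x$sigma_T, x$sigma_M, x$seed))
  invisible(x)
}

#' The six bench-like scenario presets
#'
#' Two nominal microwave powers (0.35 and 0.70 kW) crossed with three
#' tempering moisture contents (0.20, 0.35, 0.50 d.b.), using the packaged
#' per-treatment coefficient tables as ground truth, the treatment-specific
#' Biot numbers, and 15 s sampling.
#'
#' @param seed Base RNG seed; preset i uses `seed + i - 1`.
#' @param ... Overrides passed to every [drying_scenario()] call (e.g.
#'   `sigma_T = 0`).
#' @return A named list of six `drying_scenario` objects.
#' @examples
#' scns <- make_bench_scenarios(seed = 7, sigma_T = 0, sigma_M = 0)
#' names(scns)
#' @export
make_bench_scenarios <- function(seed = 1L, ...) {
  trts <- lentil_treatments()
  scns <- lapply(seq_len(nrow(trts)), function(i) {
    tm <- treatment_models(trts$treatment[i])
    drying_scenario(loss = tm$loss, diff = tm$diff, source = tm$source,
                    bi_heat = tm$bi_heat, bi_mass = tm$bi_mass,
                    T0_C = tm$T0_C, M0 = tm$imc_db,
                    seed = seed + i - 1L, treatment_id = trts$treatment[i], ...)
  })
  stats::setNames(scns, trts$treatment)
}

#' Generate a synthetic drying record from a scenario
#'
#' Runs the coupled forward model with the scenario's true coefficients,
#' samples the surface temperature and mean moisture content at the sampling
#' schedule (truncated where the mean moisture reaches `stop_M`), and adds
#' independent Gaussian measurement noise per channel. The true generating
#' models and the noise-free series are kept in the record's `meta` attribute
#' so recovery studies can close the loop.
#'
#' @param scenario A [drying_scenario()].
#' @param target_h Mesh resolution (m) for the generating run.
#' @param dt Time step (s) for the generating run.
#' @param as_mass Also emit a mass series for a nominal 50 g sample.
#' @return A [drying_record()].
#' @export
generate_record <- function(scenario, target_h = 2e-4, dt = 1, as_mass = FALSE) {
  stopifnot(inherits(scenario, "drying_scenario"))
  mesh <- generate_mesh(lens_geometry(), target_h = target_h)
  fem <- fem_assemble(mesh)
  config <- simulation_config(T0_C = scenario$T0_C, M0 = scenario$M0,
                              t_end = scenario$t_max, dt = dt)
  bc <- boundary_model(scenario$bi_heat, scenario$bi_mass)
  sol <- run_forward(fem, config, scenario$loss, scenario$diff,
                     scenario$source, bc, stop_below_M = scenario$stop_M)
  t_stop <- max(sol$summary$time_s)
  sched <- seq(0, t_stop, by = scenario$sample_dt)
  clean <- summaries(sol, sched, c("surface_T_C", "mean_M_db"))

  set.seed(scenario$seed)
  noisy_T <- clean$surface_T_C + stats::rnorm(nrow(clean), 0, scenario$sigma_T)
  noisy_M <- pmax(clean$mean_M_db + stats::rnorm(nrow(clean), 0, scenario$sigma_M), 0)
  noisy_M[1] <- scenario$M0   # the initial moisture is set by tempering, not measured

  meta <- list(scenario = scenario, clean = clean,
               source = scenario$source,
               bi_heat = scenario$bi_heat, bi_mass = scenario$bi_mass,
               T0_C = scenario$T0_C, M0 = scenario$M0)
  if (as_mass) {
    m_dry <- 50 / (1 + scenario$M0)
    drying_record(sched, noisy_T, mass_g = m_dry * (1 + noisy_M),
                  M0 = scenario$M0, treatment_id = scenario$treatment_id,
                  meta = meta)
  } else {
    drying_record(sched, noisy_T, moisture_db = noisy_M,
                  treatment_id = scenario$treatment_id, meta = meta)
  }
}
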