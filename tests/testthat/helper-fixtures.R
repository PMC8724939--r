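# Shared fixtures, cached across test files (one process per test run).
sw_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = sw_cache)) assign(key, force(expr), envir = sw_cache)
  get(key, envir = sw_cache)
}

coarse_fem <- function() cached("coarse_fem", {
  fem_assemble(generate_mesh(lens_geometry(), target_h = 4e-4))
})

# a near-constant diffusivity model (Arrhenius factor ~ 1)
flat_diffusivity <- function(D = 1e-7) diffusivity_model(D, 1e-3, 0, 0)

zero_loss <- function() loss_factor_model(rep(0, 8), ash_db = 0)

table_average_models <- function() cached("avg_models", treatment_models("average"))

# noise-free synthetic record for the hottest treatment (shared by several
# estimation tests); generated at a finer time step than the estimation uses
noisefree_record <- function() cached("noisefree_record", {
  scn <- make_bench_scenarios(seed = 1, sigma_T = 0, sigma_M = 0)[["0.70kW-50"]]
  list(scenario = scn, record = generate_record(scn, target_h = 4e-4, dt = 1))
})

# relative error of model property along a (T, M) trajectory
trajectory_rel_err <- function(f_est, f_true, T_K, M) {
  max(abs(f_est(T_K, M) / f_true(T_K, M) - 1))
}
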