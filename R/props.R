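# Physical constants used throughout the package.
.const <- list(
  R_gas    = 8.3143,     # universal gas constant, J/mol/K
  eps0     = 8.854e-12,  # vacuum permittivity, F/m
  f_mw     = 2.45e9,     # magnetron frequency, Hz
  T_zero_C = 273.15      # 0 degC in kelvin
)

#' Bulk density of lentil as a function of moisture content
#'
#' Quadratic correlation in dry-basis moisture content:
#' \eqn{\rho(M) = (0.193 M^2 - 0.311 M + 1.4729) \times 10^3} kg/m3.
#'
#' @param M Dry-basis moisture content (kg water per kg dry matter, decimal;
#'   0.50 means 50 \% d.b.). Vectorised.
#' @return Density in kg/m3.
#' @examples
#' lentil_density(c(0, 0.2, 0.5))
#' @export
lentil_density <- function(M) {
  stopifnot(is.numeric(M))
  if (any(M < 0)) stop("moisture content `M` must be non-negative (dry-basis decimal)")
  (0.193 * M^2 - 0.311 * M + 1.4729) * 1e3
}

#' Specific heat of lentil
#'
#' Correlation in wet-basis moisture fraction \eqn{w = M/(1+M)} and Celsius
#' temperature: \eqn{C_p = (0.5773 + 0.00709\,T' + 6.22 w - 9.14 w^2) \times 10^3}
#' J/kg/K. The temperature enters in degrees Celsius: evaluated in kelvin the
#' correlation would put the specific heat of moist lentil near that of liquid
#' water, which is physically implausible for a seed that is mostly starch.
#'
#' @param T_K Temperature in kelvin. Vectorised.
#' @param M Dry-basis moisture content (decimal). Vectorised.
#' @return Specific heat in J/kg/K.
#' @examples
#' lentil_specific_heat(T_K = 353.15, M = 0.35)
#' @export
lentil_specific_heat <- function(T_K, M) {
  stopifnot(is.numeric(T_K), is.numeric(M))
  if (any(T_K <= 0)) stop("`T_K` must be positive (kelvin)")
  if (any(M < 0)) stop("moisture content `M` must be non-negative")
  Tc <- T_K - .const$T_zero_C
  w <- M / (1 + M)
  (0.5773 + 0.00709 * Tc + 6.22 * w - 9.14 * w^2) * 1e3
}

#' Effective thermal conductivity of lentil
#'
#' \eqn{k_{eff} = 0.193 + 10^{-4} (T - 273.15) + 0.152\, M/(1+M)} W/m/K.
#'
#' @inheritParams lentil_specific_heat
#' @return Thermal conductivity in W/m/K.
#' @export
lentil_thermal_conductivity <- function(T_K, M) {
  stopifnot(is.numeric(T_K), is.numeric(M))
  if (any(T_K <= 0)) stop("`T_K` must be positive (kelvin)")
  if (any(M < 0)) stop("moisture content `M` must be non-negative")
  0.193 + 1e-4 * (T_K - .const$T_zero_C) + 0.152 * M / (1 + M)
}

#' Latent heat of water evaporation
#'
#' Linear correlation \eqn{H_{evap} = 2503000 - 2386\,(T - 273.15)} J/kg,
#' strictly decreasing in temperature.
#'
#' @param T_K Temperature in kelvin. Vectorised.
#' @return Latent heat in J/kg.
#' @export
latent_heat <- function(T_K) {
  stopifnot(is.numeric(T_K))
  if (any(T_K <= 0)) stop("`T_K` must be positive (kelvin)")
  2503000 - 2386 * (T_K - .const$T_zero_C)
}

#' Dielectric loss-factor model
#'
#' Constructs the parametric model for the dielectric loss factor
#' \eqn{\varepsilon''(T', M)} of the seed,
#' \deqn{\varepsilon'' = g_0 + g_1 T' + g_2 T'^2 + 100 g_3 M + 100 g_4 M T'
#'       + g_5 A + g_6 A^2 + g_7 A T'}
#' where \eqn{T'} is the temperature in degrees Celsius, \eqn{M} the dry-basis
#' moisture content and \eqn{A = \mathrm{ash}_{db}/(1+M)} the wet-basis ash
#' content in percent. The ash content is assumed constant on a dry basis
#' during processing, so its wet-basis value varies only through \eqn{M}.
#'
#' @param g Numeric vector of the eight coefficients `g0` ... `g7` (named or
#'   positional).
#' @param ash_db Ash content, percent dry basis. Default 2.6, a typical value
#'   for red lentil.
#' @return An object of class `loss_factor_model`.
#' @examples
#' m <- loss_factor_model(c(2.123, -0.102, 1.68e-4, -8.56e-3,
#'                          5.08e-4, 2.876, -1.566, 0.0479))
#' loss_factor(384.15, 0.10, m)
#' @export
loss_factor_model <- function(g, ash_db = 2.6) {
  g <- as.numeric(g)
  if (length(g) != 8 || anyNA(g)) stop("`g` must be eight finite coefficients g0..g7")
  if (!is.numeric(ash_db) || length(ash_db) != 1 || ash_db < 0)
    stop("`ash_db` must be a single non-negative percentage")
  structure(list(g = stats::setNames(g, paste0("g", 0:7)), ash_db = ash_db),
            class = "loss_factor_model")
}

#' @export
print.loss_factor_model <- function(x, ...) {
  cat("<loss_factor_model>  eps''(T', M), ash =", x$ash_db, "% d.b.\n")
  print(signif(x$g, 4))
  invisible(x)
}

#' Evaluate the dielectric loss factor
#'
#' @param T_K Temperature in kelvin. Vectorised with `M`.
#' @param M Dry-basis moisture content (decimal).
#' @param model A [loss_factor_model()].
#' @return Loss factor \eqn{\varepsilon''} (dimensionless). Positivity is a
#'   constraint of the inverse estimation, not of this evaluator: out-of-range
#'   coefficient sets may legitimately return non-positive values and the
#'   optimiser rejects them.
#' @export
loss_factor <- function(T_K, M, model) {
  stopifnot(inherits(model, "loss_factor_model"))
  Tc <- T_K - .const$T_zero_C
  A <- model$ash_db / (1 + M)
  g <- model$g
  g[[1]] + g[[2]] * Tc + g[[3]] * Tc^2 + 100 * g[[4]] * M +
    100 * g[[5]] * M * Tc + g[[6]] * A + g[[7]] * A^2 + g[[8]] * A * Tc
}

#' Effective moisture diffusivity model
#'
#' Arrhenius temperature kernel with exponential moisture coupling:
#' \deqn{D(T, M) = D_0 \exp\!\big(-E_a 10^3 / (R T)\big)\,
#'       \exp\!\big((a_0 T - a_1) M\big)}
#' with \eqn{T} in kelvin in both exponents, \eqn{E_a} in kJ/mol and
#' \eqn{R = 8.3143} J/mol/K.
#'
#' @param D0 Pre-exponential factor (m2/s), positive.
#' @param Ea Activation energy (kJ/mol), positive.
#' @param a0 Moisture-temperature coupling coefficient (1/K).
#' @param a1 Moisture coefficient (dimensionless).
#' @return An object of class `diffusivity_model`.
#' @examples
#' d <- diffusivity_model(D0 = 2.36e-3, Ea = 29.026, a0 = 1e-6, a1 = 0.5)
#' diffusivity(384.15, 0.10, d)
#' @export
diffusivity_model <- function(D0, Ea, a0, a1) {
  vals <- c(D0 = D0, Ea = Ea, a0 = a0, a1 = a1)
  if (anyNA(vals) || !all(is.finite(vals))) stop("diffusivity coefficients must be finite")
  if (D0 <= 0) stop("`D0` must be positive")
  if (Ea <= 0) stop("`Ea` must be positive (kJ/mol)")
  structure(as.list(vals), class = "diffusivity_model")
}

#' @export
print.diffusivity_model <- function(x, ...) {
  cat(sprintf("<diffusivity_model>  D0 = %.3e m2/s, Ea = %.3f kJ/mol, a0 = %.3e 1/K, a1 = %.3f\n",
              x$D0, x$Ea, x$a0, x$a1))
  invisible(x)
}

#' Evaluate the effective moisture diffusivity
#'
#' @param T_K Temperature in kelvin. Vectorised with `M`.
#' @param M Dry-basis moisture content (decimal).
#' @param model A [diffusivity_model()].
#' @return Diffusivity in m2/s.
#' @export
diffusivity <- function(T_K, M, model) {
  stopifnot(inherits(model, "diffusivity_model"))
  if (any(T_K <= 0)) stop("`T_K` must be positive (kelvin)")
  D <- model$D0 * exp(-model$Ea * 1e3 / (.const$R_gas * T_K)) *
    exp((model$a0 * T_K - model$a1) * M)
  if (any(!is.finite(D))) stop("diffusivity evaluation produced a non-finite value")
  D
}

#' Microwave power source
#'
#' Describes the uniform electric field the seed is exposed to. The field
#' strength is either supplied directly (`e_field` + `e_field_mode =
#' "direct"`) or derived from the available magnetron power and cavity
#' reflection coefficient. Two calibration variants are provided because the
#' published form is used in both renderings in the literature:
#' `"sqrt_over"` (default) gives \eqn{E = \sqrt{2 P_{av}/(1 - |S_{11}|^2)}} in
#' V/cm (converted to V/m), `"sqrt_times"` gives
#' \eqn{E = \sqrt{2 P_{av} (1 - |S_{11}|^2)}}. Any constant miscalibration of
#' `E` is absorbed into the fitted loss-factor scale during inverse
#' estimation, so the estimated heating trajectory is invariant to the variant
#' up to a rescaling of the g-coefficients.
#'
#' @param pav_watts Available magnetron power (W).
#' @param s11 Reflection coefficient, `0 <= s11 < 1`.
#' @param f Field frequency in Hz (default 2.45e9).
#' @param e_field Electric field strength in V/m, used when
#'   `e_field_mode = "direct"`.
#' @param e_field_mode One of `"sqrt_over"`, `"sqrt_times"`, `"direct"`.
#' @return An object of class `microwave_source` with the resolved field
#'   strength in V/m stored as `$E`.
#' @examples
#' microwave_source(pav_watts = 616, s11 = 0.421)
#' @export
microwave_source <- function(pav_watts = NULL, s11 = NULL, f = .const$f_mw,
                             e_field = NULL,
                             e_field_mode = c("sqrt_over", "sqrt_times", "direct")) {
  e_field_mode <- match.arg(e_field_mode)
  if (e_field_mode == "direct") {
    if (is.null(e_field) || e_field < 0) stop("`e_field` (V/m, >= 0) required in direct mode")
    E <- e_field
  } else {
    if (is.null(pav_watts) || pav_watts <= 0) stop("`pav_watts` must be positive")
    if (is.null(s11) || s11 < 0 || s11 >= 1)
      stop("`s11` must satisfy 0 <= s11 < 1 (s11 >= 1 reflects all power)")
    E <- switch(e_field_mode,
      sqrt_over  = sqrt(2 * pav_watts / (1 - s11^2)) * 100, # V/cm -> V/m
      sqrt_times = sqrt(2 * pav_watts * (1 - s11^2)) * 100
    )
  }
  structure(list(f = f, eps0 = .const$eps0, pav_watts = pav_watts, s11 = s11,
                 E = E, e_field_mode = e_field_mode),
            class = "microwave_source")
}

#' @export
print.microwave_source <- function(x, ...) {
  cat(sprintf("<microwave_source>  E = %.1f V/m (%s), f = %.3g Hz\n",
              x$E, x$e_field_mode, x$f))
  invisible(x)
}

#' Field strength of a microwave source
#'
#' @param source A [microwave_source()].
#' @return Electric field strength in V/m.
#' @export
field_strength <- function(source) {
  stopifnot(inherits(source, "microwave_source"))
  source$E
}

#' Volumetric microwave heating rate
#'
#' Dissipated microwave power per unit volume of a lossy dielectric in a
#' uniform field: \eqn{q_{MW} = 2 \pi f \varepsilon_0 \varepsilon'' E^2}.
#'
#' @param E Electric field strength (V/m).
#' @param eps_pp Dielectric loss factor (dimensionless). Vectorised.
#' @param source A [microwave_source()] supplying the frequency.
#' @return Heating rate in W/m3.
#' @export
volumetric_heating <- function(E, eps_pp, source) {
  stopifnot(inherits(source, "microwave_source"))
  if (any(E < 0)) stop("`E` must be non-negative")
  2 * pi * source$f * source$eps0 * eps_pp * E^2
}

#' Evaluate lentil properties over a state grid
#'
#' Convenience tabulation of every property correlation at the supplied
#' states; handy for plotting property surfaces.
#'
#' @param states A data frame with columns `T_K` and `M`.
#' @param loss A [loss_factor_model()] or `NULL`.
#' @param diff A [diffusivity_model()] or `NULL`.
#' @return A tibble with one row per state and one column per property.
#' @export
lentil_properties <- function(states, loss = NULL, diff = NULL) {
  stopifnot(is.data.frame(states), all(c("T_K", "M") %in% names(states)))
  out <- tibble::tibble(
    T_K = states$T_K,
    M = states$M,
    density_kg_m3 = lentil_density(states$M),
    cp_J_kgK = lentil_specific_heat(states$T_K, states$M),
    k_W_mK = lentil_thermal_conductivity(states$T_K, states$M),
    h_evap_J_kg = latent_heat(states$T_K)
  )
  if (!is.null(loss)) out$loss_factor <- loss_factor(states$T_K, states$M, loss)
  if (!is.null(diff)) out$diffusivity_m2_s <- diffusivity(states$T_K, states$M, diff)
  out
}
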