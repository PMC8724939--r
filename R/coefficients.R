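#' Packaged coefficient tables for the lentil drying treatments
#'
#' Returns the fitted model coefficients for the six drying treatments
#' (two nominal microwave powers crossed with three tempering moisture
#' contents). `"loss_factor"` holds the eight polynomial coefficients
#' `g0` ... `g7` of [loss_factor_model()]; `"diffusivity"` holds `D0` (m2/s),
#' `Ea` (kJ/mol), `a0` (1/K) and `a1` of [diffusivity_model()].
#'
#' @param table Which table to load.
#' @return A tibble with one row per treatment, keyed by `treatment`,
#'   `power_kW` and `imc_db` (initial moisture content, dry-basis decimal).
#' @examples
#' lentil_coefficients("diffusivity")
#' @export
lentil_coefficients <- function(table = c("loss_factor", "diffusivity")) {
  table <- match.arg(table)
  path <- system.file("extdata", paste0(table, "_coefficients.json"),
                      package = "seedwave", mustWork = TRUE)
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Per-treatment process configuration
#'
#' Operating conditions for the six drying treatments: nominal and available
#' magnetron power, cavity reflection coefficient, tempering (initial)
#' moisture content, and the heat/mass-transfer Biot numbers recovered by the
#' inverse estimation. The available power is 0.616 kW at the 0.7 kW nominal
#' setting (88 \% of rating, calorimetric calibration) and half of that at the
#' 0.35 kW setting. Reflection coefficients are 0.694 (0.35 kW) and 0.421
#' (0.7 kW). The heat-transfer Biot number is 0.043 for every treatment except
#' the hottest one (0.7 kW at 50 \% tempering, 0.038); the mass-transfer Biot
#' number is 0.015 except for the 50 \% temperings (0.016).
#'
#' @return A tibble with one row per treatment.
#' @export
lentil_treatments <- function() {
  trt <- tibble::tibble(
    treatment = c("0.70kW-20", "0.70kW-35", "0.70kW-50",
                  "0.35kW-20", "0.35kW-35", "0.35kW-50"),
    power_kW = rep(c(0.70, 0.35), each = 3),
    imc_db = rep(c(0.20, 0.35, 0.50), 2),
    pav_watts = rep(c(616, 308), each = 3),
    s11 = rep(c(0.421, 0.694), each = 3)
  )
  trt$bi_heat <- ifelse(trt$treatment == "0.70kW-50", 0.038, 0.043)
  trt$bi_mass <- ifelse(trt$imc_db == 0.50, 0.016, 0.015)
  trt$T0_C <- 4.5   # mid-range of the 3-6 degC initial seed temperatures
  trt
}

#' Models for a named treatment
#'
#' Convenience constructor bundling the packaged coefficient rows and process
#' configuration of one treatment into ready-to-use model objects.
#'
#' @param treatment Treatment id, e.g. `"0.70kW-50"`, or `"average"` for the
#'   across-treatment mean coefficients.
#' @param ash_db Ash content (percent dry basis) passed to
#'   [loss_factor_model()].
#' @return A list with elements `loss`, `diff`, `source`, `bi_heat`,
#'   `bi_mass`, `imc_db`, `T0_C` and `treatment`.
#' @examples
#' tm <- treatment_models("0.70kW-50")
#' diffusivity(384.15, 0.10, tm$diff)
#' @export
treatment_models <- function(treatment, ash_db = 2.6) {
  lf <- lentil_coefficients("loss_factor")
  df <- lentil_coefficients("diffusivity")
  trts <- lentil_treatments()
  if (identical(treatment, "average")) {
    g <- colMeans(lf[paste0("g", 0:7)])
    dd <- colMeans(df[c("D0", "Ea", "a0", "a1")])
    cfg <- trts[trts$treatment == "0.70kW-35", ]   # representative conditions
  } else {
    if (!treatment %in% lf$treatment)
      stop("unknown treatment '", treatment, "'; see lentil_treatments()")
    g <- unlist(lf[lf$treatment == treatment, paste0("g", 0:7)])
    dd <- unlist(df[df$treatment == treatment, c("D0", "Ea", "a0", "a1")])
    cfg <- trts[trts$treatment == treatment, ]
  }
  list(
    loss = loss_factor_model(g, ash_db = ash_db),
    diff = diffusivity_model(D0 = dd[["D0"]], Ea = dd[["Ea"]],
                             a0 = dd[["a0"]], a1 = dd[["a1"]]),
    source = microwave_source(pav_watts = cfg$pav_watts, s11 = cfg$s11),
    bi_heat = cfg$bi_heat, bi_mass = cfg$bi_mass,
    imc_db = cfg$imc_db, T0_C = cfg$T0_C,
    treatment = if (identical(treatment, "average")) "average" else cfg$treatment
  )
}
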