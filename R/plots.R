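#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a drying fit
#'
#' One row per estimated coefficient, mirroring the layout of the published
#' per-treatment coefficient tables.
#'
#' @param x A [estimate_treatment()] result.
#' @param ... Unused.
#' @return A tibble with `treatment`, `term`, `estimate`, `lower`, `upper`.
#' @method tidy drying_fit
#' @export
tidy.drying_fit <- function(x, ...) {
  bounds <- default_bounds(fit_biot = x$control$fit_biot)
  tibble::tibble(
    treatment = x$treatment_id,
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    lower = bounds$lb[match(names(x$coefficients), bounds$name)],
    upper = bounds$ub[match(names(x$coefficients), bounds$name)]
  )
}

#' One-row summary of a drying fit
#'
#' The per-treatment fit-quality row: attainment level and, for each
#' measured channel, SSE, R2, RMSE and MRPE.
#'
#' @inheritParams tidy.drying_fit
#' @return A one-row tibble.
#' @method glance drying_fit
#' @export
glance.drying_fit <- function(x, ...) {
  tibble::tibble(
    treatment = x$treatment_id,
    gamma = x$gamma,
    sse_T = x$stats_T$sse, r2_T = x$stats_T$r2,
    rmse_T = x$stats_T$rmse, mrpe_T = x$stats_T$mrpe,
    sse_M = x$stats_M$sse, r2_M = x$stats_M$r2,
    rmse_M = x$stats_M$rmse, mrpe_M = x$stats_M$mrpe,
    n = x$stats_T$n, evaluations = x$evaluations, converged = x$converged
  )
}

#' Plot measured and fitted drying curves
#'
#' Two panels: surface temperature and mean moisture content, measurements as
#' points and the fitted coupled-model trajectories as lines.
#'
#' @param object A `drying_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drying_fit
#' @export
autoplot.drying_fit <- function(object, ...) {
  rec <- object$record
  obs <- dplyr::bind_rows(
    tibble::tibble(time_s = rec$time_s, value = rec$surface_T_C,
                   channel = "surface temperature (degC)"),
    tibble::tibble(time_s = rec$time_s, value = rec$moisture_db,
                   channel = "mean moisture (d.b.)"))
  sim <- dplyr::bind_rows(
    tibble::tibble(time_s = object$sim$time_s, value = object$sim$surface_T_C,
                   channel = "surface temperature (degC)"),
    tibble::tibble(time_s = object$sim$time_s, value = object$sim$mean_M_db,
                   channel = "mean moisture (d.b.)"))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = sim, colour = "red3") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("Inverse fit:", object$treatment_id)) +
    ggplot2::theme_bw()
}

#' Plot simulated drying summary curves
#'
#' Mean, surface and center trajectories of temperature and moisture from a
#' [simulate_drying()] run.
#'
#' @param object A `drying_simulation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot drying_simulation
#' @export
autoplot.drying_simulation <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                              names_to = "series", values_to = "value")
  long$channel <- ifelse(grepl("_T_C$", long$series),
                         "temperature (degC)", "moisture (d.b.)")
  long$location <- sub("_(T_C|M_db)$", "", long$series)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$location)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_bw()
}

#' Plot estimated property trajectories against a reference
#'
#' Evaluates the fitted loss-factor and diffusivity models along the fitted
#' mean-state trajectory, optionally with reference (true) models for
#' parameter-recovery studies.
#'
#' @param fit A `drying_fit`.
#' @param reference Optional list with elements `loss` and/or `diff`.
#' @return A ggplot object.
#' @export
plot_property_trajectories <- function(fit, reference = NULL) {
  sim <- fit$sim
  T_K <- sim$mean_T_C + 273.15
  M <- sim$mean_M_db
  dat <- dplyr::bind_rows(
    tibble::tibble(time_s = sim$time_s, model = "estimated",
                   value = loss_factor(T_K, M, fit$loss),
                   property = "loss factor"),
    tibble::tibble(time_s = sim$time_s, model = "estimated",
                   value = diffusivity(T_K, M, fit$diff),
                   property = "diffusivity (m2/s)"))
  if (!is.null(reference$loss))
    dat <- dplyr::bind_rows(dat, tibble::tibble(
      time_s = sim$time_s, model = "reference",
      value = loss_factor(T_K, M, reference$loss), property = "loss factor"))
  if (!is.null(reference$diff))
    dat <- dplyr::bind_rows(dat, tibble::tibble(
      time_s = sim$time_s, model = "reference",
      value = diffusivity(T_K, M, reference$diff),
      property = "diffusivity (m2/s)"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s, y = .data$value,
                                    linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_bw()
}
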