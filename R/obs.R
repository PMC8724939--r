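#' Construct a drying record
#'
#' A drying record holds the measured time series of one treatment: sample
#' time stamps (s, strictly increasing from 0), dry-basis moisture content
#' (either given directly or derived from a mass series via
#' [moisture_from_mass()]), and mean surface temperature (degrees Celsius).
#'
#' @param times Measurement times (s), strictly increasing, starting at 0.
#' @param surface_T_C Mean surface temperature series (degC).
#' @param moisture_db Dry-basis moisture series (decimal). Give exactly one of
#'   `moisture_db` or `mass_g`.
#' @param mass_g Sample mass series (g); converted with `M0`.
#' @param M0 Initial dry-basis moisture, required with `mass_g`.
#' @param treatment_id Label for the treatment.
#' @param meta Optional named list of process metadata (power, initial state,
#'   source and boundary settings); stored as an attribute.
#' @return A tibble of class `drying_record` with columns `time_s`,
#'   `moisture_db`, `surface_T_C` (and `mass_g` when supplied).
#' @export
drying_record <- function(times, surface_T_C, moisture_db = NULL, mass_g = NULL,
                          M0 = NULL, treatment_id = "treatment", meta = list()) {
  if (length(times) < 2 || is.unsorted(times, strictly = TRUE) || times[1] != 0)
    stop("`times` must be strictly increasing and start at 0")
  if (is.null(moisture_db) == is.null(mass_g))
    stop("supply exactly one of `moisture_db` or `mass_g`")
  if (is.null(surface_T_C) || length(surface_T_C) != length(times))
    stop("`surface_T_C` must match `times` in length")
  out <- tibble::tibble(time_s = as.numeric(times),
                        surface_T_C = as.numeric(surface_T_C))
  if (!is.null(mass_g)) {
    if (is.null(M0)) stop("`M0` is required to convert a mass series")
    out$mass_g <- as.numeric(mass_g)
    out$moisture_db <- moisture_from_mass(mass_g, M0)
  } else {
    if (any(moisture_db < 0)) stop("`moisture_db` must be non-negative")
    out$moisture_db <- as.numeric(moisture_db)
  }
  out <- out[, c("time_s", intersect("mass_g", names(out)), "moisture_db",
                 "surface_T_C")]
  attr(out, "treatment_id") <- treatment_id
  attr(out, "meta") <- meta
  class(out) <- c("drying_record", class(out))
  out
}

#' Dry-basis moisture from a mass series
#'
#' The dry-matter mass is fixed by the first sample,
#' \eqn{m_{dry} = m(0)/(1 + M_0)}, and
#' \eqn{M(t) = (m(t) - m_{dry})/m_{dry}} thereafter.
#'
#' @param mass_g Sample mass series (g), positive.
#' @param M0 Initial dry-basis moisture content (decimal), >= 0.
#' @return Dry-basis moisture series (decimal).
#' @examples
#' moisture_from_mass(c(60, 55), M0 = 0.20)
#' @export
moisture_from_mass <- function(mass_g, M0) {
  if (any(mass_g <= 0)) stop("`mass_g` must be positive")
  if (M0 < 0) stop("`M0` must be >= 0")
  m_dry <- mass_g[1] / (1 + M0)
  M <- (mass_g - m_dry) / m_dry
  if (any(M < -1e-6))
    stop("mass series implies negative moisture: `M0` inconsistent with the data")
  M
}

#' Read / write drying-record CSV files
#'
#' Comma-separated, header row, UTF-8; times in seconds, temperature in
#' degrees Celsius, moisture as dry-basis decimal (column `moisture_db`) or
#' mass in grams (column `mass_g`, converted with `M0`).
#'
#' @param path File path.
#' @param M0 Initial moisture (d.b.), required when the file carries `mass_g`
#'   instead of `moisture_db`.
#' @param treatment_id,meta Passed to [drying_record()].
#' @return [read_drying_record()]: a `drying_record`;
#'   [write_drying_record()]: `path`, invisibly.
#' @export
read_drying_record <- function(path, M0 = NULL, treatment_id = basename(path),
                               meta = list()) {
  df <- utils::read.csv(path)
  if (!"time_s" %in% names(df)) stop("missing required column `time_s`")
  if (!"surface_T_C" %in% names(df)) stop("missing required column `surface_T_C`")
  if ("moisture_db" %in% names(df)) {
    drying_record(df$time_s, df$surface_T_C, moisture_db = df$moisture_db,
                  treatment_id = treatment_id, meta = meta)
  } else if ("mass_g" %in% names(df)) {
    drying_record(df$time_s, df$surface_T_C, mass_g = df$mass_g, M0 = M0,
                  treatment_id = treatment_id, meta = meta)
  } else stop("need a `moisture_db` or `mass_g` column")
}

#' @rdname read_drying_record
#' @param record A `drying_record`.
#' @export
write_drying_record <- function(record, path) {
  utils::write.csv(as.data.frame(record), path, row.names = FALSE)
  invisible(path)
}

#' Fit a truncated Fourier series to a time series
#'
#' Nonlinear least squares of
#' \deqn{f(t) = a_0 + \sum_{k=1}^{K} \big(a_k \cos(k\omega t) + b_k \sin(k\omega t)\big)}
#' with free fundamental frequency \eqn{\omega}. For fixed \eqn{\omega} the
#' problem is linear, so the fit profiles \eqn{\omega}: a grid around the
#' initialiser \eqn{\omega_0 = 2\pi/(t_{max}-t_{min})} followed by a local
#' golden-section refinement, each inner solve an ordinary least squares.
#' This is the smoothing used to drive the decoupled stage-1 estimators; the
#' smoothed curve is never itself a reported result.
#'
#' @param times,values Equal-length numeric series; at least `2K + 3` points.
#' @param n_harmonics Number of harmonic pairs K (default 5).
#' @return An object of class `fourier_fit` with elements `a0`, `a`, `b`,
#'   `omega`, `domain`, `sse`, `fitted`. Supports `predict(fit, t)` and
#'   `fourier_derivative(fit, t)`.
#' @export
fit_fourier <- function(times, values, n_harmonics = 5) {
  n <- length(times)
  stopifnot(n == length(values), n_harmonics >= 1)
  npar <- 2 * n_harmonics + 2
  if (n < npar + 1)
    stop("need at least ", npar + 1, " points for ", n_harmonics, " harmonics")
  span <- diff(range(times))
  if (span <= 0) stop("`times` must span a positive interval")
  omega0 <- 2 * pi / span

  design <- function(w) {
    k <- seq_len(n_harmonics)
    cbind(1, cos(outer(times, k * w)), sin(outer(times, k * w)))
  }
  sse_at <- function(w) {
    fit <- stats::lm.fit(design(w), values)
    sum(fit$residuals^2)
  }
  # profile omega: coarse grid then local refinement
  grid <- omega0 * exp(seq(log(0.15), log(6), length.out = 80))
  sses <- vapply(grid, sse_at, numeric(1))
  i <- which.min(sses)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(sse_at, interval = c(lo, hi), tol = omega0 * 1e-8)
  omega <- if (opt$objective < sses[i]) opt$minimum else grid[i]

  X <- design(omega)
  fit <- stats::lm.fit(X, values)
  coefs <- fit$coefficients
  if (anyNA(coefs)) {
    # rank-deficient at the profiled omega: fall back to the initialiser
    # frequency where the harmonics are orthogonal over the span
    omega <- omega0
    X <- design(omega)
    fit <- stats::lm.fit(X, values)
    coefs <- fit$coefficients
    coefs[is.na(coefs)] <- 0
  }
  k <- seq_len(n_harmonics)
  structure(list(a0 = unname(coefs[1]), a = unname(coefs[1 + k]),
                 b = unname(coefs[1 + n_harmonics + k]),
                 omega = omega, domain = range(times),
                 n_harmonics = n_harmonics,
                 sse = sum(fit$residuals^2),
                 fitted = as.numeric(X %*% coefs)),
            class = "fourier_fit")
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("<fourier_fit>  %d harmonics, omega = %.4g 1/s, SSE = %.4g\n",
              x$n_harmonics, x$omega, x$sse))
  invisible(x)
}

#' @export
predict.fourier_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) NULL else
    if (is.data.frame(newdata)) newdata$time_s else newdata
  if (is.null(t)) return(object$fitted)
  if (any(t < object$domain[1] - 1e-9) || any(t > object$domain[2] + 1e-9))
    stop("fourier fit evaluated outside its fitted domain")
  k <- seq_len(object$n_harmonics)
  as.numeric(object$a0 + cos(outer(t, k * object$omega)) %*% object$a +
               sin(outer(t, k * object$omega)) %*% object$b)
}

#' Analytic time derivative of a Fourier fit
#'
#' @param fit A [fit_fourier()] result.
#' @param t Times inside the fitted domain.
#' @return The derivative series.
#' @export
fourier_derivative <- function(fit, t) {
  if (any(t < fit$domain[1] - 1e-9) || any(t > fit$domain[2] + 1e-9))
    stop("fourier fit evaluated outside its fitted domain")
  k <- seq_len(fit$n_harmonics)
  kw <- k * fit$omega
  as.numeric(-sin(outer(t, kw)) %*% (kw * fit$a) +
               cos(outer(t, kw)) %*% (kw * fit$b))
}

#' Goodness-of-fit statistics between observed and predicted series
#'
#' Sum of squared errors, coefficient of determination, root mean square
#' error and mean relative percentage error:
#' \eqn{MRPE = (100/n) \sum |o_i - p_i| / |o_i|}, computed on the reporting
#' scale of the series. Points with a zero observed value are excluded from
#' the MRPE and counted in `n_excluded_mrpe`.
#'
#' @param observed,predicted Equal-length numeric series, `n >= 2`.
#' @return A one-row tibble: `sse`, `r2`, `rmse`, `mrpe`, `n`,
#'   `n_excluded_mrpe`. `r2` is `NA` for a constant observed series.
#' @examples
#' fit_statistics(c(1, 3), c(2, 2))
#' @export
fit_statistics <- function(observed, predicted) {
  n <- length(observed)
  stopifnot(n == length(predicted), n >= 2)
  res <- observed - predicted
  sse <- sum(res^2)
  sst <- sum((observed - mean(observed))^2)
  nz <- observed != 0
  tibble::tibble(
    sse = sse,
    r2 = if (sst > 0) 1 - sse / sst else NA_real_,
    rmse = sqrt(sse / n),
    mrpe = 100 * mean(abs(res[nz]) / abs(observed[nz])),
    n = n,
    n_excluded_mrpe = sum(!nz)
  )
}
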