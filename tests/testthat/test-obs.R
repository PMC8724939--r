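test_that("moisture is recovered from a mass series by dry-matter bookkeeping", {
  M <- moisture_from_mass(c(60, 55), M0 = 0.20)
  expect_equal(M, c(0.20, 0.10))
  expect_equal(moisture_from_mass(c(48, 48, 48), 0.35), rep(0.35, 3))
  # round trip: mass -> moisture -> mass
  mass <- c(52, 50, 47.5, 45)
  M <- moisture_from_mass(mass, 0.30)
  m_dry <- 52 / 1.30
  expect_equal(m_dry * (1 + M), mass, tolerance = 1e-12)
  expect_error(moisture_from_mass(c(50, 30), M0 = 0.1), "inconsistent")
})

test_that("drying-record construction validates its inputs", {
  t <- seq(0, 150, by = 15)
  T_C <- seq(5, 60, length.out = 11)
  rec <- drying_record(t, T_C, moisture_db = seq(0.5, 0.3, length.out = 11))
  expect_s3_class(rec, "drying_record")
  expect_named(rec, c("time_s", "moisture_db", "surface_T_C"))
  rec2 <- drying_record(t, T_C, mass_g = seq(60, 50, length.out = 11), M0 = 0.5)
  expect_equal(rec2$moisture_db[1], 0.5)
  expect_error(drying_record(t - 1, T_C, moisture_db = T_C * 0), "start at 0")
  expect_error(drying_record(t, T_C), "exactly one")
  expect_error(drying_record(t, T_C[-1], moisture_db = T_C * 0), "length")
})

test_that("drying-record CSV round trip preserves the data", {
  t <- seq(0, 150, by = 15)
  rec <- drying_record(t, seq(5, 60, length.out = 11),
                       moisture_db = seq(0.5, 0.3, length.out = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  write_drying_record(rec, path)
  back <- read_drying_record(path)
  expect_equal(back$time_s, rec$time_s)
  expect_equal(back$moisture_db, rec$moisture_db)
  expect_equal(back$surface_T_C, rec$surface_T_C)
})

test_that("fourier fit recovers an exact five-harmonic series", {
  t <- seq(0, 400, by = 8)
  om <- 2 * pi / 400 * 1.2
  a0 <- 3; a <- c(0.8, -0.4, 0.2, 0.1, -0.05); b <- c(0.5, 0.3, -0.2, 0.05, 0.02)
  y <- a0 + sapply(seq_along(t), function(i)
    sum(a * cos(1:5 * om * t[i]) + b * sin(1:5 * om * t[i])))
  fit <- fit_fourier(t, y)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$omega, om, tolerance = 1e-4)
  expect_equal(predict(fit, t), y, tolerance = 1e-5)
})

test_that("fourier fit of a constant series is the constant", {
  t <- seq(0, 300, by = 15)
  fit <- fit_fourier(t, rep(2.5, length(t)))
  expect_equal(fit$a0, 2.5, tolerance = 1e-8)
  expect_lt(max(abs(c(fit$a, fit$b))), 1e-6)
})

test_that("fourier residual is nested in harmonics and beats the constant fit", {
  t <- seq(0, 450, by = 15)
  y <- 0.5 * exp(-t / 150) + 0.1        # drying-like decay
  sse_const <- sum((y - mean(y))^2)
  sses <- vapply(1:5, function(k) fit_fourier(t, y, n_harmonics = k)$sse,
                 numeric(1))
  expect_true(all(diff(sses) <= 1e-12))
  expect_lte(sses[1], sse_const)
  expect_error(fit_fourier(t[1:10], y[1:10]), "at least")
})

test_that("fourier derivative matches a numerical derivative inside the domain", {
  t <- seq(0, 400, by = 10)
  y <- 60 - 55 * exp(-t / 120)
  fit <- fit_fourier(t, y)
  tt <- seq(50, 350, by = 25)
  h <- 1e-3
  num <- (predict(fit, tt + h) - predict(fit, tt - h)) / (2 * h)
  expect_equal(fourier_derivative(fit, tt), num, tolerance = 1e-5)
  expect_error(predict(fit, 500), "domain")
  expect_error(fourier_derivative(fit, -5), "domain")
})

test_that("fit statistics reproduce hand-computed values and invariances", {
  perfect <- fit_statistics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$sse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mrpe, 0)

  s <- fit_statistics(c(1, 3), c(2, 2))
  expect_equal(s$sse, 2)
  expect_equal(s$rmse, 1)
  expect_equal(s$r2, 0)
  expect_equal(s$mrpe, 100 * (1 / 1 + 1 / 3) / 2)   # 66.67 %

  # shift invariance of sse and rmse
  o <- c(2, 5, 7, 4); p <- c(2.5, 4.4, 7.3, 3.6)
  s1 <- fit_statistics(o, p); s2 <- fit_statistics(o + 10, p + 10)
  expect_equal(s1$sse, s2$sse)
  expect_equal(s1$rmse, s2$rmse)

  # zero observations are excluded from mrpe and counted
  s3 <- fit_statistics(c(0, 1, 2), c(0.1, 1, 2))
  expect_equal(s3$n_excluded_mrpe, 1)
  expect_equal(s3$mrpe, 0)
})
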