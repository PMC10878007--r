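test_that("Savitzky-Golay second derivative is exact for low-degree polynomials", {
  w <- short_grid()
  const <- spectra_set(w, matrix(5, 1, length(w)))
  expect_equal(max(abs(savgol(const, deriv_order = 2)$values)), 0,
               tolerance = 1e-10)
  # quadratic in wavenumber: second derivative 2*a everywhere (edges included)
  a <- 3e-4
  quad <- spectra_set(w, matrix(a * (w - 1400)^2, 1))
  d2 <- savgol(quad, deriv_order = 2)$values
  expect_equal(as.numeric(d2), rep(2 * a, length(w)), tolerance = 1e-8)
  # smoothing leaves a polynomial of the fitted degree untouched
  sm <- savgol(quad, deriv_order = 0)$values
  expect_equal(as.numeric(sm), a * (w - 1400)^2, tolerance = 1e-8)
})

test_that("Savitzky-Golay matches the per-window polyfit oracle on random input", {
  set.seed(11)
  w <- short_grid()
  y <- cumsum(rnorm(length(w), sd = 0.05))
  s <- spectra_set(w, matrix(y, 1))
  ts <- 1.928
  for (m in c(0, 2)) {
    got <- as.numeric(savgol(s, window = 11, poly_order = 2,
                             deriv_order = m)$values)
    want <- savgol_oracle(y, window = 11, p = 2, m = m, ts = ts)
    expect_equal(got, want, tolerance = 1e-8, info = paste("deriv", m))
  }
  # cubic signal: interior second derivative equals the analytic 6*x
  x <- seq_along(w) * ts
  cube <- spectra_set(w, matrix(x^3, 1))
  d2 <- as.numeric(savgol(cube, deriv_order = 2)$values)
  interior <- 6:(length(w) - 5)
  expect_equal(d2[interior], 6 * x[interior], tolerance = 1e-7)
})

test_that("savgol rejects bad windows and non-uniform grids", {
  w <- short_grid()
  s <- spectra_set(w, matrix(rnorm(length(w)), 1))
  expect_error(savgol(s, window = 10), regexp = "odd")
  expect_error(savgol(s, window = 3, poly_order = 4), regexp = "odd|poly")
  wbad <- sort(c(seq(1900, 1000, by = -5), 997), decreasing = TRUE)
  sbad <- spectra_set(wbad, matrix(rnorm(length(wbad)), 1))
  expect_error(savgol(sbad), regexp = "resample")
})

test_that("region cutting retains exactly the gap intervals", {
  g <- ftir_grid()
  s <- spectra_set(g, matrix(seq_along(g), 1))
  cc <- cut_regions(s)
  w <- cc$wavenumbers
  expect_equal(length(w), sum(g >= 2800 & g <= 3100) +
                 sum(g >= 900 & g <= 1800))
  expect_false(any(w > 1800 & w < 2800))
  expect_false(any(w > 3100 | w < 900))
  # closed retained boundary: a grid point exactly at 3100 survives
  s2 <- spectra_set(seq(3150, 2750, by = -50), matrix(0, 1, 9))
  w2 <- cut_regions(s2, list(c(4000, 3100), c(2800, 1800)))$wavenumbers
  expect_true(3100 %in% w2)
  expect_true(2800 %in% w2)
  expect_false(3150 %in% w2)
  # empty removal list is the identity, repetition is idempotent
  expect_identical(cut_regions(s, list())$values, s$values)
  expect_identical(cut_regions(cc)$wavenumbers, cc$wavenumbers)
  expect_error(cut_regions(s, list(c(4000, 400))), regexp = "no grid points")
})

test_that("EMSC recovers affine constructions exactly", {
  w <- short_grid()
  ref <- gaussian_spectrum(w, c(1742, 1656, 1083), c(0.5, 1, 0.6),
                           c(8, 10, 11))
  set <- spectra_set(w, rbind(ref, 2 * ref + 5), c("ref", "affine"))
  model <- emsc_fit(set, reference = ref)
  expect_equal(unname(model$coefficients["ref", "b"]), 1, tolerance = 1e-10)
  expect_equal(max(abs(model$coefficients["ref",
                                          c("a0", "a1", "a2")])), 0,
               tolerance = 1e-10)
  expect_equal(unname(model$coefficients["affine", "b"]), 2,
               tolerance = 1e-10)
  corrected <- emsc_correct(set, model)
  expect_equal(as.numeric(corrected$values[1, ]), ref, tolerance = 1e-10)
  expect_equal(as.numeric(corrected$values[2, ]), ref, tolerance = 1e-10)
})

test_that("EMSC coefficients match a generic least-squares oracle", {
  set.seed(5)
  w <- short_grid()
  ref <- gaussian_spectrum(w, c(1700, 1400, 1100), c(1, 0.7, 0.4),
                           c(15, 12, 10))
  vals <- t(replicate(6, runif(1, 0.5, 2) * ref +
                        rnorm(length(w), sd = 0.02)))
  set <- spectra_set(w, vals)
  model <- emsc_fit(set, reference = ref, poly_degree = 2)
  x <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  X <- cbind(1, x, (3 * x^2 - 1) / 2, ref)
  for (i in 1:6) {
    beta <- solve(crossprod(X), crossprod(X, vals[i, ]))
    expect_equal(unname(model$coefficients[i, c("a0", "a1", "a2", "b")]),
                 as.numeric(beta), tolerance = 1e-8)
  }
})

test_that("EMSC correction is idempotent and refits to identity", {
  set.seed(6)
  w <- short_grid()
  ref <- gaussian_spectrum(w, c(1650, 1080), c(1, 0.5), c(12, 10))
  x <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  vals <- t(sapply(1:5, function(i)
    runif(1, 0.5, 2) * ref + runif(1, -1, 1) + runif(1, -0.5, 0.5) * x +
      runif(1, -0.3, 0.3) * x^2))
  set <- spectra_set(w, vals)
  model <- emsc_fit(set, reference = ref)
  corrected <- emsc_correct(set, model)
  # refit: b == 1, baseline == 0
  refit <- emsc_fit(corrected, reference = ref)
  expect_equal(unname(refit$coefficients[, "b"]), rep(1, 5),
               tolerance = 1e-8)
  expect_equal(max(abs(refit$coefficients[, c("a0", "a1", "a2")])), 0,
               tolerance = 1e-8)
  # idempotence
  twice <- emsc_correct(corrected, refit)
  expect_equal(twice$values, corrected$values, tolerance = 1e-10)
})

test_that("EMSC flags uncorrectable spectra and singular designs", {
  w <- short_grid()
  x <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
  ref <- gaussian_spectrum(w, 1650, 1, 12)
  # a spectrum orthogonal to the reference gets b ~ 0
  set <- spectra_set(w, rbind(ref, x))
  model <- emsc_fit(set, reference = ref)
  expect_warning(corrected <- emsc_correct(set, model, b_tol = 1e-3),
                 regexp = "uncorrectable")
  expect_equal(n_spectra(corrected), 1)
  expect_equal(attr(corrected, "excluded"), set$meta$spectrum_id[2])
  # polynomial reference is collinear with the baseline basis
  expect_error(emsc_fit(spectra_set(w, matrix(x, 1)), reference = 1 + x),
               regexp = "singular")
})

test_that("mean-reference correction keeps the set mean near the reference", {
  set.seed(7)
  w <- short_grid()
  base <- gaussian_spectrum(w, c(1740, 1650, 1080), c(0.4, 1, 0.5),
                            c(8, 10, 11))
  vals <- t(replicate(8, runif(1, 0.7, 1.3) * base +
                        rnorm(length(w), sd = 0.01)))
  set <- spectra_set(w, vals)
  model <- emsc_fit(set)
  corrected <- emsc_correct(set, model)
  ref <- colMeans(set$values)
  expect_lt(max(abs(colMeans(corrected$values) - ref)), 0.02)
})

test_that("the two pipelines produce the contracted grids deterministically", {
  truth <- small_truth()
  sub <- truth$spectra[1:4, ]
  vals <- t(sapply(1:4, function(i)
    render_spectrum(truth, sub$strain_id[i], sub$temperature[i],
                    sub$bio_replicate[i], sub$tech_replicate[i],
                    noise_sd = 0.01)$values[1, ]))
  set <- spectra_set(ftir_grid(), vals, sub$spectrum_id)

  pca_out <- pipeline_pca(set)
  expect_false(any(pca_out$wavenumbers > 1800 & pca_out$wavenumbers < 2800))
  expect_false(any(pca_out$wavenumbers > 3100 | pca_out$wavenumbers < 900))
  expect_s3_class(attr(pca_out, "emsc_model"), "emsc_model")

  ratio_out <- pipeline_ratio(set)
  expect_true(all(ratio_out$wavenumbers <= 1900 &
                    ratio_out$wavenumbers >= 900))

  # bit-identical on re-run
  expect_identical(pipeline_pca(set)$values, pca_out$values)
  expect_identical(pipeline_ratio(set)$values, ratio_out$values)
})

test_that("spectra sets validate their grid and round-trip through text", {
  expect_error(spectra_set(c(1, 2, 2, 3), matrix(0, 1, 4)),
               regexp = "monotonic")
  # ascending input is normalized to descending storage
  s <- spectra_set(c(1000, 1100, 1200), matrix(c(1, 2, 3), 1))
  expect_equal(s$wavenumbers, c(1200, 1100, 1000))
  expect_equal(as.numeric(s$values), c(3, 2, 1))

  w <- seq(1900, 1700, by = -1.928)
  set <- spectra_set(w, rbind(sin(w / 50), cos(w / 70)), c("a", "b"))
  f <- tempfile(fileext = ".tsv")
  write_spectra(set, f)
  back <- read_spectra(f)
  expect_equal(back$wavenumbers, set$wavenumbers)
  expect_equal(back$values, set$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$meta$spectrum_id, c("a", "b"))
})
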