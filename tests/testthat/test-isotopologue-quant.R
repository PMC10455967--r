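test_that("channel extraction assigns peaks by ppm window", {
  ec <- petrosamine_ec()
  sp <- centroid_spectrum(mz = 422.0499, intensity = 1000, time_s = 0)
  expect_equal(as.numeric(extract_raw_intensities(sp, ec, 2, 10)),
               c(1000, 0, 0))
  sp2 <- centroid_spectrum(mz = c(422.0499, 424.0624),
                           intensity = c(800, 200), time_s = 0)
  expect_equal(as.numeric(extract_raw_intensities(sp2, ec, 2, 10)),
               c(800, 0, 200))
  # 26 ppm away is outside a 10 ppm window -> flagged, no exception
  sp3 <- centroid_spectrum(mz = 422.060, intensity = 500, time_s = 0)
  raw <- extract_raw_intensities(sp3, ec, 2, 10)
  expect_equal(as.numeric(raw), c(0, 0, 0))
  expect_true(attr(raw, "no_signal"))
})

test_that("correction matrix is triangular with conserved columns", {
  M <- build_correction_matrix(petrosamine_ec(), 2)
  expect_true(all(M[upper.tri(M)] == 0))
  expect_true(all(colSums(M) <= 1 + 1e-12))
  expect_true(all(diag(M) > 0))
  expect_equal(unname(colSums(M) + attr(M, "loss")), rep(1, 3),
               tolerance = 1e-9)
})

test_that("the d0 satellite landing in the d1 channel matches the M+1 oracle", {
  # independent hand computation: sum over elements of n * p_heavy/p_light
  # for the one-neutron-heavier isotopes (13C, 15N, 2H, 17O)
  tab <- isotope_table()
  r <- function(el, a, b) {
    tab$abundance[tab$element == el & tab$isotope == b] /
      tab$abundance[tab$element == el & tab$isotope == a]
  }
  expected <- 21 * r("C", 12, 13) + 3 * r("N", 14, 15) +
    17 * r("H", 1, 2) + 2 * r("O", 16, 17)
  M <- build_correction_matrix(petrosamine_ec(), 2)
  expect_equal(M[2, 1] / M[1, 1], expected, tolerance = 1e-6)
  expect_equal(M[2, 1] / M[1, 1], 0.2408, tolerance = 1e-3)
})

test_that("a bromine- and carbon-free species needs no correction", {
  ec <- parse_formula("P5H2", charge = 1)
  M <- build_correction_matrix(ec, 2, resolving_power = 1e6,
                               abundance_floor = 1e-3)
  expect_equal(matrix(M, 3, 3), diag(3), tolerance = 1e-3)
})

test_that("channels below instrument resolution are rejected", {
  expect_error(build_correction_matrix(petrosamine_ec(), 2,
                                       resolving_power = 100),
               "indistinguishable")
})

test_that("fraction correction inverts the convolution exactly", {
  M <- build_correction_matrix(petrosamine_ec(), 2)
  x <- c(0.2, 0.3, 0.5)
  res <- correct_fractions(as.numeric(M %*% x), M)
  expect_equal(unname(res$fractions), x, tolerance = 1e-10)
  expect_identical(res$flag, "ok")
  # pure d0 presents its own satellite pattern and must deconvolve to d0
  res0 <- correct_fractions(as.numeric(M[, 1]), M)
  expect_equal(unname(res0$fractions), c(1, 0, 0), tolerance = 1e-10)
})

test_that("round trip recovers random noiseless compositions", {
  M <- build_correction_matrix(petrosamine_ec(), 2)
  set.seed(42)
  for (i in 1:25) {
    x <- stats::runif(3)
    x <- x / sum(x)
    res <- correct_fractions(as.numeric(M %*% x), M)
    expect_equal(unname(res$fractions), x, tolerance = 1e-9)
    expect_true(all(res$fractions >= 0))
    expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
  }
})

test_that("negative solutions are clipped, renormalized and flagged", {
  M <- build_correction_matrix(petrosamine_ec(), 2)
  raw <- as.numeric(M %*% c(0.9, 0.1, 0))
  raw[2] <- raw[2] * 0.3  # distort so the solve goes negative
  res <- correct_fractions(raw, M)
  expect_true(all(res$fractions >= 0))
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
  expect_true(any(res$amounts < 0))
  expect_identical(res$flag, "clipped")
  # all-zero input is a flagged no-signal result, not an error
  resz <- correct_fractions(c(0, 0, 0), M)
  expect_identical(resz$flag, "no_signal")
})

test_that("reference normalization rescales intensities but not fractions", {
  cfg <- sim_config(noise_cv = 0, n_replicates = 1)
  sp <- simulate_time_course(cfg)
  ser <- correct_time_series(sp, cfg$ec, abundance_floor = cfg$abundance_floor)
  out <- normalize_to_reference(ser, 200)
  expect_equal(out$f_d0, ser$f_d0)
  expect_equal(out$raw_d0, ser$raw_d0 / 200)
  expect_error(normalize_to_reference(ser, 0), "positive")
  expect_error(normalize_to_reference(ser, -5), "positive")
})

test_that("peak-list and fraction CSV dialects round-trip", {
  cfg <- sim_config(n_replicates = 2, seed = 5)
  sp <- simulate_time_course(cfg)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_peaks_csv(sp, f1)
  sp2 <- read_peaks_csv(f1)
  expect_length(sp2, length(sp))
  ser <- correct_time_series(sp2, cfg$ec, abundance_floor = cfg$abundance_floor)
  write_fractions_csv(ser, f2)
  ser2 <- read_fractions_csv(f2)
  expect_equal(ser2$f_d1, ser$f_d1, tolerance = 1e-6)
})
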