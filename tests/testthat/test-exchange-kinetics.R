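test_that("closed-form fractions satisfy boundary and degenerate cases", {
  m0 <- model_fractions(0.2, 0.1, 0)
  expect_equal(as.numeric(m0[, c("f_d0", "f_d1", "f_d2")]), c(1, 0, 0))
  # table rate constants give near-complete exchange inside 90 s
  expect_gt(model_fractions(0.1311, 0.0755, 90)$f_d2, 0.90)
  # degenerate k1 = k2 limit
  expect_equal(model_fractions(0.1, 0.1, 10)$f_d1, exp(-1), tolerance = 1e-12)
  expect_error(model_fractions(0.1, 0.1, -1), "negative time")
})

test_that("closed form matches a Runge-Kutta oracle over a rate/time grid", {
  times <- seq(0, 300, by = 5)
  worst <- 0
  for (k1 in c(1e-3, 0.0755, 0.1311, 1)) {
    for (k2 in c(1e-3, 0.0755, 0.1311, 1)) {
      m <- model_fractions(k1, k2, times)
      o <- ode_fractions(k1, k2, times)
      worst <- max(worst, max(abs(as.matrix(m[, 2:4]) - as.matrix(o[, 2:4]))))
    }
  }
  expect_lt(worst, 1e-8)
})

test_that("fractions conserve mass and have the expected shapes", {
  t <- seq(0, 300, by = 1.5)
  for (ks in list(c(0.1311, 0.0755), c(0.5, 0.01), c(0.02, 0.3))) {
    m <- model_fractions(ks[1], ks[2], t)
    expect_lt(max(abs(m$f_d0 + m$f_d1 + m$f_d2 - 1)), 1e-12)
    expect_true(all(diff(m$f_d0) < 0))
    expect_true(all(diff(m$f_d2) > 0))
    # unimodal intermediate with the analytic maximum
    t_star <- d1_peak_time(ks[1], ks[2])
    i_max <- which.max(m$f_d1)
    expect_lt(abs(m$time_s[i_max] - t_star), 1.5)
    fine <- model_fractions(ks[1], ks[2],
                            c(t_star - 1e-4, t_star, t_star + 1e-4))
    expect_gte(fine$f_d1[2], fine$f_d1[1])
    expect_gte(fine$f_d1[2], fine$f_d1[3])
  }
})

test_that("swapping the rate constants leaves f_d2 invariant", {
  t <- seq(0, 200, by = 2.5)
  a <- model_fractions(0.1311, 0.0755, t)
  b <- model_fractions(0.0755, 0.1311, t)
  expect_equal(a$f_d2, b$f_d2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(a$f_d0, b$f_d0)))
})

test_that("half-exchange time matches brute force and scales with rate", {
  t_half <- half_exchange_time(0.1311, 0.0755)
  grid <- seq(0, 120, by = 1e-3)
  f2 <- model_fractions(0.1311, 0.0755, grid)$f_d2
  expect_lt(abs(t_half - grid[which(f2 >= 0.5)[1]]), 2e-3)
  # k1 = k2: root of 1 - e^{-kt}(1 + kt) = 0.5
  k <- 0.1
  root <- stats::uniroot(function(t) 1 - exp(-k * t) * (1 + k * t) - 0.5,
                         c(0, 100), tol = 1e-9)$root
  expect_equal(half_exchange_time(k, k), root, tolerance = 1e-5)
  # doubling both rates halves the time
  expect_equal(half_exchange_time(0.2622, 0.151),
               half_exchange_time(0.1311, 0.0755) / 2, tolerance = 1e-5)
})

test_that("noiseless synthetic series are refit to well under 0.1%", {
  truth <- model_fractions(0.1311, 0.0755, seq(0, 90, 15))
  series <- do.call(rbind, lapply(1:3, function(r) {
    cbind(truth, replicate_id = paste0("rep", r))
  }))
  fit <- fit_exchange(series)
  expect_lt(abs(fit$k1 - 0.1311) / 0.1311, 1e-3)
  expect_lt(abs(fit$k2 - 0.0755) / 0.0755, 1e-3)
  expect_gt(fit$r_squared, 0.999999)
  expect_false(fit$boundary)
  expect_false(fit$swapped)
  expect_true(fit$ci_k1[1] <= fit$k1 && fit$k1 <= fit$ci_k1[2])
  expect_true(fit$ci_k2[1] <= fit$k2 && fit$k2 <= fit$ci_k2[2])
})

test_that("a series without exchange hits the bound and is flagged", {
  flat <- data.frame(time_s = seq(0, 90, 15), f_d0 = 1, f_d1 = 0, f_d2 = 0)
  expect_warning(fit <- fit_exchange(flat), "bound")
  expect_true(fit$boundary)
})

test_that("too few distinct timepoints are rejected", {
  short <- model_fractions(0.1, 0.05, c(0, 15, 30))
  expect_error(fit_exchange(short), "4 distinct timepoints")
})

test_that("ratio test propagates uncertainty and flags the statistical factor", {
  truth <- model_fractions(0.1311, 0.0755, seq(0, 90, 15))
  fit <- fit_exchange(truth)
  rt <- ratio_test(fit)
  expect_equal(rt$ratio, 0.1311 / 0.0755, tolerance = 1e-3)
  expect_gt(rt$ratio, 0)
  # exact 2:1 rates with zero uncertainty are consistent by identity
  exact <- statistical_factor_consistency(2, 0)
  expect_true(exact$consistent)
  # the reported ratio with its printed sigma spans the statistical factor
  wide <- statistical_factor_consistency(1.74, 0.94)
  expect_true(wide$consistent)
  narrow <- statistical_factor_consistency(1.74, 0.01)
  expect_false(narrow$consistent)
})
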