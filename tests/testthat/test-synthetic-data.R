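test_that("simulation is deterministic in the seed and sensitive to it", {
  cfg <- sim_config(seed = 11)
  a <- simulate_time_course(cfg)
  b <- simulate_time_course(cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(seed = 12)
  c <- simulate_time_course(cfg2)
  expect_false(identical(a, c))
})

test_that("at t = 0 the noiseless spectrum is the pure d0 isotope pattern", {
  cfg <- sim_config(noise_cv = 0, n_replicates = 1)
  sp <- simulate_time_course(cfg)[[1]]
  expect_equal(attr(sp, "time_s"), 0)
  pat <- cfg$patterns[[1]]
  # exactly the d0 pattern, scaled; its monoisotopic peak sits at 422.0499
  expect_equal(sp$intensity / sum(sp$intensity), pat$abundance,
               tolerance = 1e-12)
  expect_equal(sp$mz[1], 422.0499, tolerance = 2e-4 / 422)
  expect_equal(sp$mz, pat$mz)
})

test_that("noiseless total ion intensity is conserved over the time course", {
  cfg <- sim_config(noise_cv = 0, n_replicates = 1)
  totals <- vapply(simulate_time_course(cfg),
                   function(sp) sum(sp$intensity), numeric(1))
  expect_lt(max(abs(totals / totals[1] - 1)), 1e-9)
})

test_that("generated fractions equal the kinetic model before noise", {
  cfg <- sim_config(noise_cv = 0, n_replicates = 1)
  truth <- attr(simulate_time_course(cfg), "true_fractions")
  expect_equal(truth[, c("f_d0", "f_d1", "f_d2")],
               model_fractions(cfg$k1, cfg$k2, cfg$t_grid)[
                 , c("f_d0", "f_d1", "f_d2")])
})

test_that("the zero-noise pipeline returns the generating rates to < 0.1%", {
  cfg <- sim_config(noise_cv = 0)
  sp <- simulate_time_course(cfg)
  ser <- correct_time_series(sp, cfg$ec, max_d = 2,
                             resolving_power = cfg$resolving_power,
                             abundance_floor = cfg$abundance_floor)
  truth <- attr(sp, "true_fractions")
  one_rep <- ser[ser$replicate_id == "rep1", ]
  expect_lt(max(abs(one_rep$f_d0 - truth$f_d0)), 1e-6)
  expect_lt(max(abs(one_rep$f_d1 - truth$f_d1)), 1e-6)
  expect_lt(max(abs(one_rep$f_d2 - truth$f_d2)), 1e-6)
  fit <- fit_exchange(ser)
  expect_lt(abs(fit$k1 - cfg$k1) / cfg$k1, 1e-3)
  expect_lt(abs(fit$k2 - cfg$k2) / cfg$k2, 1e-3)
})

test_that("dead time shifts the kinetic clock of every sample", {
  cfg0 <- sim_config(noise_cv = 0, n_replicates = 1)
  cfgd <- sim_config(noise_cv = 0, n_replicates = 1, dead_time_s = 5)
  t0 <- attr(simulate_time_course(cfg0), "true_fractions")
  td <- attr(simulate_time_course(cfgd), "true_fractions")
  expect_lt(td$f_d0[1], t0$f_d0[1])
  expect_equal(td$f_d0[1], model_fractions(cfg0$k1, cfg0$k2, 5)$f_d0)
})

test_that("replicate substreams are order-independent", {
  cfg <- sim_config(seed = 3, n_replicates = 3)
  all3 <- simulate_time_course(cfg)
  cfg1 <- sim_config(seed = 3, n_replicates = 1)
  first <- simulate_time_course(cfg1)
  n_t <- length(cfg$t_grid)
  for (i in seq_len(n_t)) {
    expect_equal(all3[[i]]$intensity, first[[i]]$intensity)
  }
})
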