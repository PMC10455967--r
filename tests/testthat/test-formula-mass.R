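test_that("Hill-notation formulas parse to element counts", {
  ec <- parse_formula("C21H17BrN3O2", charge = 1)
  expect_equal(ec$counts, c(C = 21L, H = 17L, Br = 1L, N = 3L, O = 2L))
  expect_identical(ec$charge, 1L)
  expect_equal(parse_formula("H2O")$counts, c(H = 2L, O = 1L))
  expect_error(parse_formula("C0H2"), "zero atom count")
  expect_error(parse_formula("Xq3"), "unknown element")
  expect_error(parse_formula("C2!"), "cannot parse")
  expect_error(parse_formula("C21H17BrN3O2", n_labile = 18), "n_labile")
})

test_that("monoisotopic m/z reproduces the printed petrosamine cation values", {
  ec <- petrosamine_ec()
  expect_equal(monoisotopic_mz(ec, n_labile = 0), 422.0499, tolerance = 2e-4 / 422)
  expect_equal(monoisotopic_mz(ec, n_labile = 1), 423.0561, tolerance = 2e-4 / 423)
  expect_equal(monoisotopic_mz(ec, n_labile = 2), 424.0624, tolerance = 2e-4 / 424)
  # neutral species: no electron correction, hand-summed 1H/16O masses
  expect_equal(monoisotopic_mz(parse_formula("H2O")), 18.010565, tolerance = 1e-5 / 18)
})

test_that("each deuterium substitution adds exactly m(D) - m(1H)", {
  ec <- petrosamine_ec()
  tab <- isotope_table()
  dm <- tab$mass_da[tab$element == "H" & tab$isotope == 2] -
    tab$mass_da[tab$element == "H" & tab$isotope == 1]
  for (n in 0:1) {
    expect_equal(monoisotopic_mz(ec, n + 1) - monoisotopic_mz(ec, n), dm,
                 tolerance = 1e-12)
  }
  expect_equal(dm, 1.006277, tolerance = 1e-6)
})

test_that("single-element patterns match pinned natural abundances", {
  br <- isotope_pattern(parse_formula("Br1"), resolving_power = Inf)
  expect_equal(nrow(br), 2L)
  expect_equal(br$abundance, c(0.5069, 0.4931), tolerance = 1e-9)
  cc <- isotope_pattern(parse_formula("C1"), resolving_power = Inf)
  expect_equal(cc$abundance, c(0.9893, 0.0107), tolerance = 1e-9)
  hh <- isotope_pattern(parse_formula("H1"), resolving_power = 1e6)
  expect_gte(hh$abundance[1], 0.9998)
})

test_that("pattern invariants hold: normalization, ordering, positivity", {
  cases <- list(
    isotope_pattern(petrosamine_ec(), 20000, 1e-4),
    isotope_pattern(parse_formula("C6H12O6"), Inf, 0),
    isotope_pattern(parse_formula("C21H17BrN3O2", charge = 1, n_labile = 2),
                    20000, 1e-6)
  )
  for (pat in cases) {
    expect_equal(sum(pat$abundance), 1, tolerance = 1e-9)
    expect_true(all(diff(pat$mz) > 0))
    expect_true(all(pat$abundance >= 0))
  }
})

test_that("convolution pattern equals brute-force enumeration for small formulas", {
  for (f in list(parse_formula("C2H3BrO"),
                 parse_formula("C3H4Cl2"),
                 parse_formula("C2H2O2", charge = 1, n_labile = 1))) {
    pat <- isotope_pattern(f, resolving_power = Inf, abundance_floor = 0)
    oracle <- pattern_oracle(f)
    # compare above a common floor: the convolution prunes products below
    # 1e-14, the oracle keeps everything
    pat <- pat[pat$abundance > 1e-12, ]
    oracle <- oracle[oracle$abundance > 1e-12, ]
    expect_equal(nrow(pat), nrow(oracle))
    expect_lt(max(abs(pat$mz - oracle$mz)), 1e-8)
    expect_lt(max(abs(pat$abundance - oracle$abundance)), 1e-10)
  }
})

test_that("finite resolving power merges unresolved fine structure", {
  full <- isotope_pattern(petrosamine_ec(), Inf, 1e-8)
  merged <- isotope_pattern(petrosamine_ec(), 20000, 1e-8)
  expect_lt(nrow(merged), nrow(full))
  # the M+1 region collapses to a single centroid at TOF resolution
  m1 <- merged[merged$mz > 422.5 & merged$mz < 423.5, ]
  expect_equal(nrow(m1), 1L)
})
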