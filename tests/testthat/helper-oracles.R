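# Independent oracles used across the test files.

# Brute-force isotope pattern: enumerate every atom-by-atom isotope
# assignment (feasible for <= 10 atoms), multiply abundances, and
# aggregate exactly equal masses. Independent of the package's
# multinomial-convolution path.
pattern_oracle <- function(ec) {
  counts <- petrokin:::.effective_counts(ec)
  atoms <- rep(names(counts), counts)
  iso <- lapply(atoms, petrokin:::.element_isotopes)
  grid <- do.call(expand.grid, lapply(iso, function(d) seq_len(nrow(d))))
  mass <- rowSums(mapply(function(d, idx) d$mass_da[idx], iso, grid))
  ab <- apply(mapply(function(d, idx) d$abundance[idx], iso, grid), 1, prod)
  mz <- petrokin:::.neutral_to_mz(mass, ec$charge)
  key <- sprintf("%.9f", mz)
  agg <- tapply(ab, key, sum)
  out <- data.frame(mz = as.numeric(names(agg)), abundance = as.numeric(agg))
  out[order(out$mz), ]
}

# Runge-Kutta integration of the consecutive first-order system, as an
# oracle for the closed-form fractions.
ode_fractions <- function(k1, k2, times) {
  rhs <- function(t, y, parms) {
    list(c(-parms[1] * y[1], parms[1] * y[1] - parms[2] * y[2]))
  }
  sol <- deSolve::ode(y = c(f0 = 1, f1 = 0), times = times, func = rhs,
                      parms = c(k1, k2), method = "ode45",
                      rtol = 1e-11, atol = 1e-12)
  data.frame(time_s = sol[, "time"], f_d0 = sol[, "f0"], f_d1 = sol[, "f1"],
             f_d2 = 1 - sol[, "f0"] - sol[, "f1"])
}

petrosamine_ec <- function() parse_formula("C21H17BrN3O2", charge = 1)
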