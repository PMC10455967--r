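# Sequential first-order H/D exchange: d0 -k1-> d1 -k2-> d2.
#
# Closed form of the consecutive-reaction system with f_d0(0) = 1:
#   f_d0 = exp(-k1 t)
#   f_d1 = k1/(k2-k1) (exp(-k1 t) - exp(-k2 t))   (k1 t exp(-k1 t) at k1=k2)
#   f_d2 = 1 - f_d0 - f_d1
# The difference of exponentials is evaluated via expm1 to avoid
# cancellation when k1 and k2 are close.

# Relative threshold below which the degenerate (k1 = k2) limit is used.
.DEGENERACY_EPS <- 1e-9

#' Isotopologue fractions under the sequential two-site exchange model
#'
#' Evaluates the closed-form solution of the consecutive first-order scheme
#' d0 -> d1 -> d2 with rate constants `k1` and `k2`, starting from pure d0.
#'
#' @param k1 First exchange rate constant (s^-1), > 0.
#' @param k2 Second exchange rate constant (s^-1), > 0.
#' @param t Time(s) since dissolution, seconds, >= 0 (vectorized).
#' @return data.frame with columns `time_s`, `f_d0`, `f_d1`, `f_d2`; each
#'   row sums to 1.
#' @export
#' @examples
#' model_fractions(0.1311, 0.0755, seq(0, 90, 15))
model_fractions <- function(k1, k2, t) {
  stopifnot(is.numeric(k1), is.numeric(k2), k1 > 0, k2 > 0)
  if (any(t < 0)) stop("negative time", call. = FALSE)
  f0 <- exp(-k1 * t)
  delta <- k2 - k1
  if (abs(delta) < .DEGENERACY_EPS * max(k1, k2)) {
    f1 <- k1 * t * exp(-k1 * t)
  } else {
    # k1/(k2-k1) (e^{-k1 t} - e^{-k2 t}) = -k1/delta e^{-k1 t} expm1(-delta t)
    f1 <- -(k1 / delta) * f0 * expm1(-delta * t)
  }
  f2 <- pmax(0, 1 - f0 - f1)
  data.frame(time_s = t, f_d0 = f0, f_d1 = f1, f_d2 = f2)
}

#' Time of maximal d1 population
#'
#' Analytic maximum of the intermediate trajectory,
#' t* = ln(k1/k2) / (k1 - k2), with limit 1/k at k1 = k2.
#'
#' @inheritParams model_fractions
#' @return t* in seconds.
#' @export
d1_peak_time <- function(k1, k2) {
  stopifnot(k1 > 0, k2 > 0)
  if (abs(k2 - k1) < .DEGENERACY_EPS * max(k1, k2)) return(1 / k1)
  log(k1 / k2) / (k1 - k2)
}

#' Time to 50% complete exchange
#'
#' Smallest t with f_d2(t) >= 0.5, found by root bisection to the requested
#' tolerance (a root exists and is unique for positive rates).
#'
#' @inheritParams model_fractions
#' @param tol Absolute tolerance on t in seconds (default 1e-6).
#' @return Half-exchange time in seconds.
#' @export
half_exchange_time <- function(k1, k2, tol = 1e-6) {
  stopifnot(k1 > 0, k2 > 0)
  f <- function(t) model_fractions(k1, k2, t)$f_d2 - 0.5
  upper <- 1 / min(k1, k2)
  while (f(upper) < 0) upper <- upper * 2
  stats::uniroot(f, lower = 0, upper = upper, tol = tol)$root
}

# Stacked residuals of all three fraction trajectories.
.exchange_residuals <- function(par, data) {
  m <- model_fractions(par[[1]], par[[2]], data$time_s)
  c(data$f_d0 - m$f_d0, data$f_d1 - m$f_d1, data$f_d2 - m$f_d2)
}

# Numerical Jacobian of the residual vector by central differences.
.residual_jacobian <- function(par, data) {
  J <- matrix(0, nrow = 3L * nrow(data), ncol = 2L)
  for (p in 1:2) {
    h <- max(1e-7, 1e-7 * abs(par[[p]]))
    up <- par; up[[p]] <- par[[p]] + h
    dn <- par; dn[[p]] <- par[[p]] - h
    J[, p] <- (.exchange_residuals(up, data) -
                 .exchange_residuals(dn, data)) / (2 * h)
  }
  J
}

#' Fit the sequential exchange model to isotopologue fraction time courses
#'
#' Unweighted least squares over all three fraction trajectories
#' simultaneously, with all replicates pooled, via Levenberg-Marquardt
#' ([minpack.lm::nls.lm]). Confidence intervals are t-based Wald intervals
#' from the Jacobian covariance at the optimum, with two refinements that
#' keep them calibrated on compositional data: residual degrees of freedom
#' are counted as two per spectrum (the three fractions of one spectrum sum
#' to one, so their residuals are linearly dependent), and the reported
#' standard error of each rate is the wider of the pooled-variance estimate
#' and a cluster-robust (by spectrum) sandwich estimate, since fraction
#' errors are correlated within a spectrum and heteroscedastic across the
#' time course. Initialization: k1 from a
#' log-linear regression of f_d0 against time, k2 = k1/2 (the statistical
#' factor expected for two equivalent sites); k1 >= k2 is imposed at
#' initialization only, and a fit that crosses is reported with
#' `swapped = TRUE` rather than forced back.
#'
#' @param series An `isotopologue_series` (or any data.frame with columns
#'   `time_s`, `f_d0`, `f_d1`, `f_d2` and optionally `replicate_id`).
#' @param init Optional numeric `c(k1, k2)` starting values; `NULL` for the
#'   automatic initializer.
#' @param lower,upper Box bounds on both rate constants (s^-1).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return An `exchange_fit` list: `k1`, `k2`, `ci_k1`, `ci_k2`, `vcov`,
#'   `ratio`, `ratio_sigma`, `r_squared`, `n_obs`, `n_timepoints`,
#'   `n_replicates`, `boundary`, `swapped`, `deviance`, `niter`.
#' @export
fit_exchange <- function(series, init = NULL, lower = 1e-6, upper = 10,
                         conf_level = 0.95) {
  data <- as.data.frame(series)
  need <- c("time_s", "f_d0", "f_d1", "f_d2")
  stopifnot(all(need %in% names(data)))
  data <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  if (length(unique(data$time_s)) < 4L) {
    stop("need at least 4 distinct timepoints pooled across replicates",
         call. = FALSE)
  }
  if (is.null(init)) {
    usable <- data$f_d0 > 0.01 & data$f_d0 < 0.999
    if (sum(usable) >= 2L && length(unique(data$time_s[usable])) >= 2L) {
      sl <- stats::coef(stats::lm(log(f_d0) ~ time_s,
                                  data = data[usable, ]))[["time_s"]]
      k1_0 <- min(max(-sl, lower * 10), upper / 2)
    } else {
      k1_0 <- 0.1
    }
    init <- c(k1 = k1_0, k2 = k1_0 / 2)
  }
  init <- pmin(pmax(init, lower * 1.01), upper * 0.99)
  fit <- minpack.lm::nls.lm(
    par = c(k1 = init[[1]], k2 = init[[2]]),
    lower = rep(lower, 2), upper = rep(upper, 2),
    fn = .exchange_residuals, data = data,
    control = minpack.lm::nls.lm.control(maxiter = 500)
  )
  if (!(fit$info %in% 1:4)) {
    stop(sprintf(
      "exchange fit did not converge (info %d, deviance %.4g, %d iterations)",
      fit$info, fit$deviance, fit$niter), call. = FALSE)
  }
  par <- fit$par
  n_res <- 3L * nrow(data)
  m <- nrow(data)
  # Fractions are compositional: the three residuals of one spectrum sum to
  # zero identically, so each spectrum contributes 2, not 3, residual
  # degrees of freedom.
  df_res <- 2L * m - 2L
  sigma2 <- fit$deviance / df_res
  J <- .residual_jacobian(par, data)
  bread <- solve(crossprod(J))
  vcov_iid <- sigma2 * bread
  # Cluster-robust (by spectrum) covariance: fraction errors within one
  # spectrum are correlated and heteroscedastic across timepoints, which
  # the pooled-variance estimate misallocates between the two rates.
  resid <- fit$fvec
  meat <- matrix(0, 2, 2)
  for (s in seq_len(m)) {
    idx <- c(s, s + m, s + 2L * m)
    g <- crossprod(J[idx, , drop = FALSE], resid[idx])
    meat <- meat + tcrossprod(g)
  }
  vcov_cluster <- bread %*% meat %*% bread * m / (m - 2)
  dimnames(vcov_iid) <- dimnames(vcov_cluster) <-
    list(c("k1", "k2"), c("k1", "k2"))
  # conservative interval: the wider of the two standard errors per rate
  se <- pmax(sqrt(diag(vcov_iid)), sqrt(diag(vcov_cluster)))
  vcov <- if (sum(diag(vcov_cluster)) > sum(diag(vcov_iid)))
    vcov_cluster else vcov_iid
  tq <- stats::qt(1 - (1 - conf_level) / 2, df_res)
  y <- c(data$f_d0, data$f_d1, data$f_d2)
  r2 <- 1 - fit$deviance / sum((y - mean(y))^2)
  boundary <- any(par <= lower * 1.001) || any(par >= upper * 0.999)
  if (boundary) {
    warning("estimate at parameter bound; rate constants not identified ",
            "from these data", call. = FALSE)
  }
  ratio <- par[["k1"]] / par[["k2"]]
  # first-order (delta-method) propagation for k1/k2, from the wider of the
  # two covariance estimates
  prop_sigma <- function(V) {
    ratio * sqrt(V["k1", "k1"] / par[["k1"]]^2 +
                   V["k2", "k2"] / par[["k2"]]^2 -
                   2 * V["k1", "k2"] / (par[["k1"]] * par[["k2"]]))
  }
  ratio_sigma <- max(prop_sigma(vcov_iid), prop_sigma(vcov_cluster))
  structure(list(
    k1 = par[["k1"]], k2 = par[["k2"]],
    ci_k1 = c(par[["k1"]] - tq * se[["k1"]], par[["k1"]] + tq * se[["k1"]]),
    ci_k2 = c(par[["k2"]] - tq * se[["k2"]], par[["k2"]] + tq * se[["k2"]]),
    se = se, vcov = vcov, vcov_iid = vcov_iid,
    vcov_cluster = vcov_cluster, conf_level = conf_level,
    ratio = ratio, ratio_sigma = ratio_sigma,
    r_squared = r2, deviance = fit$deviance, niter = fit$niter,
    n_obs = n_res, df_residual = df_res,
    n_timepoints = length(unique(data$time_s)),
    n_replicates = if ("replicate_id" %in% names(data))
      length(unique(data$replicate_id)) else 1L,
    boundary = boundary, swapped = par[["k1"]] < par[["k2"]]
  ), class = "exchange_fit")
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat("Sequential H/D exchange fit (d0 -> d1 -> d2)\n")
  cat(sprintf("  k1 = %.4f s^-1  %g%% CI [%.4f, %.4f]\n",
              x$k1, 100 * x$conf_level, x$ci_k1[1], x$ci_k1[2]))
  cat(sprintf("  k2 = %.4f s^-1  %g%% CI [%.4f, %.4f]\n",
              x$k2, 100 * x$conf_level, x$ci_k2[1], x$ci_k2[2]))
  cat(sprintf("  k1/k2 = %.3f (sigma %.3f),  R^2 = %.4f\n",
              x$ratio, x$ratio_sigma, x$r_squared))
  cat(sprintf("  %d observations, %d timepoints, %d replicate(s)\n",
              x$n_obs, x$n_timepoints, x$n_replicates))
  if (x$boundary) cat("  WARNING: estimate at parameter bound\n")
  if (x$swapped) cat("  note: fitted k1 < k2 (label-swapped solution)\n")
  invisible(x)
}

#' Consistency of a rate-constant ratio with the statistical factor
#'
#' For two equivalent exchangeable sites with no primary kinetic isotope
#' effect the macroscopic first step is twice as fast as the second, so
#' k1/k2 = 2. The ratio is deemed consistent when the interval
#' ratio +- z * sigma contains the statistical factor.
#'
#' @param ratio Point estimate of k1/k2.
#' @param sigma Its propagated standard uncertainty.
#' @param statistical_factor Expected ratio (default 2).
#' @param z Normal quantile for the interval (default 1.96, i.e. 95%).
#' @return List with `consistent` (logical) and `interval`.
#' @export
statistical_factor_consistency <- function(ratio, sigma,
                                           statistical_factor = 2,
                                           z = 1.96) {
  stopifnot(ratio > 0, sigma >= 0)
  interval <- c(ratio - z * sigma, ratio + z * sigma)
  list(consistent = interval[1] <= statistical_factor &&
         statistical_factor <= interval[2],
       interval = interval)
}

#' Statistical-factor ratio test on a fitted exchange model
#'
#' Computes k1/k2 with first-order uncertainty propagation from the fit
#' covariance and tests whether the 95% interval contains the statistical
#' factor of 2 expected for two equivalent sites (deviation would indicate
#' a primary kinetic isotope effect or site inequivalence).
#'
#' @param fit An `exchange_fit` from [fit_exchange()].
#' @param statistical_factor Expected ratio under the null (default 2).
#' @return List with `ratio`, `sigma`, `interval`,
#'   `consistent_with_statistical_factor`.
#' @export
ratio_test <- function(fit, statistical_factor = 2) {
  stopifnot(inherits(fit, "exchange_fit"))
  if (fit$k2 <= 0) stop("non-positive k2", call. = FALSE)
  cons <- statistical_factor_consistency(fit$ratio, fit$ratio_sigma,
                                         statistical_factor)
  list(ratio = fit$ratio, sigma = fit$ratio_sigma,
       interval = cons$interval,
       consistent_with_statistical_factor = cons$consistent)
}
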