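# Phosphopeptide-dependent phosphatase activation: EC50 curve fitting,
# Kd-EC50 correlation, and basal catalytic-efficiency folds.

#' Construct an activation dataset
#'
#' Initial phosphatase rates measured at increasing activator (phosphopeptide)
#' concentrations; the zero-activator point anchors the basal rate.
#'
#' @param concentration Activator concentrations, uM (>= 0).
#' @param rate Initial rates (signal per second).
#' @param peptide_label Activating peptide name.
#' @param enzyme_label Enzyme variant name.
#' @param replicate Replicate label.
#' @return An object of class `activation_dataset`.
#' @export
activation_dataset <- function(concentration, rate, peptide_label = "peptide",
                               enzyme_label = "enzyme", replicate = "rep1") {
  stopifnot(length(concentration) == length(rate), all(concentration >= 0))
  if (!any(concentration == 0)) {
    warning("no zero-activator point; the basal rate is extrapolated")
  }
  structure(
    list(concentration = concentration, rate = rate,
         peptide_label = peptide_label, enzyme_label = enzyme_label,
         replicate = replicate),
    class = "activation_dataset")
}

#' Hyperbolic (optionally Hill) activation forward model
#'
#' `rate(c) = basal + (max - basal) * c^n / (EC50^n + c^n)`; at `c = EC50`
#' the rate is the midpoint of basal and maximal rates for `n = 1`.
#'
#' @param concentration Activator concentrations, uM.
#' @param basal,max Basal and maximal rates.
#' @param ec50 Half-maximal activation concentration, uM (> 0).
#' @param hill_n Hill coefficient, default 1.
#' @return Numeric rates.
#' @export
activation_rate <- function(concentration, basal, max, ec50, hill_n = 1) {
  stopifnot(all(concentration >= 0), ec50 > 0, hill_n > 0)
  cn <- concentration^hill_n
  basal + (max - basal) * cn / (ec50^hill_n + cn)
}

#' Fit an activation titration (EC50)
#'
#' Least-squares fit of [activation_rate()] over `{EC50, basal, max}` (plus
#' the Hill coefficient when `hill = TRUE`). EC50 is log-parameterised and
#' profiled over the exactly solved linear rate endpoints (global grid plus
#' golden-section refinement; Nelder-Mead over both nonlinear parameters in
#' Hill mode). The basal rate is a fitted parameter, not subtracted, so
#' zero-activator points inform it.
#'
#' @param ds An `activation_dataset` with at least 5 points spanning the
#'   transition.
#' @param hill Fit a Hill coefficient instead of fixing `n = 1`.
#' @return An `activation_fit`: list with `ec50`, `ec50_se`, `rate_basal`,
#'   `rate_max`, `hill_n`, `rss`, `converged`, `no_transition`, `n_points`.
#'   Degenerate inputs (all concentrations zero, or a flat response) set
#'   `no_transition = TRUE` and `converged = FALSE` rather than erroring.
#' @export
fit_activation <- function(ds, hill = FALSE) {
  stopifnot(inherits(ds, "activation_dataset"))
  conc <- ds$concentration; rate <- ds$rate
  flat <- stats::sd(rate) == 0 ||
    diff(range(rate)) <= 1e-9 * max(abs(rate), 1)
  if (all(conc == 0) || flat) {
    return(structure(
      list(ec50 = NA_real_, ec50_se = NA_real_, rate_basal = mean(rate),
           rate_max = mean(rate), hill_n = if (hill) NA_real_ else 1,
           rss = sum((rate - mean(rate))^2), converged = FALSE,
           no_transition = TRUE, n_points = length(rate)),
      class = "activation_fit"))
  }
  # variable projection: basal/max are linear, so only (log EC50[, log n])
  # is searched over the profiled residual sum of squares
  a <- min(rate); b <- diff(range(rate))
  y <- (rate - a) / b
  n_points <- length(rate)
  occ <- function(logec50, logn = 0) {
    n <- exp(logn)
    cn <- conc^n
    cn / (exp(logec50)^n + cn)
  }
  lin_solve <- function(m) {
    fit <- stats::lm.fit(cbind(1 - m, m), y)
    list(coef = stats::coef(fit), rss = sum(fit$residuals^2))
  }
  pos <- conc[conc > 0]
  grid <- seq(log(min(pos)) - 6, log(max(pos)) + 6, length.out = 80L)
  prss1 <- function(l) lin_solve(occ(l))$rss
  vals <- vapply(grid, prss1, numeric(1))
  i <- which.min(vals)
  opt <- stats::optimize(prss1, c(grid[max(i - 1L, 1L)],
                                  grid[min(i + 1L, length(grid))]),
                         tol = 1e-10)
  theta <- c(logec50 = .refine_min(prss1, opt$minimum), logn = 0)
  if (hill) {
    nm <- stats::optim(theta, function(p) lin_solve(occ(p[1L], p[2L]))$rss,
                       method = "Nelder-Mead",
                       control = list(reltol = 1e-14, maxit = 5000))
    theta <- nm$par
  }
  m <- occ(theta[1L], theta[2L])
  ls <- lin_solve(m)
  basal <- ls$coef[[1L]]; rmax <- ls$coef[[2L]]
  rss <- ls$rss

  # Gauss-Newton covariance at the optimum (numeric derivative in log EC50
  # and, in Hill mode, log n)
  h <- 1e-6
  d1 <- (occ(theta[1L] + h, theta[2L]) - occ(theta[1L] - h, theta[2L])) /
    (2 * h)
  J <- cbind((rmax - basal) * d1, 1 - m, m)
  if (hill) {
    d2 <- (occ(theta[1L], theta[2L] + h) - occ(theta[1L], theta[2L] - h)) /
      (2 * h)
    J <- cbind(J, (rmax - basal) * d2)
  }
  dof <- n_points - ncol(J)
  se <- rep(NA_real_, ncol(J))
  if (dof > 0) {
    cov <- tryCatch(rss / dof * solve(crossprod(J)), error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  ec50 <- exp(theta[[1L]])
  interior <- theta[[1L]] > grid[1L] + 1e-6 &&
    theta[[1L]] < grid[length(grid)] - 1e-6
  structure(
    list(ec50 = ec50, ec50_se = ec50 * se[1L],
         rate_basal = a + b * basal, rate_max = a + b * rmax,
         hill_n = if (hill) exp(theta[[2L]]) else 1,
         rss = rss * b^2,
         converged = is.finite(ec50) && abs(rmax - basal) > 0 && interior,
         no_transition = FALSE, n_points = n_points),
    class = "activation_fit")
}

#' @export
print.activation_fit <- function(x, ...) {
  cat(sprintf("activation_fit: EC50 = %.4g uM (SE %.2g), basal %.4g, max %.4g, n = %g, converged: %s\n",
              x$ec50, x$ec50_se, x$rate_basal, x$rate_max, x$hill_n,
              x$converged))
  invisible(x)
}

#' Correlation between binding affinity and activation potency
#'
#' Pearson correlation of `log10(EC50)` against `log10(Kd)`, with the slope
#' and intercept of the log-log regression. When one variable has zero
#' variance the correlation is undefined and reported as `NA`.
#'
#' @param kd Dissociation constants, uM (> 0).
#' @param ec50 Half-maximal activation concentrations, uM (> 0), aligned
#'   with `kd`.
#' @return List with `r`, `slope`, `intercept`, `n`, and `undefined` flag.
#' @export
kd_ec50_correlation <- function(kd, ec50) {
  stopifnot(length(kd) == length(ec50), length(kd) >= 3L,
            all(kd > 0), all(ec50 > 0))
  x <- log10(kd); y <- log10(ec50)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, slope = NA_real_, intercept = NA_real_,
                n = length(kd), undefined = TRUE))
  }
  fit <- stats::lm(y ~ x)
  list(r = stats::cor(x, y),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       n = length(kd), undefined = FALSE)
}

#' Basal catalytic-efficiency fold-change
#'
#' Ratio of kcat/Km values between an enzyme variant and the wild type.
#'
#' @param eff_variant,eff_wt Catalytic efficiencies (kcat/Km), same units,
#'   both > 0.
#' @return `eff_variant / eff_wt`.
#' @export
catalytic_fold <- function(eff_variant, eff_wt) {
  stopifnot(all(eff_variant > 0), all(eff_wt > 0))
  eff_variant / eff_wt
}
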