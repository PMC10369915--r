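# Fluorescence-polarization binding: exact ligand-depletion (direct) and
# ternary competitive equilibrium forward models, nonlinear least-squares
# fits with log-parameterised constants, and Kd fold-change statistics.

#' Bound probe fraction under the exact ligand-depletion model
#'
#' Solves the single-site equilibrium `R + L <-> RL` exactly (no
#' excess-receptor approximation):
#' `bound = ((R + L + Kd) - sqrt((R + L + Kd)^2 - 4 R L)) / 2`,
#' returned as a fraction of total probe. In the trace-probe limit
#' (`L -> 0`) this reduces to the hyperbola `R / (R + Kd)`.
#'
#' @param receptor_total Total receptor concentration(s), uM. Vectorised.
#' @param probe_total Total fluorescent probe concentration, uM.
#' @param kd Equilibrium dissociation constant, uM (> 0).
#' @return Bound fraction(s) in `[0, 1]`.
#' @export
bound_fraction_direct <- function(receptor_total, probe_total, kd) {
  stopifnot(all(receptor_total >= 0), probe_total >= 0, kd > 0)
  R <- receptor_total; L <- probe_total
  if (L == 0) return(R / (R + kd))
  s <- R + L + kd
  disc <- s * s - 4 * R * L
  stopifnot(all(disc >= -1e-12 * s * s))
  bound <- (s - sqrt(pmax(disc, 0))) / 2
  bound / L
}

#' Exact ternary competitive equilibrium
#'
#' Two ligands (fluorescent probe, dissociation constant `probe_kd`, and
#' unlabeled competitor, `competitor_ki`) compete for a single receptor
#' site. The free receptor concentration is the unique physical root of the
#' cubic
#' `F^3 + (Ka + Kb + A + B - R) F^2 + (Ka Kb + Kb (A - R) + Ka (B - R)) F - Ka Kb R = 0`
#' with `Ka = probe_kd`, `Kb = competitor_ki`, `A = probe_total`,
#' `B = competitor_total`, `R = receptor_total`. The root is polished by
#' Newton iteration and checked for mass balance to 1e-9 relative.
#'
#' @param receptor_total Total receptor, uM.
#' @param probe_total Total probe, uM.
#' @param competitor_total Total competitor, uM. Vectorised.
#' @param probe_kd Probe dissociation constant, uM (> 0).
#' @param competitor_ki Competitor dissociation constant, uM (> 0).
#' @return List with numeric vectors `free_receptor`, `probe_bound`, and
#'   `competitor_bound` (uM), aligned with `competitor_total`.
#' @export
free_species_competition <- function(receptor_total, probe_total,
                                     competitor_total, probe_kd,
                                     competitor_ki) {
  stopifnot(receptor_total >= 0, probe_total >= 0,
            all(competitor_total >= 0), probe_kd > 0, competitor_ki > 0)
  R <- receptor_total; A <- probe_total; Ka <- probe_kd; Kb <- competitor_ki
  n <- length(competitor_total)
  free_R <- numeric(n)
  cubic <- function(f, B) {
    f^3 + (Ka + Kb + A + B - R) * f^2 +
      (Ka * Kb + Kb * (A - R) + Ka * (B - R)) * f - Ka * Kb * R
  }
  dcubic <- function(f, B) {
    3 * f^2 + 2 * (Ka + Kb + A + B - R) * f +
      (Ka * Kb + Kb * (A - R) + Ka * (B - R))
  }
  for (i in seq_len(n)) {
    B <- competitor_total[i]
    if (R == 0) { free_R[i] <- 0; next }
    roots <- polyroot(c(-Ka * Kb * R,
                        Ka * Kb + Kb * (A - R) + Ka * (B - R),
                        Ka + Kb + A + B - R,
                        1))
    re <- Re(roots)[abs(Im(roots)) < 1e-8 * (abs(Re(roots)) + 1)]
    phys <- re[re > 0 & re <= R * (1 + 1e-9)]
    stopifnot(length(phys) >= 1L)   # a physical root always exists
    f <- min(phys)
    # Newton polish for tight mass-balance agreement
    for (it in 1:50) {
      step <- cubic(f, B) / dcubic(f, B)
      if (!is.finite(step)) break
      f_new <- f - step
      if (f_new <= 0) f_new <- f / 2
      if (abs(f_new - f) <= 1e-15 * max(f, 1e-300)) { f <- f_new; break }
      f <- f_new
    }
    free_R[i] <- min(f, R)
  }
  probe_bound <- A * free_R / (Ka + free_R)
  competitor_bound <- competitor_total * free_R / (Kb + free_R)
  resid <- abs(free_R + probe_bound + competitor_bound - R)
  stopifnot(all(resid <= 1e-9 * max(R, 1)))
  list(free_receptor = free_R, probe_bound = probe_bound,
       competitor_bound = competitor_bound)
}

#' Construct a titration dataset
#'
#' @param mode `"direct"` (titrant = receptor against fixed probe) or
#'   `"competition"` (titrant = unlabeled competitor against fixed
#'   receptor + probe).
#' @param concentration Titrant concentrations, uM.
#' @param signal Polarization signal at each concentration.
#' @param probe_total Fixed probe concentration, uM.
#' @param receptor_total Fixed receptor concentration, uM (competition only).
#' @param probe_kd Probe dissociation constant from a prior direct fit, uM
#'   (competition only).
#' @param replicate Replicate label.
#' @return An object of class `titration_dataset`.
#' @export
titration_dataset <- function(mode = c("direct", "competition"),
                              concentration, signal, probe_total,
                              receptor_total = NULL, probe_kd = NULL,
                              replicate = "rep1") {
  mode <- match.arg(mode)
  stopifnot(length(concentration) == length(signal),
            all(concentration >= 0), probe_total >= 0)
  pos <- concentration[concentration > 0]
  if (length(concentration) < 5L ||
      (length(pos) > 0 && max(pos) / min(pos) < 100)) {
    warning("titration has < 5 points or spans < 2 orders of magnitude; ",
            "the fit may be poorly constrained")
  }
  if (mode == "competition") {
    if (is.null(receptor_total)) stop("competition mode needs receptor_total")
  }
  structure(
    list(mode = mode, concentration = concentration, signal = signal,
         probe_total = probe_total, receptor_total = receptor_total,
         probe_kd = probe_kd, replicate = replicate),
    class = "titration_dataset")
}

.binding_fit <- function(mode, constant, constant_se, signal_free,
                         signal_bound, se_free, se_bound, rss, converged,
                         n_points) {
  structure(
    list(mode = mode, constant = constant, constant_se = constant_se,
         signal_free = signal_free, signal_bound = signal_bound,
         signal_free_se = se_free, signal_bound_se = se_bound,
         rss = rss, converged = converged, n_points = n_points),
    class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  lab <- if (x$mode == "direct") "Kd" else "Ki"
  cat(sprintf("binding_fit (%s): %s = %.4g uM (SE %.2g), endpoints %.4g / %.4g, RSS %.4g, converged: %s\n",
              x$mode, lab, x$constant, x$constant_se, x$signal_free,
              x$signal_bound, x$rss, x$converged))
  invisible(x)
}

# Newton polish of a smooth 1-D minimum: golden-section search resolves the
# argmin only to ~sqrt(machine eps); a few Newton steps on the central-
# difference derivative recover close to full precision.
.refine_min <- function(f, x0, h = 1e-4, iters = 12L) {
  x <- x0
  for (i in seq_len(iters)) {
    fp <- f(x + h); fm <- f(x - h); f0 <- f(x)
    g <- (fp - fm) / (2 * h)
    hess <- (fp - 2 * f0 + fm) / h^2
    if (!is.finite(g) || !is.finite(hess) || hess <= 0) break
    step <- g / hess
    if (!is.finite(step)) break
    x <- x - step
    if (abs(step) < 1e-13) break
  }
  x
}

# Variable-projection fit of signal = sf + (sb - sf) * m(conc; k): the
# endpoints enter linearly, so for each candidate log k the linear pair is
# solved exactly and only the profiled residual sum of squares is searched
# (coarse log-spaced grid, then golden-section refinement). Standard errors
# come from the Gauss-Newton covariance of the full 3-parameter Jacobian at
# the optimum, with the delta method for the constant itself.
.fit_fp <- function(conc, signal, model_fn, mode, n_points) {
  rng <- range(signal)
  if (diff(rng) <= 1e-9 * max(abs(rng), 1) || stats::sd(signal) == 0) {
    return(.binding_fit(mode, NA_real_, NA_real_, mean(signal), mean(signal),
                        NA_real_, NA_real_, sum((signal - mean(signal))^2),
                        converged = FALSE, n_points = n_points))
  }
  a <- min(signal); b <- diff(rng)   # scale-free residuals
  y <- (signal - a) / b
  lin_solve <- function(m) {
    X <- cbind(1 - m, m)
    fit <- stats::lm.fit(X, y)
    list(coef = stats::coef(fit), rss = sum(fit$residuals^2))
  }
  prss <- function(logk) lin_solve(model_fn(conc, exp(logk)))$rss

  pos <- conc[conc > 0]
  grid <- seq(log(min(pos)) - 6, log(max(pos)) + 6, length.out = 80L)
  vals <- vapply(grid, prss, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
  opt <- stats::optimize(prss, c(lo, hi), tol = 1e-10)
  logk <- .refine_min(prss, opt$minimum)
  m <- model_fn(conc, exp(logk))
  ls <- lin_solve(m)
  sf <- ls$coef[[1L]]; sb <- ls$coef[[2L]]
  rss <- ls$rss

  # Gauss-Newton covariance of (logk, sf, sb) at the optimum
  h <- 1e-6
  dm <- (model_fn(conc, exp(logk + h)) - model_fn(conc, exp(logk - h))) /
    (2 * h)
  J <- cbind((sb - sf) * dm, 1 - m, m)
  dof <- n_points - 3L
  se <- rep(NA_real_, 3)
  if (dof > 0) {
    cov <- tryCatch(sum(rss) / dof * solve(crossprod(J)),
                    error = function(e) NULL)
    if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  }
  k <- exp(logk)
  interior <- logk > grid[1L] + 1e-6 && logk < grid[length(grid)] - 1e-6
  conv <- is.finite(k) && abs(sb - sf) > 0 && interior
  .binding_fit(mode, k, k * se[1L], a + b * sf, a + b * sb,
               b * se[2L], b * se[3L], rss * b^2, conv, n_points)
}

#' Fit a direct fluorescence-polarization titration
#'
#' Least-squares fit of
#' `signal(R) = sf + (sb - sf) * bound_fraction_direct(R, L, Kd)` over
#' `{Kd, sf, sb}`. Kd is log-parameterised and profiled: the endpoints are
#' linear and solved exactly at each candidate, so the search over log Kd is
#' global (coarse grid spanning the titrated range, then golden-section
#' refinement). Standard errors come from the Gauss-Newton covariance at the
#' optimum (delta method for Kd).
#'
#' @param ds A `titration_dataset` with `mode = "direct"`.
#' @return A `binding_fit` with `constant` = Kd (uM). Non-convergence (e.g.
#'   a flat titration) is flagged via `converged = FALSE`, not raised.
#' @export
fit_direct <- function(ds) {
  stopifnot(inherits(ds, "titration_dataset"), ds$mode == "direct")
  L <- ds$probe_total
  .fit_fp(ds$concentration, ds$signal,
          function(conc, k) bound_fraction_direct(conc, L, k),
          mode = "direct", n_points = length(ds$signal))
}

#' Fit a competition fluorescence-polarization titration
#'
#' Least-squares fit over `{Ki, sf, sb}` using the exact ternary competitive
#' equilibrium ([free_species_competition()]); no IC50 / Cheng-Prusoff
#' approximation is used. `sb` is the signal with no displacement (probe
#' maximally bound at the fixed receptor concentration) and `sf` the fully
#' displaced signal.
#'
#' @param ds A `titration_dataset` with `mode = "competition"`, carrying
#'   `receptor_total`, `probe_total` and `probe_kd` (from a prior
#'   [fit_direct()]).
#' @return A `binding_fit` with `constant` = Ki (uM).
#' @export
fit_competition <- function(ds) {
  stopifnot(inherits(ds, "titration_dataset"), ds$mode == "competition")
  if (is.null(ds$probe_kd)) stop("competition fit requires probe_kd")
  R <- ds$receptor_total; L <- ds$probe_total; Kp <- ds$probe_kd
  model <- function(conc, k) {
    free_species_competition(R, L, conc, Kp, k)$probe_bound / L
  }
  .fit_fp(ds$concentration, ds$signal, model,
          mode = "competition", n_points = length(ds$signal))
}

#' Fold-change in Kd between a reference and a variant domain
#'
#' `fold = geometric mean Kd(reference) / geometric mean Kd(variant)`, so
#' fold > 1 means the variant binds tighter. With at least three replicate
#' fits per side, a two-sided Welch t-test on log-Kd gives a p-value and a
#' confidence interval (computed on the log scale and back-transformed).
#'
#' @param fits_ref,fits_var Lists of `binding_fit` objects (or bare numeric
#'   Kd vectors) for the reference and variant domains.
#' @param labels Character pair naming reference and variant.
#' @param conf_level Confidence level, default 0.95.
#' @return A `fold_change`: list with `fold`, `ci` (or `NA`s), `p_value`
#'   (or `NA`), `n_ref`, `n_var`, `labels`.
#' @export
fold_change <- function(fits_ref, fits_var,
                        labels = c("reference", "variant"),
                        conf_level = 0.95) {
  get_kd <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(f) {
      if (inherits(f, "binding_fit")) f$constant else as.numeric(f)
    }, numeric(1))
  }
  kd_ref <- get_kd(fits_ref); kd_var <- get_kd(fits_var)
  stopifnot(length(kd_ref) >= 1L, length(kd_var) >= 1L,
            all(kd_ref > 0), all(kd_var > 0))
  lr <- log(kd_ref); lv <- log(kd_var)
  fold <- exp(mean(lr) - mean(lv))
  p <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (length(lr) >= 3L && length(lv) >= 3L &&
      (stats::sd(lr) > 0 || stats::sd(lv) > 0)) {
    tt <- stats::t.test(lr, lv, conf.level = conf_level)
    p <- tt$p.value
    ci <- exp(tt$conf.int)
  }
  structure(
    list(fold = fold, ci = ci, p_value = p,
         n_ref = length(lr), n_var = length(lv), labels = labels),
    class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold_change %s / %s: %.3g (n = %d, %d)",
              x$labels[1], x$labels[2], x$fold, x$n_ref, x$n_var))
  if (!is.na(x$p_value)) {
    cat(sprintf(", 95%% CI [%.3g, %.3g], p = %.3g",
                x$ci[1], x$ci[2], x$p_value))
  }
  cat("\n")
  invisible(x)
}
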