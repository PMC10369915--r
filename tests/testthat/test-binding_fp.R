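# Equilibrium forward models (exact direct and ternary competitive),
# FP titration fits, and Kd fold-change statistics.

test_that("direct binding model: limits and the exact equilibrium solution", {
  # trace-probe limit: receptor at Kd gives half-maximal binding
  expect_equal(bound_fraction_direct(1, 0, 1), 0.5)
  expect_equal(bound_fraction_direct(1, 1e-9, 1), 0.5, tolerance = 1e-6)
  # stoichiometric limit: Kd -> 0 with excess receptor binds everything
  expect_equal(bound_fraction_direct(2, 1, 1e-9), 1, tolerance = 1e-6)
  # R = L = Kd = 1: bound = (3 - sqrt(5)) / 2, and the equilibrium
  # equation (R - b)(L - b) = Kd * b holds to 1e-12
  frac <- bound_fraction_direct(1, 1, 1)
  b <- frac * 1
  expect_equal(b, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_lt(abs((1 - b) * (1 - b) - 1 * b), 1e-12)
  # monotone decreasing in Kd
  kds <- 10^seq(-2, 2, length.out = 20)
  fr <- vapply(kds, function(k) bound_fraction_direct(0.5, 0.1, k),
               numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("competitive equilibrium: reductions, oracle agreement, mass balance", {
  # competitor 0 reduces to the direct model
  fs <- free_species_competition(0.8, 0.05, 0, 1, 5)
  expect_equal(fs$probe_bound / 0.05, bound_fraction_direct(0.8, 0.05, 1),
               tolerance = 1e-9)
  # inert competitor (Ki -> infinity) likewise
  fs2 <- free_species_competition(0.8, 0.05, 100, 1, 1e12)
  expect_equal(fs2$probe_bound / 0.05, bound_fraction_direct(0.8, 0.05, 1),
               tolerance = 1e-9)
  # monotone decreasing probe binding in competitor concentration
  comp <- 10^seq(-2, 3, length.out = 25)
  pb <- free_species_competition(1, 0.01, comp, 1, 5)$probe_bound
  expect_true(all(diff(pb) < 0))

  # random inputs agree with the independent bisection oracle and conserve
  # mass to 1e-9 relative
  set.seed(123)
  for (i in 1:500) {
    R <- runif(1, 1e-3, 100); A <- runif(1, 1e-4, 10)
    B <- runif(1, 0, 1000)
    Ka <- 10^runif(1, -3, 2); Kb <- 10^runif(1, -3, 2)
    fs <- free_species_competition(R, A, B, Ka, Kb)
    f_oracle <- oracle_free_receptor(R, A, B, Ka, Kb)
    expect_equal(fs$free_receptor, f_oracle, tolerance = 1e-9)
    expect_lt(abs(fs$free_receptor + fs$probe_bound + fs$competitor_bound - R),
              1e-9 * max(R, 1))
  }
})

test_that("direct fits recover truth exactly without noise and flag flat data", {
  tr <- titration_truth("direct",
                        list(kd = 1, probe_total = 0.01, signal_free = 50,
                             signal_bound = 200), noise_sd = 0)
  ds <- simulate_titration(tr, direct_conc(1))
  fit <- fit_direct(ds)
  expect_true(fit$converged)
  expect_equal(fit$constant, 1, tolerance = 1e-6)
  expect_equal(fit$signal_free, 50, tolerance = 1e-4)
  expect_equal(fit$signal_bound, 200, tolerance = 1e-4)

  flat <- suppressWarnings(titration_dataset(
    "direct", direct_conc(1), rep(120, length(direct_conc(1))),
    probe_total = 0.01))
  expect_false(fit_direct(flat)$converged)
})

test_that("competition fits recover truth exactly and bracket the data endpoints", {
  tr <- titration_truth("competition",
                        list(ki = 5, probe_kd = 1, probe_total = 0.01,
                             receptor_total = 1, signal_free = 50,
                             signal_bound = 200), noise_sd = 0)
  ds <- simulate_titration(tr, competition_conc(5))
  fit <- fit_competition(ds)
  expect_true(fit$converged)
  expect_equal(fit$constant, 5, tolerance = 1e-6)
  # fitted endpoints bracket the observed signal range
  expect_lte(min(fit$signal_free, fit$signal_bound), min(ds$signal) + 1e-6)
  expect_gte(max(fit$signal_free, fit$signal_bound), max(ds$signal) - 1e-6)

  ds$probe_kd <- NULL
  expect_error(fit_competition(ds), "probe_kd")
})

test_that("noisy fits cover the truth within 2 SE in at least 90% of repeats", {
  n_rep <- 100
  cover_direct <- logical(n_rep)
  cover_comp <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    trd <- titration_truth("direct",
                           list(kd = 1, probe_total = 0.01,
                                signal_free = 50, signal_bound = 200),
                           noise_sd = 2, seed = 1000 + i)
    fd <- fit_direct(simulate_titration(trd, direct_conc(1)))
    cover_direct[i] <- fd$converged &&
      abs(fd$constant - 1) <= 2 * fd$constant_se
    trc <- titration_truth("competition",
                           list(ki = 5, probe_kd = 1, probe_total = 0.01,
                                receptor_total = 1, signal_free = 50,
                                signal_bound = 200),
                           noise_sd = 2, seed = 2000 + i)
    fc <- fit_competition(simulate_titration(trc, competition_conc(5)))
    cover_comp[i] <- fc$converged && abs(fc$constant - 5) <= 2 * fc$constant_se
  }
  expect_gte(mean(cover_direct), 0.9)
  expect_gte(mean(cover_comp), 0.9)

  # median relative error across noisy competition fits stays below 10%
  errs <- vapply(1:20, function(i) {
    trc <- titration_truth("competition",
                           list(ki = 5, probe_kd = 1, probe_total = 0.01,
                                receptor_total = 1, signal_free = 50,
                                signal_bound = 200),
                           noise_sd = 2, seed = 3000 + i)
    fc <- fit_competition(simulate_titration(trc, competition_conc(5)))
    abs(fc$constant - 5) / 5
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
})

test_that("fold changes use geometric means and Welch tests on log Kd", {
  # single fits: plain ratio
  fc <- fold_change(10, 2)
  expect_equal(fc$fold, 5)
  expect_true(is.na(fc$p_value))

  # identical replicate sets: fold 1, p near 1
  kds <- c(1.1, 0.9, 1.0)
  fc2 <- fold_change(kds, kds)
  expect_equal(fc2$fold, 1, tolerance = 1e-12)
  expect_gt(fc2$p_value, 0.95)
  expect_true(fc2$ci[1] <= fc2$fold && fc2$fold <= fc2$ci[2])

  # geometric-mean ratio for asymmetric replicates
  fc3 <- fold_change(c(8, 12.5), c(2, 2))
  expect_equal(fc3$fold, sqrt(8 * 12.5) / 2, tolerance = 1e-12)

  # recovered from fitted titrations: truth ratio 5 (reference 10 uM,
  # variant 2 uM), three replicates each
  fits_ref <- lapply(1:3, function(i) {
    tr <- titration_truth("competition",
                          list(ki = 10, probe_kd = 1, probe_total = 0.01,
                               receptor_total = 1, signal_free = 50,
                               signal_bound = 200), noise_sd = 2,
                          seed = 4000 + i)
    fit_competition(simulate_titration(tr, competition_conc(10)))
  })
  fits_var <- lapply(1:3, function(i) {
    tr <- titration_truth("competition",
                          list(ki = 2, probe_kd = 1, probe_total = 0.01,
                               receptor_total = 1, signal_free = 50,
                               signal_bound = 200), noise_sd = 2,
                          seed = 4100 + i)
    fit_competition(simulate_titration(tr, competition_conc(2)))
  })
  fc4 <- fold_change(fits_ref, fits_var, labels = c("WT", "T42A"))
  expect_equal(fc4$fold, 5, tolerance = 0.15)
  expect_lt(fc4$p_value, 0.05)
})
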