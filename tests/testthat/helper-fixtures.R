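# Shared fixtures: tiny deterministic libraries, random count tables, and
# the independent bisection oracle for the competitive equilibrium.

tiny_library <- function() {
  peptide_library(data.frame(
    id = c("p1", "p2", "p3", "c1"),
    peptide = c("VDAGEYDFAHA", "LNHTPYINASL", "ALVSEYHELQP", "ALVSEFHELQP"),
    category = c("wildtype_site", "wildtype_site", "wildtype_site",
                 "tyr_free_control"),
    stringsAsFactors = FALSE), name = "tiny")
}

# count table straight from a named vector, bypassing a screen
ct_from_counts <- function(counts, lib, label = "sample") {
  count_table(counts, lib, sample_label = label)
}

random_count_pair <- function(lib, depth = 1000L) {
  ids <- lib$entries$id
  list(
    input = ct_from_counts(
      stats::setNames(stats::rmultinom(1, depth, rep(1, length(ids)))[, 1],
                      ids), lib, "input"),
    selected = ct_from_counts(
      stats::setNames(stats::rmultinom(1, depth,
                                       stats::runif(length(ids)))[, 1],
                      ids), lib, "selected"))
}

# independent mass-action oracle: bracketing on the monotone balance
# equation, then Newton refinement with the analytic derivative (uniroot
# alone bottoms out at its absolute tolerance for tiny roots)
oracle_free_receptor <- function(R, A, B, Ka, Kb) {
  if (R == 0) return(0)
  g <- function(x) x + A * x / (Ka + x) + B * x / (Kb + x) - R
  dg <- function(x) 1 + A * Ka / (Ka + x)^2 + B * Kb / (Kb + x)^2
  x <- stats::uniroot(g, c(0, R), tol = 1e-14)$root
  for (i in 1:50) {
    step <- g(x) / dg(x)
    x_new <- x - step
    if (x_new <= 0) x_new <- x / 2
    if (abs(x_new - x) <= 1e-16 * max(x, 1e-300)) { x <- x_new; break }
    x <- x_new
  }
  x
}

# standard titration designs used across fitting tests: 12 concentrations
# measured in technical duplicate, the usual plate layout for FP and
# activity assays
direct_conc <- function(kd) {
  rep(10^seq(log10(kd) - 2.5, log10(kd) + 1.5, length.out = 12), each = 2)
}
competition_conc <- function(ki) {
  rep(c(0, 10^seq(log10(ki) - 2, log10(ki) + 3, length.out = 11)), each = 2)
}
activation_conc <- function(ec50) {
  rep(c(0, 10^seq(log10(ec50) - 1.5, log10(ec50) + 2.5, length.out = 11)),
      each = 2)
}
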