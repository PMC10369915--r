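# Double-mutant cycle thermodynamics: Kd ratios -> binding free-energy
# differences and the interaction (coupling) energy between two mutations.

#' Gas constant in kcal mol^-1 K^-1
#' @keywords internal
.R_KCAL <- 1.9872e-3

#' Thermal energy RT
#'
#' @param temperature Temperature in kelvin; default 298.15.
#' @param units `"kcal"` (default) or `"kJ"` per mol.
#' @return RT in the requested units.
#' @export
rt_energy <- function(temperature = 298.15, units = c("kcal", "kJ")) {
  units <- match.arg(units)
  stopifnot(temperature > 0)
  rt <- .R_KCAL * temperature
  if (units == "kJ") rt * 4.184 else rt
}

#' Binding free-energy difference from a Kd fold-change
#'
#' `ddG = -RT * ln(fold)` with `fold = Kd_reference / Kd_variant`, so an
#' affinity-enhancing change (fold > 1) gives a negative ddG.
#'
#' @param fold Kd fold-change(s), > 0.
#' @param temperature Kelvin; default 298.15.
#' @param units `"kcal"` or `"kJ"` per mol.
#' @return ddG in the requested units.
#' @export
ddg_from_fold <- function(fold, temperature = 298.15,
                          units = c("kcal", "kJ")) {
  stopifnot(all(fold > 0))
  -rt_energy(temperature, units) * log(fold)
}

#' Construct a double-mutant thermodynamic cycle
#'
#' Four states measured against the same peptide under the same conditions:
#' wild type, single mutants A and B, and the double mutant AB. Each
#' single-state perturbation energy is `ddG_X = RT ln(Kd_X / Kd_wt)`
#' (negative = tighter binding, matching [ddg_from_fold()]), and the
#' interaction energy is
#' `ddG_int = ddG_AB - ddG_A - ddG_B = RT ln((Kd_AB * Kd_wt) / (Kd_A * Kd_B))`.
#' A negative `ddG_int` means the double mutant binds tighter than
#' additivity predicts; a positive value means the two mutations are
#' sub-additive (part of one mutation's effect requires the other residue).
#'
#' @param kd_wt,kd_a,kd_b,kd_ab Dissociation constants, uM, all > 0.
#' @param labels Character vector of four state labels.
#' @param temperature Kelvin; default 298.15.
#' @param units `"kcal"` or `"kJ"` per mol.
#' @return A `coupling_cycle`: list with the four Kds, `ddg_a`, `ddg_b`,
#'   `ddg_ab`, `ddg_int`, `temperature`, `rt`, `units`, `labels`.
#' @export
coupling_cycle <- function(kd_wt, kd_a, kd_b, kd_ab,
                           labels = c("wt", "A", "B", "AB"),
                           temperature = 298.15, units = c("kcal", "kJ")) {
  units <- match.arg(units)
  stopifnot(kd_wt > 0, kd_a > 0, kd_b > 0, kd_ab > 0,
            length(labels) == 4L)
  rt <- rt_energy(temperature, units)
  ddg <- function(kd) rt * log(kd / kd_wt)   # = ddg_from_fold(kd_wt / kd)
  structure(
    list(kd = stats::setNames(c(kd_wt, kd_a, kd_b, kd_ab), labels),
         ddg_a = ddg(kd_a), ddg_b = ddg(kd_b), ddg_ab = ddg(kd_ab),
         ddg_int = ddg(kd_ab) - ddg(kd_a) - ddg(kd_b),
         temperature = temperature, rt = rt, units = units,
         labels = labels),
    class = "coupling_cycle")
}

#' Interaction (coupling) free energy of a double-mutant cycle
#'
#' @param cycle A `coupling_cycle`.
#' @return `ddG_int` in the cycle's units.
#' @export
coupling_energy <- function(cycle) {
  stopifnot(inherits(cycle, "coupling_cycle"))
  cycle$ddg_int
}

#' Coupling energy from two fold-changes
#'
#' Equivalent route when only fold-changes are reported: mutation A's effect
#' measured as a Kd fold-change in the wild-type background (`fold_wt_bg`)
#' and in the background of mutation B (`fold_b_bg`) gives
#' `ddG_int = ddg_from_fold(fold_b_bg) - ddg_from_fold(fold_wt_bg)
#'          = RT * ln(fold_wt_bg / fold_b_bg)`.
#' Attenuation of the fold by the second mutation (sub-additivity) yields a
#' positive coupling energy; enhancement yields a negative one. Either way a
#' nonzero value means the two residues are energetically coupled.
#'
#' @param fold_wt_bg Fold-change of mutation A in the wild-type background.
#' @param fold_b_bg Fold-change of mutation A in the mutant-B background.
#' @param temperature Kelvin; default 298.15.
#' @param units `"kcal"` or `"kJ"` per mol.
#' @return `ddG_int` in the requested units.
#' @export
coupling_from_folds <- function(fold_wt_bg, fold_b_bg, temperature = 298.15,
                                units = c("kcal", "kJ")) {
  stopifnot(all(fold_wt_bg > 0), all(fold_b_bg > 0))
  rt_energy(temperature, units) * log(fold_wt_bg / fold_b_bg)
}

#' @export
print.coupling_cycle <- function(x, ...) {
  cat(sprintf("coupling_cycle (%s, T = %.2f K):\n", x$units, x$temperature))
  cat(sprintf("  Kd: %s\n",
              paste(sprintf("%s = %.4g", names(x$kd), x$kd), collapse = ", ")))
  cat(sprintf("  ddG(%s) = %.4g, ddG(%s) = %.4g, ddG(%s) = %.4g, ddG_int = %.4g %s/mol\n",
              x$labels[2], x$ddg_a, x$labels[3], x$ddg_b,
              x$labels[4], x$ddg_ab, x$ddg_int, x$units))
  invisible(x)
}
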