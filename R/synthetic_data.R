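# Ground-truth simulators: multinomial selection screens, binding and
# activation titrations with additive Gaussian noise, and fixture peptide
# libraries. All randomness is scoped to an explicit per-call seed.

#' Selection-screen ground truth
#'
#' @param weights Named positive selection weights (relative binding
#'   propensity, 1 = neutral) covering every library peptide id.
#'   Tyrosine-free controls should be held at 1 (non-binders passing through
#'   at background) unless deliberately perturbed.
#' @param depth_input,depth_selected Sequencing depths (reads) for the input
#'   and selected samples.
#' @param seed Integer seed; all sampling in [simulate_screen()] flows from
#'   it.
#' @return An object of class `screen_truth`.
#' @export
screen_truth <- function(weights, depth_input, depth_selected, seed = 1L) {
  stopifnot(is.numeric(weights), !is.null(names(weights)),
            all(weights > 0), depth_input >= 1, depth_selected >= 1)
  structure(
    list(weights = weights, depth_input = as.integer(depth_input),
         depth_selected = as.integer(depth_selected),
         seed = as.integer(seed)),
    class = "screen_truth")
}

#' Simulate one round of affinity selection plus sequencing
#'
#' Input counts are drawn multinomially at `depth_input` from `input_freqs`
#' (uniform by default); selected counts are drawn multinomially at
#' `depth_selected` with probabilities proportional to
#' `input_freq x weight`. The expected enrichment score of peptide `i` is
#' therefore `w_i / sum_j(f_j w_j)`, independent of depth. Deterministic
#' given the truth seed.
#'
#' @param lib A `peptide_library`.
#' @param truth A `screen_truth` whose weights cover all library ids.
#' @param input_freqs Optional named input frequencies; default uniform.
#' @return List with `input` and `selected` (`count_table`s) and `truth`.
#' @export
simulate_screen <- function(lib, truth, input_freqs = NULL) {
  stopifnot(inherits(lib, "peptide_library"), inherits(truth, "screen_truth"))
  ids <- lib$entries$id
  missing <- setdiff(ids, names(truth$weights))
  if (length(missing) > 0L) {
    stop("weights missing for id(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  w <- truth$weights[ids]
  if (is.null(input_freqs)) {
    f <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  } else {
    stopifnot(all(ids %in% names(input_freqs)))
    f <- input_freqs[ids] / sum(input_freqs[ids])
  }
  withr::with_seed(truth$seed, {
    in_counts <- as.integer(stats::rmultinom(1L, truth$depth_input, f))
    sel_p <- f * w
    sel_counts <- as.integer(stats::rmultinom(1L, truth$depth_selected,
                                              sel_p / sum(sel_p)))
  })
  list(input = count_table(stats::setNames(in_counts, ids), lib, "input"),
       selected = count_table(stats::setNames(sel_counts, ids), lib,
                              "selected"),
       truth = truth)
}

#' Titration ground truth
#'
#' @param model `"direct"`, `"competition"`, or `"activation"`.
#' @param parameters Named list; required names by model:
#'   direct: `kd`, `probe_total`, `signal_free`, `signal_bound`;
#'   competition: `ki`, `probe_kd`, `probe_total`, `receptor_total`,
#'   `signal_free`, `signal_bound`;
#'   activation: `ec50`, `rate_basal`, `rate_max` (optional `hill_n`).
#'   Concentrations in uM; signals in polarization units or rate units.
#' @param noise_sd Standard deviation of additive zero-mean Gaussian noise,
#'   in signal units. Defaults: 2 mP for binding modes (typical plate-reader
#'   polarization scatter), 2% of the maximal rate for activation.
#' @param seed Integer seed.
#' @return An object of class `titration_truth`.
#' @export
titration_truth <- function(model = c("direct", "competition", "activation"),
                            parameters, noise_sd = NULL, seed = 1L) {
  model <- match.arg(model)
  need <- switch(model,
                 direct = c("kd", "probe_total", "signal_free",
                            "signal_bound"),
                 competition = c("ki", "probe_kd", "probe_total",
                                 "receptor_total", "signal_free",
                                 "signal_bound"),
                 activation = c("ec50", "rate_basal", "rate_max"))
  miss <- setdiff(need, names(parameters))
  if (length(miss) > 0L) {
    stop("model '", model, "' needs parameter(s): ",
         paste(miss, collapse = ", "))
  }
  consts <- intersect(c("kd", "ki", "probe_kd", "ec50"), names(parameters))
  stopifnot(all(unlist(parameters[consts]) > 0))
  if (is.null(noise_sd)) {
    noise_sd <- if (model == "activation") 0.02 * parameters$rate_max else 2
  }
  stopifnot(noise_sd >= 0)
  structure(
    list(model = model, parameters = parameters, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "titration_truth")
}

#' Noiseless forward signal for a titration truth
#'
#' @param truth A `titration_truth`.
#' @param concentrations Titrant concentrations, uM.
#' @return Numeric signal at each concentration.
#' @export
titration_signal <- function(truth, concentrations) {
  stopifnot(inherits(truth, "titration_truth"), all(concentrations >= 0))
  p <- truth$parameters
  switch(truth$model,
         direct = p$signal_free + (p$signal_bound - p$signal_free) *
           bound_fraction_direct(concentrations, p$probe_total, p$kd),
         competition = {
           frac <- free_species_competition(
             p$receptor_total, p$probe_total, concentrations,
             p$probe_kd, p$ki)$probe_bound / p$probe_total
           p$signal_free + (p$signal_bound - p$signal_free) * frac
         },
         activation = activation_rate(
           concentrations, p$rate_basal, p$rate_max, p$ec50,
           if (is.null(p$hill_n)) 1 else p$hill_n))
}

#' Simulate a noisy titration
#'
#' Computes the noiseless signal with the matching forward model and adds
#' zero-mean Gaussian noise of standard deviation `truth$noise_sd`.
#' Deterministic given the truth seed.
#'
#' @param truth A `titration_truth`.
#' @param concentrations Titrant concentrations, uM.
#' @param replicate Replicate label for the resulting dataset.
#' @return A `titration_dataset` (binding modes) or `activation_dataset`.
#' @export
simulate_titration <- function(truth, concentrations, replicate = "rep1") {
  mu <- titration_signal(truth, concentrations)
  signal <- withr::with_seed(truth$seed,
                             mu + stats::rnorm(length(mu), 0, truth$noise_sd))
  p <- truth$parameters
  if (truth$model == "activation") {
    return(activation_dataset(concentrations, signal, replicate = replicate))
  }
  suppressWarnings(titration_dataset(
    mode = truth$model, concentration = concentrations, signal = signal,
    probe_total = p$probe_total,
    receptor_total = p$receptor_total, probe_kd = p$probe_kd,
    replicate = replicate))
}

#' Build a random fixture library
#'
#' Random fixed-length peptides with a single central tyrosine, plus
#' tyrosine-free negative controls. Deterministic given the seed.
#'
#' @param n_sites Number of single-tyrosine peptides.
#' @param n_controls Number of tyrosine-free controls (>= 1: without
#'   controls the hit cutoff cannot be calibrated).
#' @param peptide_length Peptide length in residues (>= 1).
#' @param seed Integer seed.
#' @param name Library name.
#' @return A `peptide_library`.
#' @export
make_fixture_library <- function(n_sites, n_controls, peptide_length = 11L,
                                 seed = 1L, name = "fixture") {
  stopifnot(n_sites >= 0, peptide_length >= 1)
  if (n_controls < 1) {
    stop("n_controls must be >= 1: tyrosine-free controls are required ",
         "for cutoff calibration")
  }
  non_tyr <- setdiff(aa_alphabet(), "Y")
  centre <- (peptide_length + 1L) %/% 2L
  withr::with_seed(seed, {
    sites <- vapply(seq_len(n_sites), function(i) {
      res <- sample(non_tyr, peptide_length, replace = TRUE)
      res[centre] <- "Y"
      paste(res, collapse = "")
    }, character(1))
    ctrls <- vapply(seq_len(n_controls), function(i) {
      paste(sample(non_tyr, peptide_length, replace = TRUE), collapse = "")
    }, character(1))
  })
  entries <- data.frame(
    id = c(sprintf("site%03d", seq_len(n_sites)),
           sprintf("ctrl%03d", seq_len(n_controls))),
    peptide = c(sites, ctrls),
    category = c(rep("wildtype_site", n_sites),
                 rep("tyr_free_control", n_controls)),
    stringsAsFactors = FALSE)
  peptide_library(entries, name = name, peptide_length = peptide_length)
}

#' Selection weights from a position-weight model
#'
#' Builds per-peptide selection weights as the product, over positions
#' relative to the phosphotyrosine, of residue-specific multipliers
#' (1 for residues not listed). Tyrosine-free controls get weight 1.
#'
#' @param lib A `peptide_library`.
#' @param effects Named list: names are positions relative to pTyr (e.g.
#'   `"-2"`, `"1"`); each element is a named numeric vector of positive
#'   multipliers keyed by amino acid.
#' @return Named weight vector over all library ids.
#' @export
pwm_screen_weights <- function(lib, effects) {
  stopifnot(inherits(lib, "peptide_library"), is.list(effects))
  ent <- lib$entries
  w <- stats::setNames(rep(1, nrow(ent)), ent$id)
  for (pos_chr in names(effects)) {
    pos <- as.integer(pos_chr)
    mult <- effects[[pos_chr]]
    stopifnot(all(mult > 0))
    idx <- ent$phospho_index + pos
    ok <- !is.na(ent$phospho_index) & idx >= 1L & idx <= nchar(ent$peptide)
    res <- substr(ent$peptide[ok], idx[ok], idx[ok])
    hit <- res %in% names(mult)
    w[ent$id[ok][hit]] <- w[ent$id[ok][hit]] * mult[res[hit]]
  }
  w
}

#' Write simulated screen reads as FASTQ
#'
#' Reverse-translates each library peptide with a fixed codon choice and
#' emits one FASTQ record per read (constant quality), shuffled
#' deterministically. Useful for exercising [count_reads()] end to end.
#'
#' @param ct A `count_table` of simulated reads.
#' @param lib The `peptide_library`.
#' @param path Output FASTQ path.
#' @param seed Integer seed for the read-order shuffle.
#' @return `path`, invisibly.
#' @export
write_screen_fastq <- function(ct, lib, path, seed = 1L) {
  stopifnot(inherits(ct, "count_table"), inherits(lib, "peptide_library"))
  codon <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTC",
             G = "GGT", H = "CAC", I = "ATC", K = "AAA", L = "CTG",
             M = "ATG", N = "AAC", P = "CCG", Q = "CAG", R = "CGT",
             S = "TCT", T = "ACC", V = "GTT", W = "TGG", Y = "TAC")
  dna <- vapply(strsplit(lib$entries$peptide, ""), function(res)
    paste(codon[res], collapse = ""), character(1))
  names(dna) <- lib$entries$id
  reads <- rep(dna[names(ct$counts)], ct$counts)
  reads <- withr::with_seed(seed, sample(reads))
  qual <- strrep("I", 3L * lib$peptide_length)
  lines <- character(4L * length(reads))
  lines[seq(1L, by = 4L, length.out = length(reads))] <-
    sprintf("@read%06d", seq_along(reads))
  lines[seq(2L, by = 4L, length.out = length(reads))] <- unname(reads)
  lines[seq(3L, by = 4L, length.out = length(reads))] <- "+"
  lines[seq(4L, by = 4L, length.out = length(reads))] <- qual
  writeLines(lines, path)
  invisible(path)
}
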