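# Hit calling calibrated on tyrosine-free controls, hit-set overlaps,
# position-specific logo matrices, scanning-mutagenesis matrices, and
# paired domain comparisons.

.control_ids <- function(lib) {
  lib$entries$id[lib$entries$category == "tyr_free_control"]
}

.eligible_ids <- function(et, lib) {
  # single-tyrosine, non-control peptides present in the table
  ntyr <- tyrosine_counts(lib)
  ids <- intersect(rownames(et$scores), lib$entries$id)
  ctrl <- .control_ids(lib)
  ids[ntyr[ids] == 1L & !(ids %in% ctrl)]
}

#' Calibrate the hit cutoff from tyrosine-free control peptides
#'
#' Tyrosine-free peptides cannot be phosphorylated and therefore measure the
#' non-specific background of the selection. The calibrated cutoff is the
#' smallest value `c`, among the sorted control scores plus a configured
#' floor, such that the fraction of controls with mean score strictly above
#' `c` is at most `max_control_fraction`.
#'
#' @param et An `enrichment_table` containing the control peptides.
#' @param lib A `peptide_library` (or list of them) defining the controls.
#' @param max_control_fraction Maximum tolerated control false-positive
#'   fraction; default 0.02.
#' @param floor Lower bound included in the candidate set; default 0.
#' @return The calibrated cutoff (numeric scalar).
#' @export
calibrate_cutoff <- function(et, lib, max_control_fraction = 0.02, floor = 0) {
  stopifnot(inherits(et, "enrichment_table"),
            max_control_fraction > 0, max_control_fraction < 1)
  libs <- if (inherits(lib, "peptide_library")) list(lib) else lib
  ctrl <- unlist(lapply(libs, .control_ids), use.names = FALSE)
  ctrl <- intersect(ctrl, rownames(et$scores))
  if (length(ctrl) == 0L) {
    stop("no tyr_free_control peptides present; cannot calibrate a cutoff")
  }
  cs <- mean_scores(et)[ctrl]
  candidates <- sort(unique(c(floor, cs)))
  candidates <- candidates[candidates >= floor]  # the floor is a lower bound
  for (c in candidates) {
    if (mean(cs > c) <= max_control_fraction) return(c)
  }
  max(candidates)  # unreachable: the largest control score always qualifies
}

#' Fraction of control peptides scoring above a cutoff
#'
#' @inheritParams calibrate_cutoff
#' @param cutoff Enrichment-score cutoff (strictly-greater comparison).
#' @return Fraction in `[0, 1]`.
#' @export
control_fpr <- function(et, lib, cutoff) {
  libs <- if (inherits(lib, "peptide_library")) list(lib) else lib
  ctrl <- unlist(lapply(libs, .control_ids), use.names = FALSE)
  ctrl <- intersect(ctrl, rownames(et$scores))
  if (length(ctrl) == 0L) stop("no tyr_free_control peptides present")
  mean(mean_scores(et)[ctrl] > cutoff)
}

#' Call enriched peptides above a cutoff
#'
#' Hits are single-tyrosine, non-control peptides whose enrichment score is
#' strictly greater than the cutoff. By default the mean score over
#' replicates is compared; `mode = "all_replicates"` instead requires every
#' replicate to exceed the cutoff.
#'
#' @param et An `enrichment_table`.
#' @param lib A `peptide_library` or list of them.
#' @param cutoff Non-negative enrichment-score cutoff (the screens in this
#'   field typically fix 3.2, at which < 2% of controls score as binders).
#' @param mode `"mean"` (default) or `"all_replicates"`.
#' @return A `hit_set`: list with `domain_label`, `cutoff`, `hit_ids`, and
#'   `control_fpr_at_cutoff`.
#' @export
call_hits <- function(et, lib, cutoff, mode = c("mean", "all_replicates")) {
  stopifnot(inherits(et, "enrichment_table"), cutoff >= 0)
  mode <- match.arg(mode)
  libs <- if (inherits(lib, "peptide_library")) list(lib) else lib
  elig <- unlist(lapply(libs, function(l) .eligible_ids(et, l)),
                 use.names = FALSE)
  passed <- if (mode == "mean") {
    mean_scores(et)[elig] > cutoff
  } else {
    apply(et$scores[elig, , drop = FALSE] > cutoff, 1L, all, na.rm = TRUE)
  }
  fpr <- tryCatch(control_fpr(et, lib, cutoff), error = function(e) NA_real_)
  structure(
    list(domain_label = et$domain_label, cutoff = cutoff,
         hit_ids = elig[passed], control_fpr_at_cutoff = fpr),
    class = "hit_set")
}

#' @export
print.hit_set <- function(x, ...) {
  cat(sprintf("hit_set '%s': %d hits above cutoff %g (control FPR %.3g)\n",
              x$domain_label, length(x$hit_ids), x$cutoff,
              x$control_fpr_at_cutoff))
  invisible(x)
}

#' Venn decomposition of two or more hit sets
#'
#' @param sets List of at least two `hit_set` objects (or plain character
#'   vectors of ids); names are taken from the domain labels when available.
#' @return An `overlap_report`: list with `regions` (named counts, one per
#'   non-empty membership pattern such as `"A&B"`), `set_sizes`, and
#'   `union_size`. Region counts sum to the union size.
#' @export
hit_overlap <- function(sets) {
  stopifnot(length(sets) >= 2L)
  ids <- lapply(sets, function(s) if (inherits(s, "hit_set")) s$hit_ids else
    as.character(s))
  labels <- names(sets)
  if (is.null(labels)) labels <- rep(NA_character_, length(sets))
  auto <- vapply(sets, function(s)
    if (inherits(s, "hit_set")) s$domain_label else NA_character_,
    character(1))
  labels <- ifelse(is.na(labels) | labels == "", auto, labels)
  labels[is.na(labels)] <- paste0("set", seq_along(sets))[is.na(labels)]
  labels <- make.unique(labels)

  universe <- unique(unlist(ids, use.names = FALSE))
  membership <- vapply(ids, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern <- apply(membership, 1L, function(row)
    paste(labels[row], collapse = "&"))
  regions <- table(pattern)
  structure(
    list(regions = stats::setNames(as.integer(regions), names(regions)),
         set_sizes = stats::setNames(lengths(ids), labels),
         union_size = length(universe)),
    class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("overlap_report; union size", x$union_size, "\n")
  print(x$regions)
  invisible(x)
}

# per-position amino-acid counts over peptides aligned on the phosphosite
.position_counts <- function(peptides, phospho_index, positions) {
  aa <- aa_alphabet()
  counts <- matrix(0L, nrow = length(positions), ncol = length(aa),
                   dimnames = list(positions, aa))
  covered <- integer(length(positions))
  len <- nchar(peptides)
  for (k in seq_along(positions)) {
    idx <- phospho_index + positions[k]
    ok <- idx >= 1L & idx <= len
    if (!any(ok)) next
    res <- substr(peptides[ok], idx[ok], idx[ok])
    tab <- table(factor(res, levels = aa))
    counts[k, ] <- as.integer(tab)
    covered[k] <- sum(ok)
  }
  list(counts = counts, covered = covered)
}

#' Position-specific log-probability logo matrix
#'
#' For each position `p` relative to the phosphotyrosine (pTyr = 0,
#' excluded) and amino acid `a`, the logo value is the log (base 2 by
#' default) of the pseudocounted frequency of `a` at `p` in the enriched set
#' over its pseudocounted frequency in the full single-tyrosine library:
#' `log2((n_enr + pc) / (N_enr + 20 pc)) - log2((n_lib + pc) / (N_lib + 20 pc))`.
#'
#' @param hits A `hit_set` or character vector of enriched peptide ids.
#' @param lib A `peptide_library` or list of them; the comparison set is all
#'   single-tyrosine library peptides with a phosphosite.
#' @param pseudocount Shared pseudocount (occurrences), default 1.
#' @param positions Integer window relative to pTyr; default `-5:5` (0 is
#'   dropped), clipped per peptide at the library boundaries.
#' @param base Logarithm base, default 2.
#' @return A `logo_matrix`: list with `values` (positions x 20 matrix),
#'   `positions`, `pseudocount`, `base`, `n_enriched`, `n_library`.
#' @export
logo_matrix <- function(hits, lib, pseudocount = 1, positions = -5:5,
                        base = 2) {
  hit_ids <- if (inherits(hits, "hit_set")) hits$hit_ids else
    as.character(hits)
  if (length(hit_ids) == 0L) stop("empty hit set")
  positions <- sort(unique(positions[positions != 0L]))
  libs <- if (inherits(lib, "peptide_library")) list(lib) else lib
  ent <- do.call(rbind, lapply(libs, function(l) l$entries))
  ntyr <- do.call(c, lapply(libs, tyrosine_counts))
  pool <- ent[!is.na(ent$phospho_index) & ntyr[ent$id] == 1L, , drop = FALSE]
  missing <- setdiff(hit_ids, pool$id)
  if (length(missing) > 0L) {
    stop("hit ids absent from the single-tyrosine library pool: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  enr <- pool[pool$id %in% hit_ids, , drop = FALSE]

  ce <- .position_counts(enr$peptide, enr$phospho_index, positions)
  cl <- .position_counts(pool$peptide, pool$phospho_index, positions)
  pc <- pseudocount
  f_enr <- (ce$counts + pc) / (ce$covered + 20 * pc)
  f_lib <- (cl$counts + pc) / (cl$covered + 20 * pc)
  values <- (log(f_enr) - log(f_lib)) / log(base)
  # at pseudocount 0 a residue absent from both sets carries no information
  values[f_enr == 0 & f_lib == 0] <- 0
  structure(
    list(values = values, positions = positions, pseudocount = pc,
         base = base, n_enriched = nrow(enr), n_library = nrow(pool)),
    class = "logo_matrix")
}

#' @export
print.logo_matrix <- function(x, ...) {
  cat(sprintf("logo_matrix: %d positions x 20 aa, %d enriched / %d library peptides, pc %g, base %g\n",
              nrow(x$values), x$n_enriched, x$n_library, x$pseudocount,
              x$base))
  invisible(x)
}

#' Scanning-mutagenesis matrix relative to a wild-type peptide
#'
#' Scores a saturation-mutagenesis library: each single-substitution variant
#' is located by comparing its sequence to the wild-type peptide, and its
#' cell holds `log2(score_variant / score_wildtype)`. Cells for the
#' wild-type residue at each position are exactly 0 by construction;
#' variants absent from the table, carrying more than one substitution, or
#' (optionally) below an input-count floor are flagged missing (`NA`) rather
#' than scored.
#'
#' @param et An `enrichment_table` for the scan library.
#' @param lib The scan `peptide_library`.
#' @param wt_id Id of the wild-type peptide; its score must be positive.
#' @param input_counts Optional `count_table` for the input sample, used
#'   with `min_input_count` to mask poorly sampled variants.
#' @param min_input_count Input-count floor below which a variant is flagged
#'   missing; default 0 (no masking).
#' @return A `scan_matrix`: list with `values` (positions relative to pTyr x
#'   20 substitutions), `wt_peptide`, `wt_id`, `missing` (logical matrix).
#' @export
scan_matrix <- function(et, lib, wt_id, input_counts = NULL,
                        min_input_count = 0) {
  stopifnot(inherits(et, "enrichment_table"),
            inherits(lib, "peptide_library"))
  ms <- mean_scores(et)
  if (!wt_id %in% lib$entries$id || !wt_id %in% names(ms)) {
    stop("wild-type peptide '", wt_id, "' absent from library or scores")
  }
  wt_row <- lib$entries[lib$entries$id == wt_id, ]
  wt_pep <- wt_row$peptide
  wt_pi <- wt_row$phospho_index
  if (is.na(wt_pi)) stop("wild-type peptide has no phospho_index")
  wt_score <- ms[[wt_id]]
  if (!(wt_score > 0)) stop("wild-type enrichment score must be > 0")

  aa <- aa_alphabet()
  positions <- setdiff(seq_len(lib$peptide_length) - wt_pi, 0L)
  values <- matrix(NA_real_, nrow = length(positions), ncol = length(aa),
                   dimnames = list(positions, aa))
  # wild-type residue cells are defined and exactly zero
  for (k in seq_along(positions)) {
    values[k, substr(wt_pep, wt_pi + positions[k], wt_pi + positions[k])] <- 0
  }

  in_counts <- if (!is.null(input_counts)) input_counts$counts else NULL
  ent <- lib$entries[lib$entries$id != wt_id, , drop = FALSE]
  wt_chars <- strsplit(wt_pep, "")[[1L]]
  for (i in seq_len(nrow(ent))) {
    v <- ent$peptide[i]
    if (nchar(v) != nchar(wt_pep)) next
    diffs <- which(strsplit(v, "")[[1L]] != wt_chars)
    if (length(diffs) != 1L) next   # not a single-substitution variant
    pos <- diffs - wt_pi
    if (pos == 0L) next             # substitution of the pTyr itself
    id <- ent$id[i]
    if (!id %in% names(ms)) next
    if (!is.null(in_counts) && in_counts[[id]] < min_input_count) next
    sub <- substr(v, diffs, diffs)
    values[as.character(pos), sub] <- log2(ms[[id]] / wt_score)
  }

  structure(
    list(values = values, wt_peptide = wt_pep, wt_id = wt_id,
         missing = is.na(values)),
    class = "scan_matrix")
}

#' Paired comparison of enrichment scores between two domains
#'
#' Joins two enrichment tables on their shared peptide ids and reports the
#' per-peptide score pair, the log2 ratio, and a flag for peptides whose
#' absolute log2 ratio exceeds a threshold (disproportionate enrichment).
#' Peptides present in only one table are excluded and reported in the
#' `excluded` attribute.
#'
#' @param et_a,et_b `enrichment_table` objects with overlapping peptides.
#' @param log2_threshold Flag threshold on `|log2(score_b / score_a)|`;
#'   default 1 (two-fold).
#' @return Data frame with columns `id`, `score_a`, `score_b`, `log2_ratio`,
#'   `flagged`, plus attributes `labels` and `excluded`.
#' @export
compare_domains <- function(et_a, et_b, log2_threshold = 1) {
  stopifnot(inherits(et_a, "enrichment_table"),
            inherits(et_b, "enrichment_table"))
  ma <- mean_scores(et_a); mb <- mean_scores(et_b)
  shared <- intersect(names(ma), names(mb))
  if (length(shared) == 0L) stop("no shared peptide ids between the tables")
  ratio <- log2(mb[shared] / ma[shared])
  out <- data.frame(id = shared, score_a = unname(ma[shared]),
                    score_b = unname(mb[shared]),
                    log2_ratio = unname(ratio),
                    flagged = !is.na(ratio) & is.finite(ratio) &
                      abs(ratio) > log2_threshold,
                    stringsAsFactors = FALSE)
  attr(out, "labels") <- c(a = et_a$domain_label, b = et_b$domain_label)
  attr(out, "excluded") <- c(setdiff(names(ma), shared),
                             setdiff(names(mb), shared))
  out
}
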