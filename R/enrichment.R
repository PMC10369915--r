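# Frequency-ratio enrichment scoring: counts -> frequencies -> per-peptide
# enrichment scores, replicate pooling, library concatenation, and the
# single-tyrosine filter.

#' Convert a count table to frequencies
#'
#' `freq_i = (count_i + pseudocount) / sum_j (count_j + pseudocount)`.
#' The default pseudocount of 1 read per peptide prevents division by zero
#' for selection dropouts while leaving well-sampled peptides essentially
#' unchanged; pseudocount 0 gives exact frequencies.
#'
#' @param ct A `count_table`.
#' @param pseudocount Non-negative pseudocount added to every peptide.
#' @return A `frequency_table`: list with `library_name`, `sample_label`,
#'   `freqs` (named numeric summing to 1), and `pseudocount`.
#' @export
frequencies <- function(ct, pseudocount = 1) {
  stopifnot(inherits(ct, "count_table"), pseudocount >= 0)
  if (ct$total_matched == 0L && pseudocount == 0) {
    stop("all counts are zero and pseudocount is zero")
  }
  adj <- ct$counts + pseudocount
  structure(
    list(library_name = ct$library_name, sample_label = ct$sample_label,
         freqs = adj / sum(adj), pseudocount = pseudocount),
    class = "frequency_table")
}

#' Construct an enrichment table
#'
#' Internal-facing constructor; most users build enrichment tables via
#' [enrichment_scores()] and [combine_enrichment()].
#'
#' @param scores Numeric matrix of per-replicate enrichment scores, rows
#'   named by peptide id, columns by replicate label. `NA` marks a peptide
#'   absent from a replicate (e.g. measured in a different library).
#' @param domain_label SH2 domain the screen was run with.
#' @param source_libraries Character vector of library names represented.
#' @param library_of Character vector giving, per row, the library each
#'   peptide belongs to.
#' @return An object of class `enrichment_table`.
#' @export
enrichment_table <- function(scores, domain_label, source_libraries,
                             library_of) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            length(library_of) == nrow(scores))
  if (any(scores < 0, na.rm = TRUE)) stop("enrichment scores must be >= 0")
  if (any(rowSums(!is.na(scores)) == 0L)) {
    stop("every peptide needs at least one replicate score")
  }
  structure(
    list(scores = scores, domain_label = domain_label,
         source_libraries = source_libraries,
         library_of = as.character(library_of)),
    class = "enrichment_table")
}

#' Mean enrichment score per peptide
#' @param et An `enrichment_table`.
#' @return Named numeric vector, arithmetic mean over available replicates.
#' @export
mean_scores <- function(et) {
  stopifnot(inherits(et, "enrichment_table"))
  rowMeans(et$scores, na.rm = TRUE)
}

#' Number of replicates per peptide
#' @param et An `enrichment_table`.
#' @return Named integer vector.
#' @export
n_replicates <- function(et) {
  stopifnot(inherits(et, "enrichment_table"))
  rowSums(!is.na(et$scores))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("enrichment_table '%s': %d peptides, %d replicate column(s), libraries: %s\n",
              x$domain_label, nrow(x$scores), ncol(x$scores),
              paste(x$source_libraries, collapse = ", ")))
  invisible(x)
}

#' Per-peptide enrichment scores from one selection replicate
#'
#' The enrichment score of a peptide is its frequency in the SH2-selected
#' sample divided by its frequency in the unselected input sample.
#'
#' @param input `frequency_table` for the unselected input sample.
#' @param selected `frequency_table` for the SH2-enriched sample.
#' @param domain_label SH2 domain label stored in the result.
#' @param replicate Replicate label; defaults to the selected sample label.
#' @return A single-replicate `enrichment_table`.
#' @export
enrichment_scores <- function(input, selected, domain_label = "SH2",
                              replicate = selected$sample_label) {
  stopifnot(inherits(input, "frequency_table"),
            inherits(selected, "frequency_table"))
  if (!identical(input$library_name, selected$library_name)) {
    stop("input and selected samples come from different libraries (",
         input$library_name, " vs ", selected$library_name, ")")
  }
  ids <- names(input$freqs)
  if (!identical(sort(ids), sort(names(selected$freqs)))) {
    stop("input and selected tables cover different peptide sets")
  }
  fin <- input$freqs[ids]
  if (any(fin == 0)) {
    stop("zero input frequency for ",
         sum(fin == 0), " peptide(s); use a positive pseudocount")
  }
  s <- selected$freqs[ids] / fin
  m <- matrix(s, ncol = 1L, dimnames = list(ids, replicate))
  enrichment_table(m, domain_label = domain_label,
                   source_libraries = input$library_name,
                   library_of = rep(input$library_name, length(ids)))
}

#' Pool replicates and concatenate libraries into one enrichment table
#'
#' Tables from the same library are pooled as replicates (ids must match);
#' tables from distinct libraries are concatenated by peptide id. The
#' per-peptide mean is the arithmetic mean over the replicates in which the
#' peptide was screened; a peptide present in one library only keeps its own
#' replicate count. With `multi_tyr_filter = TRUE` peptides containing more
#' than one tyrosine are dropped (tyrosine-free controls are retained for
#' cutoff calibration).
#'
#' @param tables List of `enrichment_table` objects sharing a domain label.
#' @param lib A `peptide_library` or list of them (needed for the tyrosine
#'   filter); may be `NULL` when `multi_tyr_filter = FALSE`.
#' @param multi_tyr_filter Drop peptides with > 1 tyrosine. Default `TRUE`.
#' @return A combined `enrichment_table`.
#' @export
combine_enrichment <- function(tables, lib = NULL, multi_tyr_filter = TRUE) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, logical(1), "enrichment_table")))
  labels <- unique(vapply(tables, `[[`, character(1), "domain_label"))
  if (length(labels) != 1L) {
    stop("conflicting domain labels: ", paste(labels, collapse = ", "))
  }
  by_lib <- split(tables, vapply(tables, function(t)
    paste(t$source_libraries, collapse = "+"), character(1)))

  pooled <- lapply(by_lib, function(ts) {
    ids <- rownames(ts[[1L]]$scores)
    for (t in ts[-1L]) {
      if (!identical(sort(rownames(t$scores)), sort(ids))) {
        stop("replicate tables within one library cover different peptides")
      }
    }
    scores <- do.call(cbind, lapply(ts, function(t) t$scores[ids, , drop = FALSE]))
    colnames(scores) <- make.unique(colnames(scores))
    list(scores = scores, library_of = ts[[1L]]$library_of)
  })

  all_ids <- unlist(lapply(pooled, function(p) rownames(p$scores)),
                    use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("peptide id collision across libraries: ",
         paste(utils::head(unique(all_ids[duplicated(all_ids)]), 5),
               collapse = ", "))
  }
  all_cols <- unlist(lapply(pooled, function(p) colnames(p$scores)),
                     use.names = FALSE)
  all_cols <- make.unique(all_cols)
  big <- matrix(NA_real_, nrow = length(all_ids), ncol = length(all_cols),
                dimnames = list(all_ids, all_cols))
  lib_of <- character(length(all_ids))
  names(lib_of) <- all_ids
  col_at <- 1L
  for (p in pooled) {
    nc <- ncol(p$scores)
    big[rownames(p$scores), col_at:(col_at + nc - 1L)] <- p$scores
    lib_of[rownames(p$scores)] <- p$library_of
    col_at <- col_at + nc
  }

  if (multi_tyr_filter) {
    if (is.null(lib)) stop("multi_tyr_filter requires the peptide library")
    libs <- if (inherits(lib, "peptide_library")) list(lib) else lib
    ntyr <- do.call(c, lapply(libs, tyrosine_counts))
    missing_ids <- setdiff(all_ids, names(ntyr))
    if (length(missing_ids) > 0L) {
      stop("peptides not found in any supplied library: ",
           paste(utils::head(missing_ids, 5), collapse = ", "))
    }
    keep <- all_ids[ntyr[all_ids] <= 1L]
    big <- big[keep, , drop = FALSE]
    lib_of <- lib_of[keep]
  }

  enrichment_table(big, domain_label = labels,
                   source_libraries = unique(unlist(lapply(tables, `[[`,
                                                           "source_libraries"))),
                   library_of = lib_of)
}
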