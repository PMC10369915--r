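# Peptide library definition, validation, FASTQ read counting, and
# TSV round-trip I/O for the tabular objects used throughout the pipeline.

#' Canonical amino-acid alphabet
#'
#' The 20 canonical single-letter amino-acid codes, alphabetically ordered.
#' Logo and scan matrices use this ordering for their columns.
#'
#' @return Character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

.valid_categories <- c("wildtype_site", "variant", "tyr_free_control", "scan_variant")

#' Construct and validate a peptide library
#'
#' A peptide library is the universe of displayed peptides in a specificity
#' screen: fixed-length sequences centred (usually) on a single tyrosine,
#' plus tyrosine-free negative controls used to calibrate the hit cutoff.
#'
#' @param entries Data frame with columns `id`, `peptide`, `category`, and
#'   optionally `phospho_index` (1-based position of the phosphotyrosine),
#'   `site_label`, and `coding_dna`.
#' @param name Library name.
#' @param peptide_length Expected peptide length; defaults to the length of
#'   the first peptide.
#' @param require_control Require at least one `tyr_free_control` entry
#'   (needed for cutoff calibration). Default `TRUE`.
#'
#' @details Validation enforces: unique ids; peptides drawn from the 20
#'   canonical amino acids; uniform length; `tyr_free_control` entries
#'   contain no tyrosine and no other category is tyrosine-free unless it
#'   carries no `phospho_index`; `peptide[phospho_index] == "Y"` when the
#'   index is given; and `coding_dna`, when given, translates to `peptide`.
#'   `phospho_index` is auto-filled for peptides with exactly one tyrosine.
#'
#' @return An object of class `peptide_library`.
#' @export
peptide_library <- function(entries, name = "library", peptide_length = NULL,
                            require_control = TRUE) {
  stopifnot(is.data.frame(entries))
  need <- c("id", "peptide", "category")
  miss <- setdiff(need, names(entries))
  if (length(miss) > 0L) {
    stop("library table is missing column(s): ", paste(miss, collapse = ", "))
  }
  entries$id <- as.character(entries$id)
  entries$peptide <- toupper(as.character(entries$peptide))
  entries$category <- as.character(entries$category)
  if (is.null(entries$phospho_index)) entries$phospho_index <- NA_integer_
  entries$phospho_index <- suppressWarnings(as.integer(entries$phospho_index))
  if (is.null(entries$site_label)) entries$site_label <- NA_character_
  if (is.null(entries$coding_dna)) entries$coding_dna <- NA_character_

  if (anyDuplicated(entries$id)) {
    dup <- unique(entries$id[duplicated(entries$id)])
    stop("duplicate peptide id(s): ", paste(dup, collapse = ", "))
  }
  bad_cat <- setdiff(unique(entries$category), .valid_categories)
  if (length(bad_cat) > 0L) {
    stop("unknown category value(s): ", paste(bad_cat, collapse = ", "))
  }
  alpha_ok <- grepl(sprintf("^[%s]+$", paste(aa_alphabet(), collapse = "")),
                    entries$peptide)
  if (!all(alpha_ok)) {
    stop("peptide contains non-canonical amino-acid letters for id(s): ",
         paste(entries$id[!alpha_ok], collapse = ", "))
  }
  if (is.null(peptide_length)) peptide_length <- nchar(entries$peptide[1L])
  len_ok <- nchar(entries$peptide) == peptide_length
  if (!all(len_ok)) {
    stop("peptide length != ", peptide_length, " for id(s): ",
         paste(entries$id[!len_ok], collapse = ", "))
  }

  n_tyr <- vapply(gregexpr("Y", entries$peptide, fixed = TRUE),
                  function(m) sum(m > 0L), integer(1))
  is_ctrl <- entries$category == "tyr_free_control"
  if (any(is_ctrl & n_tyr > 0L)) {
    stop("tyr_free_control entries contain tyrosine: ",
         paste(entries$id[is_ctrl & n_tyr > 0L], collapse = ", "))
  }

  # auto-fill the phospho index for unambiguous single-tyrosine peptides
  fill <- is.na(entries$phospho_index) & n_tyr == 1L
  entries$phospho_index[fill] <-
    vapply(gregexpr("Y", entries$peptide[fill], fixed = TRUE),
           function(m) as.integer(m[1L]), integer(1))
  has_pi <- !is.na(entries$phospho_index)
  if (any(has_pi & is_ctrl)) {
    stop("tyr_free_control entries cannot carry a phospho_index")
  }
  pi_ok <- !has_pi |
    (entries$phospho_index >= 1L & entries$phospho_index <= peptide_length &
       substr(entries$peptide, entries$phospho_index,
              entries$phospho_index) == "Y")
  if (!all(pi_ok)) {
    stop("phospho_index does not point at a tyrosine for id(s): ",
         paste(entries$id[!pi_ok], collapse = ", "))
  }

  has_dna <- !is.na(entries$coding_dna) & nzchar(entries$coding_dna)
  if (any(has_dna)) {
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(toupper(entries$coding_dna[has_dna])),
      no.init.codon = TRUE))
    ok <- tr == entries$peptide[has_dna]
    if (!all(ok)) {
      stop("coding_dna does not translate to peptide for id(s): ",
           paste(entries$id[has_dna][!ok], collapse = ", "))
    }
  }

  if (require_control && !any(is_ctrl)) {
    stop("library has no tyr_free_control entries; ",
         "cutoff calibration would be impossible")
  }

  structure(
    list(name = name,
         entries = entries[, c("id", "peptide", "phospho_index",
                               "category", "site_label", "coding_dna")],
         peptide_length = as.integer(peptide_length)),
    class = "peptide_library")
}

#' @export
print.peptide_library <- function(x, ...) {
  cat(sprintf("peptide_library '%s': %d entries, length %d\n",
              x$name, nrow(x$entries), x$peptide_length))
  print(table(x$entries$category))
  invisible(x)
}

#' Number of tyrosines per library peptide
#' @param lib A `peptide_library`.
#' @return Named integer vector (names are peptide ids).
#' @export
tyrosine_counts <- function(lib) {
  stopifnot(inherits(lib, "peptide_library"))
  n <- vapply(gregexpr("Y", lib$entries$peptide, fixed = TRUE),
              function(m) sum(m > 0L), integer(1))
  stats::setNames(n, lib$entries$id)
}

#' Read a peptide library from a TSV file
#'
#' @param path Path to a tab-separated file with a header line and columns
#'   `id`, `peptide`, `category` (plus optional `phospho_index`,
#'   `site_label`, `coding_dna`). Lines starting with `#` are metadata and
#'   are skipped.
#' @param name Library name; defaults to the file name.
#' @inheritParams peptide_library
#' @return A `peptide_library`.
#' @export
read_peptide_library <- function(path, name = NULL, require_control = TRUE) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  peptide_library(df, name = name, require_control = require_control)
}

#' Describe where the peptide-coding region sits within a read
#'
#' @param offset Number of bases preceding the coding region (0 = the read
#'   starts in frame at the first codon).
#' @param length Length of the coding region in bases; `NULL` means
#'   "to the end of the read" and is resolved against the library
#'   (3 x peptide length) at counting time.
#' @return An object of class `read_layout`.
#' @export
read_layout <- function(offset = 0L, length = NULL) {
  offset <- as.integer(offset)
  stopifnot(offset >= 0L)
  if (!is.null(length)) {
    length <- as.integer(length)
    stopifnot(length > 0L, length %% 3L == 0L)
  }
  structure(list(offset = offset, length = length), class = "read_layout")
}

#' Construct a count table
#'
#' @param counts Named non-negative integer vector over (a subset of)
#'   library peptide ids; ids absent from `counts` get 0.
#' @param lib The `peptide_library` the counts refer to.
#' @param sample_label Sample name, e.g. `"input"` or `"selected_rep1"`.
#' @param total_reads Total reads processed; defaults to `sum(counts)`.
#' @param discarded Named integer vector of discard reasons.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, lib, sample_label,
                        total_reads = NULL, discarded = integer(0)) {
  stopifnot(inherits(lib, "peptide_library"))
  ids <- lib$entries$id
  bad <- setdiff(names(counts), ids)
  if (length(bad) > 0L) {
    stop("counts contain ids not in library '", lib$name, "': ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  full <- stats::setNames(integer(length(ids)), ids)
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0L)) stop("negative counts are not allowed")
  total_matched <- sum(full)
  discarded <- stats::setNames(as.integer(discarded), names(discarded))
  if (is.null(total_reads)) total_reads <- total_matched + sum(discarded)
  total_reads <- as.integer(total_reads)
  if (total_matched + sum(discarded) != total_reads) {
    stop("total_reads must equal total_matched + sum(discarded)")
  }
  structure(
    list(library_name = lib$name, sample_label = sample_label,
         counts = full, total_matched = total_matched,
         total_reads = total_reads, discarded = discarded),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table '%s' [%s]: %d matched / %d reads\n",
              x$sample_label, x$library_name, x$total_matched, x$total_reads))
  if (length(x$discarded) > 0L) {
    cat("discarded:",
        paste(sprintf("%s=%d", names(x$discarded), x$discarded),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Count FASTQ reads against a peptide library
#'
#' Each read is sliced at the coding region given by `layout`, translated in
#' frame, and counted iff the translated peptide exactly matches a library
#' peptide. Reads with ambiguous bases in the coding region, stop codons, or
#' no exact library match are tallied under `discarded` with reasons
#' `ambiguous_base`, `stop_codon`, and `no_match`. Phred qualities are
#' ignored.
#'
#' @param fastq Path to a FASTQ file (4-line records).
#' @param lib A `peptide_library`.
#' @param layout A `read_layout`; the default takes the whole read in
#'   frame 0, using 3 x peptide length bases.
#' @param sample_label Sample name recorded in the result.
#' @return A `count_table`.
#' @export
count_reads <- function(fastq, lib, layout = read_layout(),
                        sample_label = basename(fastq)) {
  stopifnot(inherits(lib, "peptide_library"), inherits(layout, "read_layout"))
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  len <- layout$length
  if (is.null(len)) len <- 3L * lib$peptide_length
  if (len != 3L * lib$peptide_length) {
    stop("coding-region length (", len, ") does not encode a ",
         lib$peptide_length, "-residue peptide")
  }
  if (length(reads) == 0L) {
    return(count_table(integer(0), lib, sample_label, total_reads = 0L))
  }
  if (any(Biostrings::width(reads) < layout$offset + len)) {
    stop("coding region (offset ", layout$offset, ", length ", len,
         ") extends past the end of at least one read")
  }
  region <- as.character(Biostrings::subseq(reads, start = layout$offset + 1L,
                                            width = len))
  ambiguous <- grepl("[^ACGT]", region)
  pep <- rep(NA_character_, length(region))
  if (any(!ambiguous)) {
    pep[!ambiguous] <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(region[!ambiguous]), no.init.codon = TRUE))
  }
  has_stop <- !ambiguous & grepl("*", pep, fixed = TRUE)
  candidate <- !ambiguous & !has_stop
  matched <- candidate & pep %in% lib$entries$peptide

  # collapse synonymous codons: count by translated peptide, map to ids
  pep2id <- stats::setNames(lib$entries$id, lib$entries$peptide)
  tab <- table(pep2id[pep[matched]])
  counts <- stats::setNames(as.integer(tab), names(tab))
  discarded <- c(ambiguous_base = sum(ambiguous),
                 stop_codon = sum(has_stop),
                 no_match = sum(candidate & !matched))
  discarded <- discarded[discarded > 0L]
  count_table(counts, lib, sample_label,
              total_reads = length(reads), discarded = discarded)
}

# ---- TSV round-trip I/O ----------------------------------------------------

.meta_line <- function(key, value) sprintf("# %s: %s", key, value)

.write_tsv <- function(df, path, meta = character(0)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(.meta_line("tool", paste0("sh2profiler ",
                                       as.character(utils::packageVersion("sh2profiler")))),
             con)
  for (k in names(meta)) writeLines(.meta_line(k, meta[[k]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.read_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
  out <- list()
  for (m in kv) if (length(m) == 3L) out[[trimws(m[2L])]] <- m[3L]
  out
}

.read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a pipeline object to a tab-separated file
#'
#' All tabular pipeline objects are written as TSV with `#`-prefixed
#' metadata lines (tool version and the fields needed to reconstruct the
#' object) followed by a header line. Each type round-trips losslessly
#' through the matching `read_*` function.
#'
#' @param x Object to write.
#' @param path Output path.
#' @param ... Passed to methods.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, ...) UseMethod("write_table")

#' @export
write_table.peptide_library <- function(x, path, ...) {
  .write_tsv(x$entries, path,
             meta = c(type = "peptide_library", name = x$name,
                      peptide_length = x$peptide_length))
}

#' @export
write_table.count_table <- function(x, path, ...) {
  df <- data.frame(id = names(x$counts), count = unname(x$counts),
                   stringsAsFactors = FALSE)
  disc <- if (length(x$discarded) == 0L) "" else
    paste(sprintf("%s=%d", names(x$discarded), x$discarded), collapse = ";")
  .write_tsv(df, path,
             meta = c(type = "count_table", library_name = x$library_name,
                      sample_label = x$sample_label,
                      total_reads = x$total_reads, discarded = disc))
}

#' Read a count table written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @param lib The `peptide_library` the counts refer to.
#' @return A `count_table`.
#' @export
read_count_table <- function(path, lib) {
  meta <- .read_meta(path)
  df <- .read_tsv(path)
  discarded <- integer(0)
  if (!is.null(meta$discarded) && nzchar(meta$discarded)) {
    parts <- strsplit(meta$discarded, ";", fixed = TRUE)[[1L]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    discarded <- stats::setNames(vapply(kv, function(p) as.integer(p[2L]),
                                        integer(1)),
                                 vapply(kv, `[`, character(1), 1L))
  }
  ct <- count_table(stats::setNames(df$count, df$id), lib,
                    sample_label = meta$sample_label,
                    total_reads = as.integer(meta$total_reads),
                    discarded = discarded)
  if (!identical(ct$library_name, meta$library_name)) {
    stop("file was written for library '", meta$library_name,
         "', not '", lib$name, "'")
  }
  ct
}

#' @export
write_table.enrichment_table <- function(x, path, ...) {
  df <- data.frame(id = rownames(x$scores), x$scores,
                   mean_score = mean_scores(x),
                   n_replicates = n_replicates(x),
                   library_name = x$library_of,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path,
             meta = c(type = "enrichment_table", domain_label = x$domain_label,
                      replicates = paste(colnames(x$scores), collapse = ";"),
                      source_libraries = paste(x$source_libraries,
                                               collapse = ";")))
}

#' Read an enrichment table written by [write_table()]
#'
#' @param path Path to the TSV file.
#' @return An `enrichment_table`.
#' @export
read_enrichment_table <- function(path) {
  meta <- .read_meta(path)
  df <- .read_tsv(path)
  rep_cols <- strsplit(meta$replicates, ";", fixed = TRUE)[[1L]]
  scores <- as.matrix(df[, rep_cols, drop = FALSE])
  rownames(scores) <- df$id
  enrichment_table(scores, domain_label = meta$domain_label,
                   source_libraries = strsplit(meta$source_libraries, ";",
                                               fixed = TRUE)[[1L]],
                   library_of = df$library_name)
}

#' @export
write_table.hit_set <- function(x, path, ...) {
  df <- data.frame(id = sort(x$hit_ids), stringsAsFactors = FALSE)
  .write_tsv(df, path,
             meta = c(type = "hit_set", domain_label = x$domain_label,
                      cutoff = format(x$cutoff, digits = 17),
                      control_fpr_at_cutoff =
                        format(x$control_fpr_at_cutoff, digits = 17)))
}

#' Read a hit set written by [write_table()]
#' @param path Path to the TSV file.
#' @return A `hit_set`.
#' @export
read_hit_set <- function(path) {
  meta <- .read_meta(path)
  df <- .read_tsv(path)
  structure(list(domain_label = meta$domain_label,
                 cutoff = as.numeric(meta$cutoff),
                 hit_ids = as.character(df$id),
                 control_fpr_at_cutoff =
                   as.numeric(meta$control_fpr_at_cutoff)),
            class = "hit_set")
}

#' @export
write_table.logo_matrix <- function(x, path, ...) {
  df <- data.frame(position = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path,
             meta = c(type = "logo_matrix",
                      pseudocount = format(x$pseudocount, digits = 17),
                      base = format(x$base, digits = 17),
                      n_enriched = x$n_enriched, n_library = x$n_library))
}

#' Read a logo matrix written by [write_table()]
#' @param path Path to the TSV file.
#' @return A `logo_matrix`.
#' @export
read_logo_matrix <- function(path) {
  meta <- .read_meta(path)
  df <- .read_tsv(path)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$position
  structure(list(values = values,
                 positions = as.integer(df$position),
                 pseudocount = as.numeric(meta$pseudocount),
                 base = as.numeric(meta$base),
                 n_enriched = as.integer(meta$n_enriched),
                 n_library = as.integer(meta$n_library)),
            class = "logo_matrix")
}

#' @export
write_table.scan_matrix <- function(x, path, ...) {
  df <- data.frame(position = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path,
             meta = c(type = "scan_matrix", wt_peptide = x$wt_peptide,
                      wt_id = x$wt_id))
}

#' Read a scan matrix written by [write_table()]
#' @param path Path to the TSV file.
#' @return A `scan_matrix`.
#' @export
read_scan_matrix <- function(path) {
  meta <- .read_meta(path)
  df <- .read_tsv(path)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df$position
  structure(list(values = values, wt_peptide = meta$wt_peptide,
                 wt_id = meta$wt_id,
                 missing = is.na(values)),
            class = "scan_matrix")
}
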