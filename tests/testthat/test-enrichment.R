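# Frequency and enrichment-score arithmetic, replicate pooling, and the
# multi-tyrosine filter.

test_that("frequencies implement the pseudocount rule", {
  lib <- peptide_library(data.frame(
    id = c("A", "B"), peptide = c("VDAGEYDFAHA", "LNHTPYINASL"),
    category = "wildtype_site", stringsAsFactors = FALSE),
    require_control = FALSE)
  f0 <- frequencies(ct_from_counts(c(A = 90L, B = 10L), lib), 0)
  expect_equal(unname(f0$freqs[c("A", "B")]), c(0.9, 0.1))
  f1 <- frequencies(ct_from_counts(c(A = 0L, B = 10L), lib), 1)
  expect_equal(unname(f1$freqs[c("A", "B")]), c(1 / 12, 11 / 12))
  expect_equal(sum(f1$freqs), 1, tolerance = 1e-12)
  expect_error(frequencies(ct_from_counts(c(A = 0L, B = 0L), lib), 0),
               "zero")
})

test_that("enrichment scores are frequency ratios with the documented dropout value", {
  lib <- peptide_library(data.frame(
    id = c("A", "B"), peptide = c("VDAGEYDFAHA", "LNHTPYINASL"),
    category = "wildtype_site", stringsAsFactors = FALSE),
    require_control = FALSE)
  fin <- frequencies(ct_from_counts(c(A = 50L, B = 50L), lib), 0)
  fsel <- frequencies(ct_from_counts(c(A = 90L, B = 10L), lib), 0)
  s <- mean_scores(enrichment_scores(fin, fsel))
  expect_equal(unname(s[c("A", "B")]), c(1.8, 0.2))

  # identical tables give scores of exactly 1
  expect_equal(unname(mean_scores(enrichment_scores(fin, fin))), c(1, 1))

  # dropout with pseudocount 1 at depth 100/100 in a 2-peptide library:
  # ((0+1)/102) / ((50+1)/102) = 1/51
  fin1 <- frequencies(ct_from_counts(c(A = 50L, B = 50L), lib), 1)
  fsel1 <- frequencies(ct_from_counts(c(A = 0L, B = 100L), lib), 1)
  s1 <- mean_scores(enrichment_scores(fin1, fsel1))
  expect_equal(unname(s1["A"]), 1 / 51, tolerance = 1e-12)

  # library mismatch is an error
  lib2 <- peptide_library(data.frame(
    id = c("A", "B"), peptide = c("VDAGEYDFAHA", "LNHTPYINASL"),
    category = "wildtype_site", stringsAsFactors = FALSE),
    name = "other", require_control = FALSE)
  fother <- frequencies(ct_from_counts(c(A = 1L, B = 1L), lib2), 1)
  expect_error(enrichment_scores(fin, fother), "different libraries")
})

test_that("score properties: depth invariance and frequency conservation", {
  lib <- make_fixture_library(30, 8, 11, seed = 4)
  ids <- lib$entries$id
  set.seed(42)
  for (i in 1:20) {
    cin <- stats::setNames(stats::rmultinom(1, 2000, runif(38))[, 1], ids)
    csel <- stats::setNames(stats::rmultinom(1, 2000, runif(38))[, 1], ids)
    cin[cin == 0] <- 1L; csel[csel == 0] <- 1L   # pc = 0 needs support
    fin <- frequencies(ct_from_counts(cin, lib), 0)
    fsel <- frequencies(ct_from_counts(csel, lib), 0)
    s <- mean_scores(enrichment_scores(fin, fsel))
    # doubling all counts leaves scores unchanged at pseudocount 0
    fin2 <- frequencies(ct_from_counts(2L * cin, lib), 0)
    fsel2 <- frequencies(ct_from_counts(2L * csel, lib), 0)
    s2 <- mean_scores(enrichment_scores(fin2, fsel2))
    expect_equal(s, s2, tolerance = 1e-12)
    # sum_i input_freq_i * score_i = 1
    expect_equal(sum(fin$freqs[names(s)] * s), 1, tolerance = 1e-9)
  }
})

test_that("combine pools replicates, concatenates libraries, and filters multi-Tyr", {
  libA <- peptide_library(data.frame(
    id = c("a1", "a2", "a2y", "ac"),
    peptide = c("VDAGEYDFAHA", "LNHTPYINASL", "YNHTPYINASL", "ALVSEFHELQP"),
    category = c("wildtype_site", "wildtype_site", "variant",
                 "tyr_free_control"),
    stringsAsFactors = FALSE), name = "libA")
  libB <- peptide_library(data.frame(
    id = c("b1", "bc"),
    peptide = c("ALVSEYHELQP", "GNASPFHELQP"),
    category = c("wildtype_site", "tyr_free_control"),
    stringsAsFactors = FALSE), name = "libB")

  mkA <- function(sel, rep) {
    fin <- frequencies(ct_from_counts(
      c(a1 = 100L, a2 = 100L, a2y = 100L, ac = 100L), libA), 1)
    fsel <- frequencies(ct_from_counts(sel, libA), 1)
    enrichment_scores(fin, fsel, "N-SH2 WT", rep)
  }
  etA1 <- mkA(c(a1 = 200L, a2 = 100L, a2y = 50L, ac = 50L), "rep1")
  etA2 <- mkA(c(a1 = 400L, a2 = 100L, a2y = 50L, ac = 50L), "rep2")
  finB <- frequencies(ct_from_counts(c(b1 = 100L, bc = 100L), libB), 1)
  etB <- enrichment_scores(
    finB, frequencies(ct_from_counts(c(b1 = 150L, bc = 50L), libB), 1),
    "N-SH2 WT", "rep1")

  comb <- combine_enrichment(list(etA1, etA2, etB),
                             lib = list(libA, libB))
  # multi-tyrosine a2y dropped, controls kept: 4 + 2 - 1 = 5 peptides
  expect_setequal(rownames(comb$scores), c("a1", "a2", "ac", "b1", "bc"))
  # mean over replicates, and per-library replicate counts preserved
  expect_equal(unname(mean_scores(comb)["a1"]),
               mean(c(mean_scores(etA1)["a1"], mean_scores(etA2)["a1"])))
  expect_equal(unname(n_replicates(comb)[c("a1", "b1")]), c(2L, 1L))

  # two replicates 2.0 and 4.0 average to 3.0
  m <- matrix(c(2, 4), nrow = 1, dimnames = list("p", c("r1", "r2")))
  et <- enrichment_table(m, "X", "L", "L")
  expect_equal(unname(mean_scores(et)), 3)
  expect_equal(unname(n_replicates(et)), 2L)

  # conflicting domain labels refuse to combine
  etB2 <- etB; etB2$domain_label <- "N-SH2 T42A"
  expect_error(combine_enrichment(list(etA1, etB2), lib = list(libA, libB)),
               "domain labels")

  # id collisions across libraries are an error
  libB_dup <- peptide_library(data.frame(
    id = c("a1", "bc"),
    peptide = c("ALVSEYHELQP", "GNASPFHELQP"),
    category = c("wildtype_site", "tyr_free_control"),
    stringsAsFactors = FALSE), name = "libBdup")
  finD <- frequencies(ct_from_counts(c(a1 = 10L, bc = 10L), libB_dup), 1)
  etD <- enrichment_scores(finD, finD, "N-SH2 WT", "rep1")
  expect_error(combine_enrichment(list(etA1, etD),
                                  lib = list(libA, libB_dup)),
               "collision")
})
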