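# Cutoff calibration on controls, hit calling, overlaps, logo and scan
# matrices, and paired domain comparisons.

# enrichment table straight from given mean scores (one replicate)
et_from_scores <- function(scores, lib, label = "N-SH2 WT") {
  m <- matrix(scores, ncol = 1, dimnames = list(names(scores), "rep1"))
  enrichment_table(m, label, lib$name, rep(lib$name, length(scores)))
}

test_that("cutoff calibration picks the smallest score meeting the control fraction", {
  # 100 controls scoring 1..100 plus a handful of sites
  ent <- make_fixture_library(5, 100, 11, seed = 9)
  scores <- stats::setNames(c(rep(5, 5), 1:100), ent$entries$id)
  et <- et_from_scores(scores, ent)
  # exactly 2 of 100 controls above 98
  expect_equal(calibrate_cutoff(et, ent, max_control_fraction = 0.02), 98)
  expect_lte(control_fpr(et, ent, 98), 0.02)

  # all controls at zero: the configured floor is returned
  et0 <- et_from_scores(stats::setNames(c(rep(5, 5), rep(0, 100)),
                                        ent$entries$id), ent)
  expect_equal(calibrate_cutoff(et0, ent, 0.02), 0)
  expect_equal(calibrate_cutoff(et0, ent, 0.02, floor = 0.5), 0.5)

  lib_noctrl <- peptide_library(
    ent$entries[ent$entries$category != "tyr_free_control", ],
    require_control = FALSE)
  expect_error(calibrate_cutoff(et, lib_noctrl, 0.02), "control")
})

test_that("hit calling is strict, excludes controls, and is antitone in the cutoff", {
  lib <- peptide_library(data.frame(
    id = c("p1", "p2", "p3", "c1"),
    peptide = c("VDAGEYDFAHA", "LNHTPYINASL", "ALVSEYHELQP", "ALVSEFHELQP"),
    category = c(rep("wildtype_site", 3), "tyr_free_control"),
    stringsAsFactors = FALSE))
  et <- et_from_scores(c(p1 = 4.0, p2 = 3.2, p3 = 1.0, c1 = 9.0), lib)
  hits <- call_hits(et, lib, 3.2)
  # strictly greater: the boundary peptide p2 and the control c1 are out
  expect_setequal(hits$hit_ids, "p1")
  expect_setequal(call_hits(et, lib, 0)$hit_ids, c("p1", "p2", "p3"))

  # antitone: higher cutoff yields a subset, for random score tables
  lib2 <- make_fixture_library(40, 10, 11, seed = 3)
  set.seed(17)
  for (i in 1:10) {
    sc <- stats::setNames(rexp(50, 1 / 2), lib2$entries$id)
    et2 <- et_from_scores(sc, lib2)
    cuts <- sort(runif(3, 0, 6))
    h <- lapply(cuts, function(c) call_hits(et2, lib2, c)$hit_ids)
    expect_true(all(h[[2]] %in% h[[1]]))
    expect_true(all(h[[3]] %in% h[[2]]))
  }

  # per-replicate mode requires every replicate above the cutoff
  m <- matrix(c(4, 2, 4, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("p1", "p2"), c("r1", "r2")))
  et3 <- enrichment_table(m, "X", lib$name, rep(lib$name, 2))
  expect_setequal(call_hits(et3, lib, 3, mode = "all_replicates")$hit_ids,
                  "p2")
  expect_setequal(call_hits(et3, lib, 2.9, mode = "mean")$hit_ids,
                  c("p1", "p2"))
})

test_that("hit overlaps decompose exactly", {
  o <- hit_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(unname(o$regions[c("A", "A&B", "B")]), c(1L, 2L, 1L))
  expect_equal(sum(o$regions), o$union_size)

  ident <- hit_overlap(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(unname(ident$regions[["X&Y"]]), 2L)
  expect_equal(length(ident$regions), 1L)

  disj <- hit_overlap(list(X = "a", Y = "b"))
  expect_false("X&Y" %in% names(disj$regions))
  expect_equal(sum(disj$regions), 2L)
})

test_that("logo matrix identity, exact ratios, and pseudocount arithmetic", {
  lib <- make_fixture_library(60, 10, 11, seed = 21)
  site_ids <- lib$entries$id[lib$entries$category == "wildtype_site"]
  # enriched set = entire library: all values are exactly 0, any pseudocount
  for (pc in c(0, 1, 2.5)) {
    lg <- logo_matrix(site_ids, lib, pseudocount = pc)
    expect_equal(max(abs(lg$values)), 0)
  }

  # hand-built: residue at twice its library frequency, pc 0 -> +1.0
  lib2 <- peptide_library(data.frame(
    id = c("h1", "h2", "n1", "n2", "c1"),
    peptide = c("AAAVAYAAAAA", "AAAVAYAAAAA", "AAALAYAAAAA", "AAAIAYAAAAA",
                "AAALAFAAAAA"),
    category = c(rep("wildtype_site", 4), "tyr_free_control"),
    stringsAsFactors = FALSE))
  # -2 position: V in 2/4 library peptides; hits {h1,h2} have V in 2/2
  lg2 <- logo_matrix(c("h1", "h2"), lib2, pseudocount = 0, positions = -2)
  expect_equal(lg2$values["-2", "V"], log2((2 / 2) / (2 / 4)), tolerance = 1e-12)
  # residue absent from hits with pc > 0: value from the stated formula
  lg3 <- logo_matrix(c("h1", "h2"), lib2, pseudocount = 1, positions = -2)
  expected_L <- log2((0 + 1) / (2 + 20)) - log2((1 + 1) / (4 + 20))
  expect_equal(lg3$values["-2", "L"], expected_L, tolerance = 1e-12)

  # per-position reweighted identity: sum_aa f_lib * base^value = 1
  # recompute library frequencies under the same scheme to check the identity
  lg4 <- logo_matrix(c("h1", "h2"), lib2, pseudocount = 1, positions = -2:2)
  pc <- 1
  for (p in rownames(lg4$values)) {
    pos <- as.integer(p)
    res <- substr(lib2$entries$peptide[1:4], 6 + pos, 6 + pos)
    n <- table(factor(res, levels = aa_alphabet()))
    fl <- (as.numeric(n) + pc) / (4 + 20 * pc)
    expect_equal(sum(fl * 2^lg4$values[p, ]), 1, tolerance = 1e-9)
  }

  expect_error(logo_matrix(character(0), lib2), "empty")
})

test_that("logo recovers the sign pattern of a position-weight generating model", {
  lib <- make_fixture_library(400, 40, 11, seed = 31)
  effects <- list(`-2` = c(V = 6), `1` = c(A = 5), `2` = c(E = 4, W = 0.2))
  w <- pwm_screen_weights(lib, effects)
  truth <- screen_truth(w, 2e6, 2e6, seed = 32)
  sim <- simulate_screen(lib, truth)
  et <- enrichment_scores(frequencies(sim$input, 1),
                          frequencies(sim$selected, 1))
  cutoff <- calibrate_cutoff(et, lib, 0.02)
  hits <- call_hits(et, lib, cutoff)
  expect_gt(length(hits$hit_ids), 10)
  lg <- logo_matrix(hits, lib, pseudocount = 1)
  expect_gt(lg$values["-2", "V"], 0)
  expect_gt(lg$values["1", "A"], 0)
  expect_gt(lg$values["2", "E"], 0)
  expect_lt(lg$values["2", "W"], 0)
})

test_that("scan matrix is zero at wild-type cells and log2-ratios variants", {
  wt <- "VDSVDYGELDF"
  aa <- aa_alphabet()
  variants <- data.frame(id = "wt", peptide = wt,
                         category = "scan_variant",
                         stringsAsFactors = FALSE)
  for (pos in c(4, 8)) {  # -2 and +2 relative to the Tyr at index 6
    for (a in setdiff(aa, c(substr(wt, pos, pos), "Y"))) {
      v <- wt
      substr(v, pos, pos) <- a
      variants <- rbind(variants,
                        data.frame(id = sprintf("v%d%s", pos, a), peptide = v,
                                   category = "scan_variant",
                                   stringsAsFactors = FALSE))
    }
  }
  lib <- peptide_library(variants, name = "scan", require_control = FALSE)
  sc <- stats::setNames(rep(2, nrow(variants)), variants$id)
  sc["wt"] <- 2
  sc["v4A"] <- 8    # 4x wild type -> +2
  sc["v8E"] <- 2    # equal -> 0
  sc["v8W"] <- 0.5  # 1/4 -> -2
  et <- et_from_scores(sc, lib)
  sm <- scan_matrix(et, lib, "wt")
  expect_equal(sm$values["-2", "V"], 0)   # wild-type residue cell
  expect_equal(sm$values["2", "G"], 0)    # wild-type residue cell
  expect_equal(sm$values["-2", "A"], 2)
  expect_equal(sm$values["2", "E"], 0)
  expect_equal(sm$values["2", "W"], -2)
  # unmeasured positions are flagged missing, not imputed
  expect_true(all(is.na(sm$values["-5", setdiff(aa, "V")])))
  expect_true(sm$missing["-5", "A"])

  # input-count floor masks poorly sampled variants
  cts <- stats::setNames(rep(100L, nrow(variants)), variants$id)
  cts["v4A"] <- 1L
  ict <- count_table(cts, lib, "input")
  sm2 <- scan_matrix(et, lib, "wt", input_counts = ict, min_input_count = 10)
  expect_true(is.na(sm2$values["-2", "A"]))

  et0 <- et_from_scores(stats::setNames(c(0, rep(1, nrow(variants) - 1)),
                                        variants$id), lib)
  expect_error(scan_matrix(et0, lib, "wt"), "score")
})

test_that("domain comparison flags disproportionate enrichment", {
  lib <- make_fixture_library(10, 2, 11, seed = 8)
  ids <- lib$entries$id
  sa <- stats::setNames(rep(2, 12), ids)
  et_a <- et_from_scores(sa, lib, "N-SH2 WT")
  et_b <- et_from_scores(sa, lib, "N-SH2 T42A")
  cmp <- compare_domains(et_a, et_b)
  expect_true(all(cmp$log2_ratio == 0))
  expect_false(any(cmp$flagged))

  sb <- sa; sb[ids[1]] <- 20
  et_b2 <- et_from_scores(sb, lib, "N-SH2 T42A")
  cmp2 <- compare_domains(et_a, et_b2, log2_threshold = 1)
  expect_equal(cmp2$id[cmp2$flagged], ids[1])

  # a peptide present in only one table is excluded and reported
  et_a3 <- et_from_scores(sa[-1], lib, "N-SH2 WT")
  cmp3 <- compare_domains(et_a3, et_b2)
  expect_false(ids[1] %in% cmp3$id)
  expect_true(ids[1] %in% attr(cmp3, "excluded"))
})
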