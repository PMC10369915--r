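#!/usr/bin/env Rscript
# Simulate a bacterial-display selection screen with known ground truth:
# a fixture library of single-tyrosine 11-mers plus tyrosine-free controls,
# selection weights from a position-weight model (the kind of preferences an
# SH2 domain imposes), one round of affinity-weighted selection, and
# multinomial sequencing of input and selected pools (two replicates).
# Writes the library, count tables, and the truth sidecar under results/.

suppressMessages(library(sh2profiler))

seed <- 20L
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lib <- make_fixture_library(n_sites = 400, n_controls = 40,
                            peptide_length = 11, seed = seed,
                            name = "fixture400")
write_table(lib, file.path(out, "library.tsv"))

# favoured / disfavoured residues around the phosphotyrosine: -2 Val,
# +1 Ala favoured; +2 Glu favoured, +2 Trp disfavoured (a T42A-like profile)
effects <- list(`-2` = c(V = 6), `1` = c(A = 5), `2` = c(E = 4, W = 0.2))
w <- pwm_screen_weights(lib, effects)

for (rep in 1:2) {
  sim <- simulate_screen(lib, screen_truth(w, 2e6, 2e6, seed = seed + rep))
  write_table(sim$input, file.path(out, sprintf("counts_input_rep%d.tsv", rep)))
  write_table(sim$selected,
              file.path(out, sprintf("counts_selected_rep%d.tsv", rep)))
}
jsonlite::write_json(
  list(seed = seed, depth = 2e6, effects = effects,
       weights = as.list(round(w, 6))),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

message("library: ", nrow(lib$entries), " peptides (",
        sum(lib$entries$category == "tyr_free_control"),
        " tyrosine-free controls); 2 replicate screens at depth 2e6")
message("wrote ", out, "/")
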