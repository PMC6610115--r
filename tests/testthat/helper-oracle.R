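# Test helpers. The exhaustive-alignment oracle ships with the installed
# package (inst/oracle/) so the acceptance script can reuse it; it is
# sourced here into the test environment.

source(system.file("oracle", "alignment_oracle.R", package = "tripletOrigin"))

random_proteome <- function(species, n, len = 50L, prefix = species) {
  proteome(species, sprintf("%s_g%03d", prefix, seq_len(n)),
           vapply(seq_len(n), function(i)
             sample_root_sequence(len), ""))
}

# truth labels at family granularity
family_truth <- function(truth) unique(truth[c("family_id", "label")])

# the synthetic meiosis-toolkit plan mirroring a nonmotile microalga whose
# genome lacks Hop1, Dmc1 and Mnd1, and whose Rec8 slot is occupied by a
# Rad21-like mitotic cohesin (decoy); 5 of the 8 meiosis-specific genes
# are present
meiosis_plan <- function() {
  data.frame(
    gene = c("Spo11-2", "Mer3", "Hop1", "Dmc1", "Hop2", "Mnd1",
             "Msh4", "Msh5"),
    present = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, TRUE),
    decoy_distance = NA_real_,
    category = "meiosis")
}

rec8_plan <- function(decoy_distance = 1.0) {
  data.frame(gene = "Rec8", present = FALSE,
             decoy_distance = decoy_distance, category = "meiosis")
}
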