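#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic world the analysis runs on -- a true
# species tree, its family-level backbone, the two-plot community, and one
# candidate topology set per barcode x backbone condition (emulating
# posterior topology samples from the fourteen supermatrix analyses).
#
# Writes results/analysis/: true_tree.nwk, backbone.nwk,
# species_families.csv, community.csv, candidates_<condition>.nwk.

suppressMessages(library(barcodiv))

seed <- 20260927
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# Reduced problem size so every stage runs in about a minute: the full
# design (114 species, 500 of 1000 candidate trees per condition) has the
# same structure, just more of it.
sc <- synth_config(n_species = 20, richness = c(13, 12), shared = 6,
                   n_families = 8, trees_per_condition = 20,
                   n_candidates = 40, seed = seed)

truth <- simulate_true_tree(sc$n_species, stage_seed(seed, "truth"))
families <- assign_families(truth, sc$n_families)
backbone <- condense_to_families(truth, families)
community <- simulate_communities(truth, sc, stage_seed(seed, "community"))

write_newick(truth, file.path(out, "true_tree.nwk"))
write_newick(backbone, file.path(out, "backbone.nwk"))
write.csv(families, file.path(out, "species_families.csv"), row.names = FALSE)
write_community(community, file.path(out, "community.csv"))

conds <- enumerate_conditions()
for (i in seq_len(nrow(conds))) {
  cond <- unlist(conds[i, ])
  cand <- simulate_topology_set(
    truth, cond, n_trees = sc$n_candidates,
    intensity = condition_intensity(cond, sc),
    length_mult = condition_length_mult(cond, sc),
    jitter_sd = sc$jitter_sd,
    seed = stage_seed(seed, paste0("topo", i)),
    family_map = families)
  write_newick(cand$trees,
               file.path(out, sprintf("candidates_%s.nwk",
                                      condition_tag(cond))))
}

cat("Simulated", sc$n_species, "species,", nrow(conds),
    "conditions x", sc$n_candidates, "candidate trees;",
    "plot richness", paste(rowSums(community > 0), collapse = "/"),
    "with", sum(community[1, ] > 0 & community[2, ] > 0),
    "shared species.\n")
cat("Outputs in", out, "\n")
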