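#!/usr/bin/env Rscript
# Stage 2: topology selection. Conditions without the backbone constraint
# are ranked by Robinson-Foulds distance to the family-level backbone
# (species trees condensed to one exemplar per family first) and the top k
# kept; backbone-constrained conditions, whose family structure already
# matches the backbone exactly, get a random sample of k. Clade support
# (the node posterior-probability estimate) is tabulated per selected set.
#
# Reads results/analysis/ from stage 1; writes selected_<condition>.nwk,
# rf_<condition>.csv (ranked conditions), clade_support_<condition>.csv.

suppressMessages(library(barcodiv))

seed <- 20260927
out <- "results/analysis"
topk <- 20

backbone <- parse_newick(file.path(out, "backbone.nwk"))[[1]]
families <- read.csv(file.path(out, "species_families.csv"))

conds <- enumerate_conditions()
for (i in seq_len(nrow(conds))) {
  cond <- unlist(conds[i, ])
  tag <- condition_tag(cond)
  cand <- parse_newick(file.path(out, sprintf("candidates_%s.nwk", tag)))
  sel <- if (cond[["backbone"]]) {
    random_select(cand, topk, seed = stage_seed(seed, paste0("select", i)),
                  condition = cond)
  } else {
    rank_and_select(cand, backbone, topk, mapping = families,
                    condition = cond)
  }
  write_newick(sel$trees, file.path(out, sprintf("selected_%s.nwk", tag)))
  if (!is.null(sel$rf)) {
    write.csv(data.frame(tree_index = seq_along(sel$rf),
                         rf_to_backbone = sel$rf),
              file.path(out, sprintf("rf_%s.csv", tag)), row.names = FALSE)
  }
  write.csv(clade_support(sel),
            file.path(out, sprintf("clade_support_%s.csv", tag)),
            row.names = FALSE)
  msg <- if (is.null(sel$rf)) "random sample (backbone-constrained)" else
    sprintf("ranked; RF to backbone %d..%d", min(sel$rf), max(sel$rf))
  cat(sprintf("%-14s %2d trees  %s\n", tag, length(sel$trees), msg))
}
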