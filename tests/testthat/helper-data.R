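# In-code fixtures shared across test files.

toy_tree <- function() parse_newick("((A:1,B:1):1,C:2);")[[1]]

# long diversity-style table over the 14 conditions with known effects on
# the log scale; two plots with an intercept offset
make_model_df <- function(n_per_cell = 30, effects = c(ITS = 0.5),
                          plot_offset = 0.3, sd = 0.2, seed = 1) {
  set.seed(seed)
  conds <- enumerate_conditions()
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    cond <- unlist(conds[i, ])
    do.call(rbind, lapply(c("p1", "p2"), function(p) {
      mu <- 2 + sum(effects[names(effects)] * cond[names(effects)]) +
        if (p == "p1") plot_offset else -plot_offset
      data.frame(metric = "PD",
                 value = exp(stats::rnorm(n_per_cell, mu, sd)),
                 tree_index = seq_len(n_per_cell),
                 rbcL = cond[["rbcL"]], matK = cond[["matK"]],
                 ITS = cond[["ITS"]], ITS2 = cond[["ITS2"]],
                 backbone = cond[["backbone"]], plot = p,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# random abundance vector over a tree's tips with a given richness
rand_community <- function(tree, richness) {
  sp <- sample(tree$tip.label, richness)
  ab <- stats::setNames(integer(length(tree$tip.label)), tree$tip.label)
  ab[sp] <- 1L + stats::rgeom(richness, 0.35)
  ab
}
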