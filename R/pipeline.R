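# Orchestration: wire the stages end to end -- simulate (or load) topology
# sets, rank/select against the backbone, smooth to relative time, build the
# diversity table, run the per-metric multi-model comparison and bootstrap,
# and write every table plus a run manifest.

#' Pipeline run configuration
#'
#' Defaults follow the analysis design the pipeline reproduces: the top 500
#' topologies per condition, smoothing penalty 1000, and 100 bootstrap
#' replicates.
#'
#' @param synth a [synth_config()]; the generator supplies trees, backbone
#'   and communities.
#' @param topk number of topologies selected per condition (default 500).
#' @param lambda smoothing penalty (default 1000).
#' @param metrics metric subset (default all seven).
#' @param bootstrap_B bootstrap replicates (default 100).
#' @param ultrametricize smooth selected trees before computing metrics
#'   (default TRUE, the standard workflow order).
#' @param seed root seed; every stage derives a named substream from it.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(), topk = 500, lambda = 1000,
                       metrics = metric_names(), bootstrap_B = 100,
                       ultrametricize = TRUE, seed = 1, out_dir = NULL) {
  stopifnot(inherits(synth, "synth_config"), topk >= 1,
            topk <= synth$n_candidates,
            lambda > 0, bootstrap_B >= 2,
            all(metrics %in% metric_names()))
  structure(list(synth = synth, topk = topk, lambda = lambda,
                 metrics = metrics, bootstrap_B = bootstrap_B,
                 ultrametricize = ultrametricize, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

# offset policy for metrics that can be exactly zero (IAC): half the
# smallest positive observed value, applied before the log transform
offset_nonpositive <- function(df) {
  if (all(df$value > 0, na.rm = TRUE)) return(df)
  pos <- df$value[is.finite(df$value) & df$value > 0]
  if (length(pos) == 0) stop("all response values non-positive")
  eps <- min(pos) / 2
  warning("non-positive diversity values offset by ", signif(eps, 4),
          " before log transform")
  df$value <- df$value + eps
  df
}

stage_msg <- function(...) message("[barcodiv] ", ...)

#' Run the full analysis pipeline
#'
#' Simulates the synthetic world (true tree, family backbone, communities,
#' per-condition candidate topology sets), selects topologies (ranked by RF
#' distance to the family backbone for unconstrained conditions, randomly
#' for backbone-constrained ones), optionally smooths every selected tree to
#' relative time, computes the diversity table, and runs the 24-model
#' comparison, model-averaged coefficients and bootstrap per metric. When
#' `cfg$out_dir` is set, writes: selected topologies (multi-tree Newick with
#' an RF sidecar CSV), clade-support CSVs, the community CSV, the long
#' diversity CSV, per-metric model-comparison and averaged-coefficient CSVs,
#' bootstrap coefficient CSVs, and a manifest.
#'
#' @param cfg a [run_config()].
#' @return List with elements `truth`, `backbone`, `families`, `community`,
#'   `sets`, `diversity`, `comparisons`, `coefs`, `bootstraps`, and `files`
#'   (paths written, if any).
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  sc <- cfg$synth
  root_seed <- cfg$seed

  stage_msg("simulating true tree (", sc$n_species, " species)")
  truth <- simulate_true_tree(sc$n_species, stage_seed(root_seed, "truth"))
  families <- assign_families(truth, sc$n_families)
  backbone <- condense_to_families(truth, families)
  community <- simulate_communities(truth, sc,
                                    stage_seed(root_seed, "community"))

  conds <- enumerate_conditions()
  stage_msg("simulating and selecting topologies for ", nrow(conds),
            " conditions")
  sets <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cond <- unlist(conds[i, ])
    cand <- simulate_topology_set(
      truth, cond, n_trees = sc$n_candidates,
      intensity = condition_intensity(cond, sc),
      length_mult = condition_length_mult(cond, sc),
      jitter_sd = sc$jitter_sd,
      seed = stage_seed(root_seed, paste0("topo", i)),
      family_map = families)
    sets[[i]] <- if (cond[["backbone"]]) {
      random_select(cand$trees, cfg$topk,
                    seed = stage_seed(root_seed, paste0("select", i)),
                    condition = cond)
    } else {
      rank_and_select(cand$trees, backbone, cfg$topk,
                      mapping = families, condition = cond)
    }
  }

  if (cfg$ultrametricize) {
    stage_msg("smoothing selected trees to relative time (lambda = ",
              cfg$lambda, ")")
    sets <- lapply(sets, ultrametricize_set, lambda = cfg$lambda)
  }

  stage_msg("computing diversity table (", length(cfg$metrics), " metrics)")
  div <- compute_diversity_table(sets, community, cfg$metrics)

  stage_msg("multi-model inference per metric")
  comparisons <- list(); coefs <- list(); boots <- list()
  for (mt in cfg$metrics) {
    dmt <- offset_nonpositive(div[div$metric == mt, , drop = FALSE])
    mc <- model_comparison(dmt)
    comparisons[[mt]] <- mc
    coefs[[mt]] <- averaged_std_coefs(mc)
    boots[[mt]] <- bootstrap_inference(
      dmt, B = cfg$bootstrap_B,
      seed = stage_seed(root_seed, paste0("boot_", mt)))
  }

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    files <- write_outputs(cfg, truth, backbone, families, community,
                           sets, div, comparisons, coefs, boots)
  }
  invisible(list(truth = truth, backbone = backbone, families = families,
                 community = community, sets = sets, diversity = div,
                 comparisons = comparisons, coefs = coefs,
                 bootstraps = boots, files = files))
}

write_outputs <- function(cfg, truth, backbone, families, community,
                          sets, div, comparisons, coefs, boots) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(cfg$out_dir, ...)
  files <- character(0)
  add <- function(f) files <<- c(files, f)

  add(write_newick(truth, p("true_tree.nwk")))
  add(write_newick(backbone, p("backbone.nwk")))
  utils::write.csv(families, p("species_families.csv"), row.names = FALSE)
  add(p("species_families.csv"))
  add(write_community(community, p("community.csv")))

  for (i in seq_along(sets)) {
    ts <- sets[[i]]
    tag <- condition_tag(ts$condition)
    add(write_newick(ts$trees, p(sprintf("trees_%s.nwk", tag))))
    if (!is.null(ts$rf)) {
      utils::write.csv(
        data.frame(tree_index = seq_along(ts$rf), rf_to_backbone = ts$rf),
        p(sprintf("rf_%s.csv", tag)), row.names = FALSE)
      add(p(sprintf("rf_%s.csv", tag)))
    }
    utils::write.csv(clade_support(ts),
                     p(sprintf("clade_support_%s.csv", tag)),
                     row.names = FALSE)
    add(p(sprintf("clade_support_%s.csv", tag)))
  }

  utils::write.csv(div, p("diversity.csv"), row.names = FALSE)
  add(p("diversity.csv"))
  for (mt in names(comparisons)) {
    utils::write.csv(comparisons[[mt]]$table,
                     p(sprintf("model_comparison_%s.csv", mt)),
                     row.names = FALSE)
    add(p(sprintf("model_comparison_%s.csv", mt)))
    cf <- merge(coefs[[mt]], boots[[mt]]$coefs, by = "term",
                suffixes = c("", "_boot"))
    utils::write.csv(cf, p(sprintf("averaged_coefficients_%s.csv", mt)),
                     row.names = FALSE)
    add(p(sprintf("averaged_coefficients_%s.csv", mt)))
  }

  manifest <- c(
    paste0("package: barcodiv ",
           as.character(utils::packageVersion("barcodiv"))),
    paste0("r_version: ", R.version.string),
    paste0("seed: ", cfg$seed),
    paste0("topk: ", cfg$topk),
    paste0("lambda: ", cfg$lambda),
    paste0("bootstrap_B: ", cfg$bootstrap_B),
    paste0("ultrametricize: ", cfg$ultrametricize),
    paste0("metrics: ", paste(cfg$metrics, collapse = ",")),
    paste0("n_species: ", cfg$synth$n_species),
    paste0("richness: ", paste(cfg$synth$richness, collapse = ",")),
    paste0("shared: ", cfg$synth$shared),
    paste0("trees_per_condition: ", cfg$synth$trees_per_condition),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  writeLines(manifest, p("manifest.txt"))
  add(p("manifest.txt"))
  files
}

#' Short file tag for a condition
#'
#' @param condition named logical condition vector.
#' @return A string such as `"R_M_I_bb"`.
#' @export
condition_tag <- function(condition) {
  codes <- c(rbcL = "R", matK = "M", ITS = "I", ITS2 = "I2",
             backbone = "bb")
  paste(codes[names(condition)[condition == TRUE]], collapse = "_")
}

#' Parameter-recovery experiment for one seed
#'
#' Generates the full 14-condition design with a branch-length effect
#' injected through the ITS indicator (default multiplier 1.5), computes
#' Faith's PD per tree and plot directly on the generated trees (the
#' scale-preserving channel: rate smoothing normalizes root age to 1 and
#' would erase a pure branch-length multiplier), runs the 24-model
#' comparison, and bootstraps the model-averaged standardized coefficients.
#'
#' @param seed integer seed.
#' @param n_trees trees per condition (default 100).
#' @param B bootstrap replicates (default 100).
#' @param its_mult injected ITS branch-length multiplier (default 1.5).
#' @param intensity NNI intensity, constant across conditions so the ITS
#'   multiplier is the only systematic difference (default 2).
#' @param synth base `synth_config` for sizes and jitter.
#' @return List with `top_model`, `top_includes_ITS`, `its_coef`
#'   (model-averaged standardized ITS coefficient), `its_ci` (bootstrap 95
#'   percent interval) and `comparison`.
#' @export
run_recovery <- function(seed, n_trees = 100, B = 100, its_mult = 1.5,
                         intensity = 2, synth = synth_config()) {
  sc <- synth
  sc$length_mult[] <- 1
  sc$length_mult[["ITS"]] <- its_mult
  truth <- simulate_true_tree(sc$n_species, stage_seed(seed, "truth"))
  community <- simulate_communities(truth, sc, stage_seed(seed, "community"))
  conds <- enumerate_conditions()
  sets <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cond <- unlist(conds[i, ])
    sets[[i]] <- simulate_topology_set(
      truth, cond, n_trees = n_trees, intensity = intensity,
      length_mult = condition_length_mult(cond, sc),
      jitter_sd = sc$jitter_sd,
      seed = stage_seed(seed, paste0("topo", i)))
  }
  div <- compute_diversity_table(sets, community, metrics = "PD")
  mc <- model_comparison(div)
  bi <- bootstrap_inference(div, B = B, seed = stage_seed(seed, "boot"))
  its <- averaged_std_coefs(mc)
  its_coef <- its$coef[its$term == "ITS"]
  ci <- unlist(bi$coefs[bi$coefs$term == "ITS", c("lo", "hi")])
  list(top_model = mc$table$model[1],
       top_includes_ITS = "ITS" %in% mc$top_spec,
       its_coef = its_coef,
       its_ci = ci,
       comparison = mc)
}
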