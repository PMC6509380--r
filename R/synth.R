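# Synthetic-data generator: a pure-birth "true" species tree, per-condition
# posterior-like topology sets (random NNI perturbation plus branch-length
# jitter, optionally constrained to preserve family-level structure), and a
# two-plot community abundance matrix. The defaults mirror the study design
# the pipeline targets: 114 species over two 1-ha plots with richness 75 and
# 73 sharing 34 species, seven barcode supermatrices crossed with a
# family-level backbone constraint, and 500 selected topologies per
# condition.

#' Enumerate the seven barcode supermatrices
#'
#' Generated from the rule: the two-plastid combination, each plastid
#' crossed with each nuclear ITS variant, and both plastids crossed with
#' each ITS variant.
#'
#' @return data.frame with logical columns `rbcL`, `matK`, `ITS`, `ITS2`;
#'   seven rows.
#' @export
enumerate_supermatrices <- function() {
  combos <- c(list(c("rbcL", "matK")),
              unlist(lapply(c("rbcL", "matK"), function(p)
                lapply(c("ITS", "ITS2"), function(i) c(p, i))),
                recursive = FALSE),
              lapply(c("ITS", "ITS2"), function(i) c("rbcL", "matK", i)))
  out <- as.data.frame(t(vapply(combos, function(cc)
    c(rbcL = "rbcL" %in% cc, matK = "matK" %in% cc,
      ITS = "ITS" %in% cc, ITS2 = "ITS2" %in% cc), logical(4))))
  out
}

#' Enumerate the fourteen analysis conditions
#'
#' The seven supermatrices crossed with the backbone indicator.
#'
#' @return data.frame with logical columns `rbcL`, `matK`, `ITS`, `ITS2`,
#'   `backbone`; fourteen rows.
#' @export
enumerate_conditions <- function() {
  sm <- enumerate_supermatrices()
  out <- rbind(cbind(sm, backbone = FALSE), cbind(sm, backbone = TRUE))
  rownames(out) <- NULL
  out
}

#' Synthetic-data configuration
#'
#' Defaults encode the emulated study design: 114 species, plot richnesses
#' 75 and 73 with 34 shared, 500 trees per condition selected from twice as
#' many candidates, geometric abundances, lognormal branch-length jitter
#' with sdlog 0.2 (posterior-scale rate noise), and a topology-perturbation
#' intensity that decreases with the number of barcodes in the supermatrix
#' (more data, better-resolved topology).
#'
#' @param n_species species pool size.
#' @param richness two plot richnesses.
#' @param shared number of species occurring in both plots.
#' @param n_families number of family-level clades cut from the true tree.
#' @param trees_per_condition selected topologies per condition.
#' @param n_candidates candidate topologies generated per condition before
#'   selection.
#' @param abund_p geometric parameter of the abundance distribution
#'   (abundance = 1 + Geom(p)).
#' @param base_intensity expected NNI moves for a hypothetical one-barcode
#'   supermatrix; a supermatrix with b barcodes gets intensity
#'   `base_intensity / b`.
#' @param jitter_sd sdlog of the lognormal branch-length jitter.
#' @param length_mult named multipliers (rbcL, matK, ITS, ITS2, backbone)
#'   applied multiplicatively to branch lengths when the indicator is on;
#'   all 1 by default (no injected effect).
#' @param seed root seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_species = 114, richness = c(75, 73), shared = 34,
                         n_families = 20, trees_per_condition = 500,
                         n_candidates = 2 * trees_per_condition,
                         abund_p = 0.3, base_intensity = 6, jitter_sd = 0.2,
                         length_mult = c(rbcL = 1, matK = 1, ITS = 1,
                                         ITS2 = 1, backbone = 1),
                         seed = 1) {
  stopifnot(n_species >= 3, length(richness) == 2,
            shared <= min(richness),
            sum(richness) - shared <= n_species,
            abund_p > 0, abund_p < 1,
            base_intensity >= 0, jitter_sd >= 0,
            all(length_mult > 0),
            all(c("rbcL", "matK", "ITS", "ITS2", "backbone") %in%
                  names(length_mult)),
            n_candidates >= trees_per_condition,
            n_families >= 2, n_families <= n_species)
  structure(list(n_species = n_species, richness = richness, shared = shared,
                 n_families = n_families,
                 trees_per_condition = trees_per_condition,
                 n_candidates = n_candidates, abund_p = abund_p,
                 base_intensity = base_intensity, jitter_sd = jitter_sd,
                 length_mult = length_mult, seed = seed),
            class = "synth_config")
}

#' Simulate the true species tree
#'
#' A pure-birth (Yule) tree conditioned on the number of tips, rescaled to
#' unit height, with tips labelled `sp001 ...`.
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer seed.
#' @return An ultrametric `phylo`.
#' @export
simulate_true_tree <- function(n_species, seed = NULL) {
  if (n_species < 3) stop("n_species must be at least 3")
  tree <- with_seed(seed, ape::rphylo(n_species, birth = 1, death = 0))
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Assign species to family-level clades
#'
#' Cuts the ultrametric true tree at the height where exactly `n_families`
#' lineages cross; each crossing lineage's tip set becomes one family
#' (so every family is monophyletic on the true tree by construction).
#'
#' @param tree ultrametric `phylo`.
#' @param n_families number of families (2 .. number of tips).
#' @return data.frame with columns `species`, `family`.
#' @export
assign_families <- function(tree, n_families) {
  n <- length(tree$tip.label)
  stopifnot(n_families >= 2, n_families <= n)
  bt_all <- ape::branching.times(tree)
  bt <- sort(bt_all, decreasing = TRUE)
  h <- if (n_families == n) bt[length(bt)] / 2 else
    (bt[n_families - 1] + bt[n_families]) / 2
  age <- c(rep(0, n), bt_all[as.character((n + 1):(n + tree$Nnode))])
  E <- tree$edge
  span <- which(age[E[, 1]] > h & age[E[, 2]] <= h)
  fams <- lapply(E[span, 2], function(v) {
    if (v <= n) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
  })
  out <- data.frame(
    species = unlist(fams),
    family = rep(sprintf("fam%02d", seq_along(fams)), lengths(fams)),
    stringsAsFactors = FALSE)
  out[order(out$species), , drop = FALSE]
}

# family id per node if all tips below belong to one family, else NA
node_family_purity <- function(E, n_tip, n_node, tip_family) {
  fam <- rep(NA_integer_, n_tip + n_node)
  fam[seq_len(n_tip)] <- tip_family
  mixed <- rep(FALSE, n_tip + n_node)
  # postorder: sort edges so children are visited before parents
  ord <- rev(order_edges_preorder(E, n_tip))
  for (e in ord) {
    p <- E[e, 1]; ch <- E[e, 2]
    if (mixed[ch]) {
      mixed[p] <- TRUE
    } else if (is.na(fam[p])) {
      fam[p] <- fam[ch]
    } else if (fam[p] != fam[ch]) {
      mixed[p] <- TRUE
    }
  }
  fam[mixed] <- NA_integer_
  fam
}

# preorder edge ordering (parents before children) for an arbitrary valid
# edge matrix, without assuming cladewise storage
order_edges_preorder <- function(E, n_tip) {
  m <- nrow(E)
  children_of <- split(seq_len(m), E[, 1])
  root <- setdiff(unique(E[, 1]), E[, 2])[1]
  out <- integer(m); k <- 0L
  stack <- children_of[[as.character(root)]]
  while (length(stack) > 0) {
    e <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L; out[k] <- e
    ch <- E[e, 2]
    if (ch > n_tip) stack <- c(stack, children_of[[as.character(ch)]])
  }
  out
}

# one random nearest-neighbour-interchange move on a rooted tree, restricted
# to edges whose parent node lies entirely inside one family when
# `tip_family` is given (preserving the family-level condensed topology)
nni_move <- function(tree, tip_family = NULL) {
  n <- length(tree$tip.label)
  E <- tree$edge
  internal_edges <- which(E[, 2] > n)
  if (!is.null(tip_family)) {
    fam <- node_family_purity(E, n, tree$Nnode, tip_family)
    internal_edges <- internal_edges[!is.na(fam[E[internal_edges, 1]])]
  }
  if (length(internal_edges) == 0) return(tree)
  e <- internal_edges[sample.int(length(internal_edges), 1)]
  u <- E[e, 1]; v <- E[e, 2]
  kids_v <- which(E[, 1] == v)
  kids_u <- setdiff(which(E[, 1] == u), e)
  if (length(kids_v) == 0 || length(kids_u) == 0) return(tree)
  a <- kids_v[sample.int(length(kids_v), 1)]
  b <- kids_u[sample.int(length(kids_u), 1)]
  E[a, 1] <- u
  E[b, 1] <- v
  tree$edge <- E
  attr(tree, "order") <- NULL
  tree
}

#' Simulate a posterior-like topology set for one condition
#'
#' Each tree is the true tree perturbed by a Poisson(`intensity`) number of
#' random NNI moves, with branch lengths multiplied by `length_mult` times
#' i.i.d. lognormal jitter (mean 1). When the condition carries the backbone
#' flag and a family map is given, moves are restricted to edges inside
#' single-family clades, so the family-level condensed topology -- and hence
#' the RF distance to the family backbone -- stays exactly 0.
#'
#' @param truth the true `phylo`.
#' @param condition named logical condition vector.
#' @param n_trees number of trees to generate.
#' @param intensity expected NNI moves per tree (>= 0).
#' @param length_mult branch-length multiplier.
#' @param jitter_sd sdlog of the lognormal jitter (0 disables jitter).
#' @param seed integer seed.
#' @param family_map species-to-family data.frame; required for
#'   backbone-constrained conditions.
#' @return A `topology_set`.
#' @export
simulate_topology_set <- function(truth, condition, n_trees,
                                  intensity = 0, length_mult = 1,
                                  jitter_sd = 0, seed = NULL,
                                  family_map = NULL) {
  stopifnot(intensity >= 0, length_mult > 0, n_trees >= 1)
  constrain <- isTRUE(condition[["backbone"]]) && !is.null(family_map)
  tip_family <- NULL
  if (constrain) {
    fam <- family_map$family[match(truth$tip.label, family_map$species)]
    if (anyNA(fam)) stop("family map does not cover all tips")
    tip_family <- as.integer(factor(fam))
  }
  truth <- stats::reorder(truth, "cladewise")
  m <- nrow(truth$edge)
  trees <- with_seed(seed, {
    lapply(seq_len(n_trees), function(i) {
      t <- truth
      k <- stats::rpois(1, intensity)
      for (j in seq_len(k)) t <- nni_move(t, tip_family)
      jit <- if (jitter_sd > 0)
        stats::rlnorm(m, meanlog = -jitter_sd^2 / 2, sdlog = jitter_sd)
      else rep(1, m)
      t$edge.length <- t$edge.length * length_mult * jit
      stats::reorder(t, "cladewise")
    })
  })
  topology_set(trees, condition = condition)
}

#' Per-condition NNI intensity implied by a configuration
#'
#' @param condition named logical condition vector.
#' @param cfg a `synth_config`.
#' @return `base_intensity` divided by the number of barcodes present.
#' @export
condition_intensity <- function(condition, cfg) {
  nb <- sum(condition[c("rbcL", "matK", "ITS", "ITS2")])
  if (nb == 0) stop("a supermatrix must contain at least one barcode")
  cfg$base_intensity / nb
}

#' Per-condition branch-length multiplier implied by a configuration
#'
#' @inheritParams condition_intensity
#' @return Product of the configured multipliers over the active indicators.
#' @export
condition_length_mult <- function(condition, cfg) {
  on <- names(condition)[condition == TRUE]
  prod(cfg$length_mult[on])
}

#' Simulate the two-plot community abundance matrix
#'
#' Draws the configured number of shared and plot-unique species from the
#' tree's tip pool and gives every occurrence an abundance 1 + Geom(p).
#'
#' @param tree the species tree supplying the pool of tip labels.
#' @param cfg a `synth_config` (fields `richness`, `shared`, `abund_p`).
#' @param seed integer seed.
#' @param plot_names two plot identifiers.
#' @return plot x species integer matrix (all pool species as columns).
#' @export
simulate_communities <- function(tree, cfg, seed = NULL,
                                 plot_names = c("plot_600m", "plot_100m")) {
  pool <- tree$tip.label
  r <- cfg$richness; s <- cfg$shared
  pooled <- sum(r) - s
  if (pooled > length(pool))
    stop("infeasible design: pooled richness ", pooled,
         " exceeds species pool ", length(pool))
  with_seed(seed, {
    chosen <- sample(pool, pooled)
    shared_sp <- chosen[seq_len(s)]
    uniq1 <- chosen[s + seq_len(r[1] - s)]
    uniq2 <- chosen[(r[1]) + seq_len(r[2] - s)]
    cm <- matrix(0L, nrow = 2, ncol = length(pool),
                 dimnames = list(plot_names, pool))
    occ1 <- c(shared_sp, uniq1)
    occ2 <- c(shared_sp, uniq2)
    cm[1, occ1] <- 1L + stats::rgeom(length(occ1), cfg$abund_p)
    cm[2, occ2] <- 1L + stats::rgeom(length(occ2), cfg$abund_p)
    cm
  })
}
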