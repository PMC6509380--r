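# Plot-level phylogenetic diversity metrics on a community matrix:
# Faith's PD (root-inclusive), MPD and MNTD with presence/absence or
# abundance weighting, phylogenetic-abundance evenness (PAE) and the
# imbalance of abundances at higher clades (IAC).

metric_names <- function() {
  c("PD", "MPD", "MPD_ed", "MNTD", "MNTD_ed", "PAE", "IAC")
}

check_species <- function(tree, species) {
  miss <- setdiff(species, tree$tip.label)
  if (length(miss) > 0)
    stop("species not on the tree: ", paste(miss, collapse = ", "))
}

# per-node count of present tips below each node, postorder
presence_counts <- function(tree, present_idx) {
  n <- length(tree$tip.label)
  tree <- stats::reorder(tree, "postorder")
  cnt <- numeric(n + tree$Nnode)
  cnt[present_idx] <- 1
  E <- tree$edge
  for (e in seq_len(nrow(E))) cnt[E[e, 1]] <- cnt[E[e, 1]] + cnt[E[e, 2]]
  list(counts = cnt, edge = E, edge.length = tree$edge.length)
}

#' Faith's phylogenetic diversity
#'
#' Sum of branch lengths of the minimal subtree connecting the present
#' species, including the path to the tree root, so single-species
#' communities are defined (their PD is the root-to-tip path length).
#'
#' @param tree a `phylo` with branch lengths.
#' @param present character vector of present species.
#' @return Total branch length of the spanning subtree.
#' @export
faith_pd <- function(tree, present) {
  present <- unique(present)
  if (length(present) < 1) stop("at least one present species required")
  check_species(tree, present)
  idx <- match(present, tree$tip.label)
  pc <- presence_counts(tree, idx)
  sum(pc$edge.length[pc$counts[pc$edge[, 2]] > 0])
}

present_from_abund <- function(abund) {
  if (is.null(names(abund))) stop("abundances must be named by species")
  names(abund)[abund > 0]
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Unweighted: mean patristic distance over unordered pairs of distinct
#' present species. Abundance-weighted: pair distances weighted by the
#' product of the two species' abundances, self-pairs excluded.
#'
#' @param tree a `phylo`.
#' @param abund named non-negative abundances; species with abundance > 0
#'   are present.
#' @param weighted logical, abundance weighting.
#' @param dist optional precomputed patristic matrix.
#' @return The mean distance, or `NA` (with a warning) for communities with
#'   fewer than two species.
#' @export
mpd <- function(tree, abund, weighted = FALSE, dist = NULL) {
  sp <- present_from_abund(abund)
  check_species(tree, sp)
  if (length(sp) < 2) {
    warning("MPD undefined for <2 species; returning NA")
    return(NA_real_)
  }
  D <- if (is.null(dist)) patristic_distances(tree) else dist
  D <- D[sp, sp]
  ut <- upper.tri(D)
  if (!weighted) return(mean(D[ut]))
  n <- abund[sp]
  W <- outer(n, n)
  sum(W[ut] * D[ut]) / sum(W[ut])
}

#' Mean nearest taxon distance (MNTD)
#'
#' Unweighted: mean, over present species, of the patristic distance to the
#' nearest other present species. Abundance-weighted: that mean weighted by
#' species abundances.
#'
#' @inheritParams mpd
#' @return The mean nearest-neighbour distance, or `NA` for <2 species.
#' @export
mntd <- function(tree, abund, weighted = FALSE, dist = NULL) {
  sp <- present_from_abund(abund)
  check_species(tree, sp)
  if (length(sp) < 2) {
    warning("MNTD undefined for <2 species; returning NA")
    return(NA_real_)
  }
  D <- if (is.null(dist)) patristic_distances(tree) else dist
  D <- D[sp, sp]
  diag(D) <- Inf
  mind <- apply(D, 1, min)
  if (!weighted) return(mean(mind))
  stats::weighted.mean(mind, abund[sp])
}

terminal_lengths <- function(tree, species) {
  idx <- match(species, tree$tip.label)
  tl <- tree$edge.length[match(idx, tree$edge[, 2])]
  names(tl) <- species
  tl
}

#' Phylogenetic-abundance evenness (PAE)
#'
#' Compares the placement of individuals on terminal branches with a
#' perfectly even placement:
#' \deqn{PAE = \frac{PD + \sum_i T_i (n_i - 1)}{PD + (N/S - 1)\sum_i T_i}}
#' where \eqn{T_i} is the terminal branch length of species i, \eqn{N} the
#' total number of individuals, \eqn{S} the species richness, and PD the
#' root-inclusive Faith diversity of the community. Equal abundances give
#' PAE = 1.
#'
#' @inheritParams mpd
#' @return PAE, or `NA` for communities with fewer than two species.
#' @export
pae <- function(tree, abund) {
  sp <- present_from_abund(abund)
  check_species(tree, sp)
  if (any(abund[sp] < 1)) stop("present species must have abundance >= 1")
  if (length(sp) < 2) {
    warning("PAE undefined for <2 species; returning NA")
    return(NA_real_)
  }
  n <- abund[sp]
  N <- sum(n)
  S <- length(sp)
  pd <- faith_pd(tree, sp)
  tl <- terminal_lengths(tree, sp)
  (pd + sum(tl * (n - 1))) / (pd + (N / S - 1) * sum(tl))
}

#' Imbalance of abundances at higher clades (IAC)
#'
#' The community total N is split equally among daughter lineages at every
#' internal node of the community subtree (recursively, root to tips),
#' giving each species an expected abundance \eqn{\hat n_i}. IAC is
#' \eqn{\sum_i |n_i - \hat n_i| / v}, with v the number of internal nodes
#' of the community subtree having two or more daughter lineages. A
#' perfectly balanced abundance distribution gives IAC = 0.
#'
#' @inheritParams mpd
#' @return IAC, or `NA` for communities with fewer than two species.
#' @export
iac <- function(tree, abund) {
  sp <- present_from_abund(abund)
  check_species(tree, sp)
  if (any(abund[sp] < 1)) stop("present species must have abundance >= 1")
  if (length(sp) < 2) {
    warning("IAC undefined for <2 species; returning NA")
    return(NA_real_)
  }
  n_tip <- length(tree$tip.label)
  idx <- match(sp, tree$tip.label)
  pc <- presence_counts(tree, idx)
  cnt <- pc$counts
  # children lists on the full tree
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  root <- n_tip + 1L
  expected <- numeric(n_tip)
  v <- 0L
  # preorder allocation: at each node, split among present-bearing daughters
  alloc <- numeric(n_tip + tree$Nnode)
  alloc[root] <- sum(abund[sp])
  stack <- root
  while (length(stack) > 0) {
    v_node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ch <- kids[[as.character(v_node)]]
    bearing <- ch[cnt[ch] > 0]
    if (length(bearing) >= 2) v <- v + 1L
    share <- alloc[v_node] / max(length(bearing), 1)
    for (c_node in bearing) {
      alloc[c_node] <- share
      if (c_node <= n_tip) expected[c_node] <- share else stack <- c(stack, c_node)
    }
  }
  if (v == 0L) {
    warning("IAC undefined: community subtree has no branching node")
    return(NA_real_)
  }
  sum(abs(abund[sp] - expected[idx])) / v
}

#' Read a plot x species community matrix from CSV
#'
#' First column holds plot identifiers; the remaining columns are species
#' abundances (non-negative integers).
#'
#' @param file CSV path.
#' @return Integer matrix with plot rownames and species colnames.
#' @export
read_community <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0) || any(m != round(m)))
    stop("community matrix must contain non-negative integers")
  m
}

#' Write a community matrix to CSV
#'
#' @param cm plot x species matrix.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_community <- function(cm, file) {
  df <- data.frame(plot = rownames(cm), cm, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Compute the long-format diversity table over topology sets
#'
#' One record per metric x tree x plot x condition; each value is exactly
#' what the corresponding single-metric function returns on that tree and
#' community row.
#'
#' @param sets list of `topology_set` objects.
#' @param cm plot x species abundance matrix (see [read_community()]).
#' @param metrics subset of `PD, MPD, MPD_ed, MNTD, MNTD_ed, PAE, IAC`.
#' @return data.frame with columns `metric`, `value`, `tree_index`,
#'   `rbcL`, `matK`, `ITS`, `ITS2`, `backbone`, `plot`.
#' @export
compute_diversity_table <- function(sets, cm, metrics = metric_names()) {
  stopifnot(all(metrics %in% metric_names()))
  if (inherits(sets, "topology_set")) sets <- list(sets)
  plots <- rownames(cm)
  need_dist <- any(metrics %in% c("MPD", "MPD_ed", "MNTD", "MNTD_ed"))
  out <- vector("list", length(sets))
  for (si in seq_along(sets)) {
    ts <- sets[[si]]
    cond <- ts$condition
    sp_all <- colnames(cm)
    rows <- vector("list", length(ts$trees))
    for (ti in seq_along(ts$trees)) {
      tree <- ts$trees[[ti]]
      check_species(tree, sp_all[colSums(cm) > 0])
      D <- if (need_dist) patristic_distances(tree) else NULL
      vals <- lapply(plots, function(p) {
        ab <- cm[p, ]
        vapply(metrics, function(mt) {
          switch(mt,
            PD      = faith_pd(tree, present_from_abund(ab)),
            MPD     = mpd(tree, ab, weighted = FALSE, dist = D),
            MPD_ed  = mpd(tree, ab, weighted = TRUE, dist = D),
            MNTD    = mntd(tree, ab, weighted = FALSE, dist = D),
            MNTD_ed = mntd(tree, ab, weighted = TRUE, dist = D),
            PAE     = pae(tree, ab),
            IAC     = iac(tree, ab))
        }, numeric(1))
      })
      rows[[ti]] <- data.frame(
        metric = rep(metrics, times = length(plots)),
        value = unlist(vals, use.names = FALSE),
        tree_index = ti,
        rbcL = cond[["rbcL"]], matK = cond[["matK"]],
        ITS = cond[["ITS"]], ITS2 = cond[["ITS2"]],
        backbone = cond[["backbone"]],
        plot = rep(plots, each = length(metrics)),
        stringsAsFactors = FALSE)
    }
    out[[si]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
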