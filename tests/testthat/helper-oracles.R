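# Brute-force oracles, written independently of the package implementation:
# they work directly on the edge matrix with explicit loops and set algebra.

# random rooted binary tree with uniform(0,1)-ish branch lengths
rand_tree <- function(n) {
  t <- ape::rtree(n)
  t$edge.length <- t$edge.length + 0.05  # keep lengths strictly positive
  t
}

# parent lookup: parent[v] = parent node of v (NA for root)
parent_map <- function(tree) {
  np <- max(tree$edge)
  par <- rep(NA_integer_, np)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

edge_len_to_parent <- function(tree) {
  np <- max(tree$edge)
  len <- rep(NA_real_, np)
  len[tree$edge[, 2]] <- tree$edge.length
  len
}

# non-trivial unrooted bipartitions as canonical strings: each internal edge
# splits the tips; the side NOT containing the first (alphabetical) tip is
# sorted and joined
bf_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  labs <- tree$tip.label
  anchor <- sort(labs)[1]
  below <- function(v) {
    if (v <= n) return(labs[v])
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, below))
  }
  internal_children <- tree$edge[tree$edge[, 2] > n, 2]
  splits <- vapply(internal_children, function(v) {
    side <- below(v)
    if (length(side) <= 1 || length(side) >= n - 1) return(NA_character_)
    if (anchor %in% side) side <- setdiff(labs, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(splits[!is.na(splits)])
}

bf_rf <- function(t1, t2) {
  s1 <- bf_bipartitions(t1)
  s2 <- bf_bipartitions(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# patristic distances by explicit root-path walking
bf_patristic <- function(tree) {
  n <- length(tree$tip.label)
  par <- parent_map(tree)
  len <- edge_len_to_parent(tree)
  path_to_root <- function(v) {
    nodes <- v; d <- 0
    while (!is.na(par[v])) {
      d <- c(d, d[length(d)] + len[v])
      v <- par[v]
      nodes <- c(nodes, v)
    }
    list(nodes = nodes, dist = d)
  }
  paths <- lapply(seq_len(n), path_to_root)
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pi <- paths[[i]]; pj <- paths[[j]]
      common <- intersect(pi$nodes, pj$nodes)
      # the most recent common ancestor is the first shared node on i's path
      mrca <- pi$nodes[min(which(pi$nodes %in% common))]
      D[i, j] <- D[j, i] <-
        pi$dist[match(mrca, pi$nodes)] + pj$dist[match(mrca, pj$nodes)]
    }
  }
  D
}

# Faith PD by union of root paths (edge identified by its child node)
bf_pd <- function(tree, present) {
  par <- parent_map(tree)
  len <- edge_len_to_parent(tree)
  idx <- match(present, tree$tip.label)
  used <- integer(0)
  for (v in idx) {
    while (!is.na(par[v])) {
      used <- union(used, v)
      v <- par[v]
    }
  }
  sum(len[used])
}

bf_mpd <- function(D, abund, weighted = FALSE) {
  sp <- names(abund)[abund > 0]
  tot <- 0; wtot <- 0
  for (i in seq_along(sp)) {
    for (j in seq_along(sp)) {
      if (j <= i) next
      w <- if (weighted) abund[[sp[i]]] * abund[[sp[j]]] else 1
      tot <- tot + w * D[sp[i], sp[j]]
      wtot <- wtot + w
    }
  }
  tot / wtot
}

bf_mntd <- function(D, abund, weighted = FALSE) {
  sp <- names(abund)[abund > 0]
  mind <- vapply(sp, function(a) {
    min(vapply(setdiff(sp, a), function(b) D[a, b], numeric(1)))
  }, numeric(1))
  if (weighted) sum(abund[sp] * mind) / sum(abund[sp]) else mean(mind)
}

# independent optimizer of the penalized rate-smoothing objective: joint
# optimization over internal node ages (as fractions of the parent age) and
# per-branch rates, from a grid of starting points -- no inner linear solve
pl_objective_oracle <- function(tree, lambda, n_random_starts = 30) {
  tree <- stats::reorder(tree, "cladewise")
  n <- length(tree$tip.label)
  E <- tree$edge
  b <- tree$edge.length
  m <- nrow(E)
  root <- n + 1L
  free <- E[E[, 2] > n, 2]  # internal non-root nodes, parents-first
  nf <- length(free)
  parent_edge <- match(E[, 1], E[, 2])
  pairs <- cbind(parent_edge[!is.na(parent_edge)],
                 which(!is.na(parent_edge)))
  evalobj <- function(par) {
    frac <- stats::plogis(par[seq_len(nf)])
    rates <- exp(par[nf + seq_len(m)])
    age <- numeric(max(E))
    age[root] <- 1
    f <- numeric(max(E)); f[free] <- frac
    for (e in seq_len(m)) {
      ch <- E[e, 2]
      if (ch > n) age[ch] <- f[ch] * age[E[e, 1]]
    }
    d <- age[E[, 1]] - age[E[, 2]]
    sum((b - rates * d)^2) +
      lambda * sum((rates[pairs[, 1]] - rates[pairs[, 2]])^2)
  }
  mean_rate <- sum(b) / 2  # crude scale for rate starts
  starts <- list(c(rep(0, nf), rep(log(mean_rate + 0.1), m)))
  if (nf > 0 && nf <= 3) {
    grid <- expand.grid(rep(list(stats::qlogis(c(0.25, 0.5, 0.75))), nf))
    for (r in seq_len(nrow(grid)))
      starts[[length(starts) + 1]] <-
        c(unlist(grid[r, ]), rep(log(mean_rate + 0.1), m))
  }
  for (s in seq_len(n_random_starts))
    starts[[length(starts) + 1]] <-
      c(stats::rnorm(nf, 0, 1.5), stats::rnorm(m, log(mean_rate + 0.1), 0.7))
  best <- Inf
  for (st in starts) {
    fit <- try(stats::nlminb(st, evalobj,
                             control = list(iter.max = 2000,
                                            eval.max = 8000)),
               silent = TRUE)
    if (!inherits(fit, "try-error") && fit$objective < best)
      best <- fit$objective
  }
  best
}
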