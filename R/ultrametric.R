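# Penalized rate smoothing: transform a rooted tree with substitution-rate
# branch lengths into an ultrametric tree on relative time.
#
# The objective is the penalized least-squares form of semiparametric rate
# smoothing: sum over branches of (b_e - r_e * d_e)^2 (lack of fit of the
# observed length b_e to rate x duration) plus lambda times the sum of
# squared rate differences between every ancestor branch and its descendant
# branches. Node ages are free parameters (tips at age 0, root fixed at 1);
# given ages, the optimal rates solve a linear system, so the outer
# optimization runs over internal-node ages only.

#' Make a tree ultrametric by penalized rate smoothing
#'
#' Same topology in, relative-time branch lengths out: all root-to-tip depths
#' equal 1 after smoothing. The smoothing penalty `lambda` controls how much
#' rate variation between ancestor and descendant branches is tolerated
#' (large values approach a strict clock); the default 1000 is the
#' conventional heavy-smoothing setting for barcode-scale data.
#'
#' @param tree rooted `phylo` with non-negative branch lengths. Zero-length
#'   branches are raised to `zero_eps` times tree height with a warning
#'   (the objective degenerates at zero durations).
#' @param lambda smoothing penalty (default 1000).
#' @param zero_eps relative floor for zero-length branches.
#' @param iter_max outer iteration budget.
#' @param restarts extra jittered starts tried if the optimizer reports
#'   non-convergence.
#' @return A `phylo` with attributes `objective` (the minimized penalized
#'   objective), `rates` (per-edge smoothed rates) and `ages` (node ages,
#'   root = 1).
#' @export
make_ultrametric <- function(tree, lambda = 1000, zero_eps = 1e-8,
                             iter_max = 1000, restarts = 3) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")

  tree <- stats::reorder(tree, "cladewise")
  n <- length(tree$tip.label)
  root <- n + 1L
  E <- tree$edge
  b <- tree$edge.length
  height <- max(ape::node.depth.edgelength(tree))
  if (height <= 0) stop("tree has zero total height")
  if (any(b == 0)) {
    warning("zero-length branches raised to ", zero_eps, " x tree height")
    b[b == 0] <- zero_eps * height
  }
  m <- nrow(E)

  # ancestor/descendant branch pairs (edge indices): descendant edge f's
  # parent node is edge e's child node
  parent_edge <- match(E[, 1], E[, 2])  # NA for edges hanging off the root
  pair_i <- parent_edge[!is.na(parent_edge)]
  pair_j <- which(!is.na(parent_edge))
  L <- matrix(0, m, m)
  for (p in seq_along(pair_i)) {
    i <- pair_i[p]; j <- pair_j[p]
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
  }
  lamL <- lambda * L

  # free internal nodes in cladewise (parents-first) order
  internal_children <- E[E[, 2] > n, 2]
  n_free <- length(internal_children)

  node_ages <- function(frac) {
    age <- numeric(n + tree$Nnode)
    age[root] <- 1
    if (n_free > 0) {
      f <- numeric(n + tree$Nnode)
      f[internal_children] <- frac
      for (e in seq_len(m)) {
        ch <- E[e, 2]
        if (ch > n) age[ch] <- f[ch] * age[E[e, 1]]
      }
    }
    age
  }

  solve_rates <- function(d) {
    A <- lamL
    diag(A) <- diag(A) + d * d
    r <- solve(A, d * b)
    obj <- sum((b - r * d)^2) +
      lambda * sum((r[pair_i] - r[pair_j])^2)
    list(rates = r, objective = obj)
  }

  objective_of <- function(par) {
    frac <- stats::plogis(par)
    age <- node_ages(frac)
    d <- age[E[, 1]] - age[E[, 2]]
    solve_rates(d)$objective
  }

  # start from the input tree's own relative node heights
  depth <- ape::node.depth.edgelength(tree)
  h_node <- height - depth
  age0 <- pmin(pmax(h_node / height, 1e-4), 1 - 1e-4)

  if (n_free == 0) {
    age <- node_ages(numeric(0))
    d <- age[E[, 1]] - age[E[, 2]]
    sol <- solve_rates(d)
    out <- tree
    out$edge.length <- d
    attr(out, "objective") <- sol$objective
    attr(out, "rates") <- sol$rates
    attr(out, "ages") <- age
    return(out)
  }

  # express starting ages as fractions of the parent age
  par0 <- numeric(n_free)
  age_start <- numeric(n + tree$Nnode)
  age_start[root] <- 1
  f0 <- numeric(n + tree$Nnode)
  for (e in seq_len(m)) {
    ch <- E[e, 2]
    if (ch > n) {
      fr <- age0[ch] / max(age_start[E[e, 1]], 1e-8)
      fr <- min(max(fr, 0.05), 0.95)
      f0[ch] <- fr
      age_start[ch] <- fr * age_start[E[e, 1]]
    }
  }
  par0 <- stats::qlogis(f0[internal_children])

  trace_env <- new.env()
  trace_env$trace <- numeric(0)
  obj_traced <- function(par) {
    v <- objective_of(par)
    trace_env$trace <- c(trace_env$trace, v)
    v
  }

  best <- NULL
  starts <- list(par0)
  for (s in seq_len(restarts)) {
    starts[[s + 1L]] <- par0 +
      with_seed(7000 + s, stats::rnorm(n_free, 0, 0.5 * s))
  }
  for (s in seq_along(starts)) {
    fit <- stats::nlminb(starts[[s]], obj_traced,
                         control = list(iter.max = iter_max,
                                        eval.max = 4 * iter_max))
    ok <- fit$convergence == 0 ||
      grepl("converg", fit$message %||% "", ignore.case = TRUE)
    if (ok && (is.null(best) || fit$objective < best$objective)) best <- fit
    if (!is.null(best) && s == 1) break  # first start converged
  }
  if (is.null(best)) {
    stop("rate smoothing failed to converge; objective trace: ",
         paste(signif(utils::tail(trace_env$trace, 20), 6), collapse = ", "))
  }

  frac <- stats::plogis(best$par)
  age <- node_ages(frac)
  d <- age[E[, 1]] - age[E[, 2]]
  sol <- solve_rates(d)
  out <- tree
  out$edge.length <- d
  attr(out, "objective") <- sol$objective
  attr(out, "rates") <- sol$rates
  attr(out, "ages") <- age
  out
}

#' Smooth every tree in a topology set
#'
#' @param ts a `topology_set`.
#' @inheritParams make_ultrametric
#' @return A `topology_set` of ultrametric trees (condition and RF
#'   annotations preserved).
#' @export
ultrametricize_set <- function(ts, lambda = 1000) {
  stopifnot(inherits(ts, "topology_set"))
  ts$trees <- lapply(ts$trees, make_ultrametric, lambda = lambda)
  ts
}
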