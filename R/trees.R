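# Tree I/O and topology processing: Newick parsing, patristic distances,
# Robinson-Foulds ranking against a family-level backbone, random selection
# for backbone-constrained sets, and clade support across a topology set.

#' Parse Newick text or a Newick file into a list of trees
#'
#' Accepts a Newick string (possibly holding several `;`-terminated trees)
#' or a path to a single- or multi-tree Newick file. Trees without branch
#' lengths get zero-length branches with a warning; duplicate tip labels are
#' an error naming the offending labels.
#'
#' @param x Newick string or file path.
#' @return A list of `phylo` objects.
#' @export
parse_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1)
  if (!grepl("\\(", x)) {
    if (!file.exists(x)) stop("not Newick text and file not found: ", x)
    x <- paste(readLines(x, warn = FALSE), collapse = "\n")
  }
  tr <- tryCatch(ape::read.tree(text = x),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("Newick parse error: no tree found in input")
  if (inherits(tr, "phylo")) tr <- list(tr) else tr <- unname(unclass(tr))
  lapply(tr, function(t) {
    dup <- unique(t$tip.label[duplicated(t$tip.label)])
    if (length(dup) > 0)
      stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
    if (is.null(t$edge.length)) {
      warning("tree has no branch lengths; all set to 0")
      t$edge.length <- rep(0, nrow(t$edge))
    }
    if (anyNA(t$edge.length) || any(t$edge.length < 0))
      stop("negative or missing branch length in tree")
    t
  })
}

#' Write trees to a multi-tree Newick file
#'
#' @param trees a `phylo` or list of `phylo`.
#' @param file output path; one tree per line.
#' @return `file`, invisibly.
#' @export
write_newick <- function(trees, file) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(t) ape::write.tree(t), character(1))
  writeLines(txt, file)
  invisible(file)
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree a `phylo` with branch lengths.
#' @return A symmetric matrix with zero diagonal, rows/cols in
#'   `tree$tip.label` order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Robinson-Foulds (symmetric) distance between two trees
#'
#' The size of the symmetric difference of the two trees' non-trivial
#' bipartition sets, under the unrooted interpretation. Both trees must
#' carry identical tip sets.
#'
#' @param t1,t2 `phylo` objects.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  only1 <- setdiff(t1$tip.label, t2$tip.label)
  only2 <- setdiff(t2$tip.label, t1$tip.label)
  if (length(only1) > 0 || length(only2) > 0)
    stop("tip sets differ; only in first: {",
         paste(only1, collapse = ", "), "}; only in second: {",
         paste(only2, collapse = ", "), "}")
  as.integer(suppressMessages(phangorn::RF.dist(t1, t2,
                                                check.labels = TRUE)))
}

#' Condense a species-level tree to one exemplar tip per family
#'
#' Keeps, for each family, the alphabetically first species as exemplar,
#' prunes the rest, and relabels exemplar tips with their family names. Used
#' to compare species trees against a family-level backbone.
#'
#' @param tree a `phylo` whose tips are species.
#' @param mapping data.frame with columns `species`, `family`.
#' @return A `phylo` with one tip per family, tips labelled by family.
#' @export
condense_to_families <- function(tree, mapping) {
  stopifnot(all(c("species", "family") %in% names(mapping)))
  miss <- setdiff(tree$tip.label, mapping$species)
  if (length(miss) > 0)
    stop("species missing from family mapping: ", paste(miss, collapse = ", "))
  mapping <- mapping[order(mapping$family, mapping$species), ]
  mapping <- mapping[mapping$species %in% tree$tip.label, ]
  exemplars <- mapping[!duplicated(mapping$family), ]
  sub <- ape::keep.tip(tree, exemplars$species)
  sub$tip.label <- exemplars$family[match(sub$tip.label, exemplars$species)]
  sub
}

#' Construct a topology set
#'
#' An ordered collection of trees over a common tip set, labelled with a
#' condition (barcode indicators plus backbone flag). Input order is
#' preserved; it defines tie-breaking in ranked selection.
#'
#' @param trees list of `phylo` over a common tip set.
#' @param condition named logical vector with elements
#'   `rbcL`, `matK`, `ITS`, `ITS2`, `backbone`.
#' @param rf optional numeric vector of RF distances to the backbone.
#' @return An object of class `topology_set`.
#' @export
topology_set <- function(trees, condition = NULL, rf = NULL) {
  stopifnot(is.list(trees), length(trees) > 0,
            all(vapply(trees, inherits, logical(1), "phylo")))
  tips <- sort(trees[[1]]$tip.label)
  same <- vapply(trees, function(t) identical(sort(t$tip.label), tips),
                 logical(1))
  if (!all(same)) stop("all trees in a topology set must share one tip set")
  condition <- condition %||%
    c(rbcL = FALSE, matK = FALSE, ITS = FALSE, ITS2 = FALSE, backbone = FALSE)
  nm <- c("rbcL", "matK", "ITS", "ITS2", "backbone")
  stopifnot(is.logical(condition), all(nm %in% names(condition)))
  condition <- condition[nm]
  if (condition[["ITS"]] && condition[["ITS2"]])
    stop("a condition cannot include both ITS and ITS2")
  structure(list(trees = trees, condition = condition, rf = rf),
            class = "topology_set")
}

#' @export
print.topology_set <- function(x, ...) {
  on <- names(x$condition)[x$condition]
  cat("topology_set:", length(x$trees), "trees,",
      length(x$trees[[1]]$tip.label), "tips; condition: {",
      paste(on, collapse = ", "), "}\n")
  invisible(x)
}

#' @export
length.topology_set <- function(x) length(x$trees)

#' Rank trees by RF distance to a backbone and keep the top k
#'
#' Each candidate is compared to the backbone by symmetric distance; when a
#' species-to-family `mapping` is supplied the candidate is first condensed
#' to family level (the backbone being a family-level topology). The k
#' smallest distances win; ties are broken by original input position
#' (stable sort), and each retained tree is annotated with its distance.
#'
#' @param trees list of `phylo` candidates.
#' @param backbone `phylo` backbone topology.
#' @param k number of trees to retain.
#' @param mapping optional species-to-family data.frame (see
#'   [condense_to_families()]).
#' @param condition optional condition vector for the returned set.
#' @return A `topology_set` with `rf` distances, ordered by rank.
#' @export
rank_and_select <- function(trees, backbone, k, mapping = NULL,
                            condition = NULL) {
  stopifnot(k >= 1)
  if (k > length(trees))
    stop("k (", k, ") exceeds the number of available trees (",
         length(trees), ")")
  d <- vapply(trees, function(t) {
    tt <- if (is.null(mapping)) t else condense_to_families(t, mapping)
    rf_distance(tt, backbone)
  }, numeric(1))
  ord <- order(d)[seq_len(k)]  # order() is stable: ties keep input order
  topology_set(trees[ord], condition = condition, rf = d[ord])
}

#' Randomly select k trees without replacement
#'
#' @param trees list of `phylo`.
#' @param k number to select.
#' @param seed integer seed; identical seeds give identical selections.
#' @param condition optional condition vector for the returned set.
#' @return A `topology_set`.
#' @export
random_select <- function(trees, k, seed = NULL, condition = NULL) {
  stopifnot(k >= 1)
  if (k > length(trees))
    stop("k (", k, ") exceeds the number of available trees (",
         length(trees), ")")
  idx <- with_seed(seed, sample.int(length(trees), k, replace = FALSE))
  topology_set(trees[idx], condition = condition)
}

#' Clade support frequencies across a topology set
#'
#' The fraction of trees in which each clade (set of tips subtended by an
#' internal node) occurs -- the usual estimate of node posterior probability
#' over a posterior topology sample.
#'
#' @param ts a `topology_set`.
#' @return data.frame with columns `clade` (comma-joined sorted tip labels),
#'   `count`, and `support` = count / number of trees.
#' @export
clade_support <- function(ts) {
  stopifnot(inherits(ts, "topology_set"))
  n <- length(ts$trees)
  pp <- ape::prop.part(ts$trees)
  labs <- attr(pp, "labels")
  counts <- attr(pp, "number")
  clade <- vapply(pp, function(i) paste(sort(labs[i]), collapse = ","),
                  character(1))
  out <- data.frame(clade = clade, count = as.integer(counts),
                    support = counts / n, stringsAsFactors = FALSE)
  out[order(-out$support, out$clade), , drop = FALSE]
}
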