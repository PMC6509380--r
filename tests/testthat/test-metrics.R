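# Toy fixture: tree ((A:1,B:1):1,C:2) with abundances A:2, B:1, C:1.

test_that("toy-fixture values match hand enumeration", {
  toy <- toy_tree()
  ab <- c(A = 2, B = 1, C = 1)

  expect_equal(faith_pd(toy, c("A", "B", "C")), 5)
  expect_equal(faith_pd(toy, c("A", "B")), 3)     # root-inclusive
  expect_equal(faith_pd(toy, "C"), 2)             # single lineage defined

  expect_equal(mpd(toy, c(A = 1, B = 1, C = 1)), 10 / 3)
  expect_equal(mpd(toy, ab, weighted = TRUE), 16 / 5)
  expect_equal(mntd(toy, c(A = 1, B = 1, C = 1)), 8 / 3)
  expect_equal(mntd(toy, ab, weighted = TRUE), 2.5)

  expect_equal(pae(toy, ab), 18 / 19)
  expect_equal(iac(toy, ab), 1)
  expect_equal(iac(toy, c(A = 1, B = 1, C = 2)), 0)

  star <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_equal(iac(star, c(A = 4, B = 1, C = 1)), 4)
})

test_that("metric errors and degenerate communities follow policy", {
  toy <- toy_tree()
  expect_error(faith_pd(toy, c("A", "Z")), "Z")
  expect_warning(v <- mpd(toy, c(A = 2, B = 0, C = 0)), "NA")
  expect_true(is.na(v))
  expect_warning(v2 <- mntd(toy, c(A = 1, B = 0, C = 0)), "NA")
  expect_true(is.na(v2))
  expect_error(pae(toy, c(A = 0.5, B = 1, C = 1)), "abundance >= 1")
})

test_that("equal abundances collapse weighted metrics and give PAE = 1", {
  set.seed(23)
  for (i in 1:25) {
    t <- rand_tree(8)
    ab <- stats::setNames(rep(3L, 8), t$tip.label)
    D <- patristic_distances(t)
    expect_equal(mpd(t, ab, weighted = TRUE, dist = D),
                 mpd(t, ab, weighted = FALSE, dist = D))
    expect_equal(mntd(t, ab, weighted = TRUE, dist = D),
                 mntd(t, ab, weighted = FALSE, dist = D))
    expect_equal(pae(t, ab), 1)
  }
})

test_that("IAC is zero exactly at the recursive equal-split expectation", {
  set.seed(31)
  for (i in 1:10) {
    t <- rand_tree(6)
    # construct abundances by splitting a power-of-two total down the tree
    n_tip <- 6
    par <- t$edge[, 1]
    ab <- stats::setNames(rep(0, n_tip), t$tip.label)
    alloc <- function(v, amount) {
      if (v <= n_tip) {
        ab[t$tip.label[v]] <<- amount
        return(invisible())
      }
      kids <- t$edge[par == v, 2]
      for (k in kids) alloc(k, amount / length(kids))
    }
    alloc(n_tip + 1, 2^6)
    if (any(ab != round(ab))) next  # only exact integer splits qualify
    expect_equal(iac(t, ab), 0)
  }
})

test_that("PD, MPD and MNTD match brute-force oracles on random communities", {
  set.seed(41)
  for (i in 1:40) {
    t <- rand_tree(8)
    ab <- rand_community(t, sample(3:8, 1))
    D <- bf_patristic(t)
    sp <- names(ab)[ab > 0]
    expect_equal(faith_pd(t, sp), bf_pd(t, sp), tolerance = 1e-12)
    expect_equal(mpd(t, ab), bf_mpd(D, ab), tolerance = 1e-12)
    expect_equal(mpd(t, ab, weighted = TRUE), bf_mpd(D, ab, weighted = TRUE),
                 tolerance = 1e-12)
    expect_equal(mntd(t, ab), bf_mntd(D, ab), tolerance = 1e-12)
    expect_equal(mntd(t, ab, weighted = TRUE),
                 bf_mntd(D, ab, weighted = TRUE), tolerance = 1e-12)
  }
})

test_that("unweighted PD/MPD/MNTD and weighted MNTD agree with picante", {
  skip_if_not_installed("picante")
  set.seed(43)
  t <- rand_tree(10)
  ab <- rand_community(t, 7)
  samp <- matrix(ab, nrow = 1, dimnames = list("p1", names(ab)))
  D <- patristic_distances(t)
  expect_equal(mpd(t, ab), unname(picante::mpd(samp, D)))
  expect_equal(mntd(t, ab), unname(picante::mntd(samp, D)))
  expect_equal(mntd(t, ab, weighted = TRUE),
               unname(picante::mntd(samp, D, abundance.weighted = TRUE)))
  pdp <- picante::pd(samp, t, include.root = TRUE)
  expect_equal(faith_pd(t, names(ab)[ab > 0]), pdp$PD[1])
})

test_that("faith_pd is monotone when species are added", {
  set.seed(47)
  t <- rand_tree(9)
  sp <- sample(t$tip.label)
  pds <- vapply(seq_along(sp), function(k) faith_pd(t, sp[1:k]), numeric(1))
  expect_true(all(diff(pds) >= -1e-12))
})

test_that("metrics are invariant to species order and tree rotation", {
  set.seed(53)
  t <- rand_tree(8)
  ab <- rand_community(t, 6)
  t2 <- ape::ladderize(t)
  perm <- sample(names(ab))
  for (f in list(function(tr, a) mpd(tr, a, weighted = TRUE),
                 function(tr, a) mntd(tr, a, weighted = TRUE),
                 pae, iac)) {
    expect_equal(f(t, ab), f(t, ab[perm]))
    expect_equal(f(t, ab), f(t2, ab))
  }
})

test_that("the diversity table has one reproducible record per cell", {
  set.seed(61)
  trees <- lapply(1:4, function(i) {
    t <- rand_tree(8); t$tip.label <- paste0("s", 1:8); t
  })
  cond1 <- c(rbcL = TRUE, matK = TRUE, ITS = FALSE, ITS2 = FALSE,
             backbone = FALSE)
  cond2 <- c(rbcL = TRUE, matK = TRUE, ITS = TRUE, ITS2 = FALSE,
             backbone = TRUE)
  sets <- list(topology_set(trees[1:2], cond1),
               topology_set(trees[3:4], cond2))
  cm <- rbind(p1 = c(2, 1, 3, 0, 1, 0, 2, 1),
              p2 = c(0, 2, 1, 1, 0, 2, 1, 0))
  colnames(cm) <- paste0("s", 1:8)
  div <- compute_diversity_table(sets, cm)
  expect_equal(nrow(div), 7 * 4 * 2)
  expect_setequal(unique(div$metric),
                  c("PD", "MPD", "MPD_ed", "MNTD", "MNTD_ed", "PAE", "IAC"))
  # each record reproducible from the single-metric call
  r <- div[div$metric == "PD" & div$plot == "p1" & div$tree_index == 2 &
             !div$ITS, ]
  expect_equal(r$value,
               faith_pd(trees[[2]], colnames(cm)[cm["p1", ] > 0]))
  r2 <- div[div$metric == "MPD_ed" & div$plot == "p2" & div$tree_index == 1 &
              div$ITS, ]
  expect_equal(r2$value, mpd(trees[[3]], cm["p2", ], weighted = TRUE))

  # permuting species columns leaves values unchanged
  perm <- sample(colnames(cm))
  div2 <- compute_diversity_table(sets, cm[, perm])
  expect_equal(div$value, div2$value)

  # single tree, single plot, PD only
  one <- compute_diversity_table(list(sets[[1]]), cm["p1", , drop = FALSE],
                                 metrics = "PD")
  expect_equal(nrow(one), 2)
  expect_equal(one$value[1], faith_pd(trees[[1]], colnames(cm)[cm[1, ] > 0]))
})
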