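test_that("condition enumeration reproduces the study design", {
  sm <- enumerate_supermatrices()
  expect_equal(nrow(sm), 7)
  # the seven published combinations (a)-(g)
  key <- apply(sm, 1, function(r)
    paste(c("R", "M", "I", "I2")[as.logical(r)], collapse = "+"))
  expect_setequal(key, c("R+M", "R+I", "R+I2", "M+I", "M+I2",
                         "R+M+I", "R+M+I2"))
  expect_false(any(sm$ITS & sm$ITS2))

  conds <- enumerate_conditions()
  expect_equal(nrow(conds), 14)
  expect_equal(sum(conds$backbone), 7)
})

test_that("the true tree is a seeded, unit-height ultrametric Yule tree", {
  t1 <- simulate_true_tree(114, seed = 10)
  t2 <- simulate_true_tree(114, seed = 10)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_length(t1$tip.label, 114)
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), 1)
  expect_error(simulate_true_tree(2), "at least 3")
})

test_that("lineage growth through time is exponential in expectation", {
  # pure-birth property: the expected lineage count grows like e^(lambda t),
  # so the replicate-averaged lineages-through-time curve is log-linear
  n <- 64
  reps <- 30
  grid <- seq(0.1, 0.9, by = 0.05)
  ltt <- sapply(1:reps, function(s) {
    t <- simulate_true_tree(n, seed = 700 + s)  # unit height
    bt <- ape::branching.times(t)               # node ages, root = 1
    vapply(grid, function(g) 1 + sum(bt > 1 - g), numeric(1))
  })
  meanN <- rowMeans(ltt)
  fit <- stats::lm(log(meanN) ~ grid)
  expect_gt(stats::coef(fit)[["grid"]], 0)
  expect_gt(summary(fit)$r.squared, 0.98)
})

test_that("family assignment cuts monophyletic clades covering all tips", {
  truth <- simulate_true_tree(40, seed = 3)
  fam <- assign_families(truth, 8)
  expect_equal(sort(fam$species), sort(truth$tip.label))
  expect_length(unique(fam$family), 8)
  for (f in unique(fam$family)) {
    sp <- fam$species[fam$family == f]
    if (length(sp) > 1) expect_true(ape::is.monophyletic(truth, sp))
  }
})

test_that("topology sets are seeded and sized, with intensity-0 identity", {
  truth <- simulate_true_tree(20, seed = 1)
  cond <- c(rbcL = TRUE, matK = TRUE, ITS = FALSE, ITS2 = FALSE,
            backbone = FALSE)
  ts0 <- simulate_topology_set(truth, cond, 10, intensity = 0,
                               length_mult = 1, jitter_sd = 0, seed = 5)
  expect_length(ts0$trees, 10)
  expect_true(all(vapply(ts0$trees, rf_distance, numeric(1), truth) == 0))
  expect_equal(ts0$trees[[1]]$edge.length, truth$edge.length)

  a <- simulate_topology_set(truth, cond, 5, intensity = 2, jitter_sd = 0.2,
                             seed = 8)
  b <- simulate_topology_set(truth, cond, 5, intensity = 2, jitter_sd = 0.2,
                             seed = 8)
  expect_equal(lapply(a$trees, ape::write.tree),
               lapply(b$trees, ape::write.tree))
})

test_that("mean RF distance to the truth increases with NNI intensity", {
  truth <- simulate_true_tree(25, seed = 2)
  cond <- c(rbcL = TRUE, matK = FALSE, ITS = FALSE, ITS2 = FALSE,
            backbone = FALSE)
  mean_rf <- vapply(c(0, 1, 5), function(int) {
    ts <- simulate_topology_set(truth, cond, 60, intensity = int,
                                jitter_sd = 0, seed = 30 + int)
    mean(vapply(ts$trees, rf_distance, numeric(1), truth))
  }, numeric(1))
  expect_equal(mean_rf[1], 0)
  expect_lt(mean_rf[1], mean_rf[2])
  expect_lt(mean_rf[2], mean_rf[3])
})

test_that("backbone-constrained sets keep family-level RF at zero", {
  truth <- simulate_true_tree(30, seed = 6)
  fam <- assign_families(truth, 6)
  backbone <- condense_to_families(truth, fam)
  cond <- c(rbcL = TRUE, matK = TRUE, ITS = TRUE, ITS2 = FALSE,
            backbone = TRUE)
  ts <- simulate_topology_set(truth, cond, 25, intensity = 4,
                              jitter_sd = 0.2, seed = 13, family_map = fam)
  rfs <- vapply(ts$trees, function(t)
    rf_distance(condense_to_families(t, fam), backbone), numeric(1))
  expect_true(all(rfs == 0))
  # moves do happen within families
  rft <- vapply(ts$trees, rf_distance, numeric(1), truth)
  expect_gt(mean(rft), 0)
})

test_that("communities honour richness, overlap and abundance floors", {
  truth <- simulate_true_tree(114, seed = 4)
  cfg <- synth_config()
  cm <- simulate_communities(truth, cfg, seed = 21)
  expect_equal(unname(rowSums(cm > 0)), c(75, 73))
  expect_equal(sum(colSums(cm) > 0), 114)
  shared <- sum(cm[1, ] > 0 & cm[2, ] > 0)
  expect_equal(shared, 34)
  expect_true(all(cm[cm > 0] >= 1))
  cm2 <- simulate_communities(truth, cfg, seed = 21)
  expect_equal(cm, cm2)
  # infeasible design: pool smaller than pooled richness
  expect_error(simulate_communities(simulate_true_tree(50, 1),
                                    synth_config(), 1),
               "infeasible")
})

test_that("abundances follow the configured geometric distribution", {
  truth <- simulate_true_tree(114, seed = 4)
  cfg <- synth_config(abund_p = 0.3)
  rejections <- 0
  for (s in 1:20) {
    cm <- simulate_communities(truth, cfg, seed = 400 + s)
    x <- cm[cm > 0] - 1
    # chi-square GOF against Geom(0.3), pooling the tail
    kmax <- max(3, stats::qgeom(0.95, 0.3))
    obs <- tabulate(pmin(x, kmax) + 1, nbins = kmax + 1)
    p <- stats::dgeom(0:kmax, 0.3)
    p[kmax + 1] <- 1 - stats::pgeom(kmax - 1, 0.3)
    cs <- suppressWarnings(stats::chisq.test(obs, p = p))
    if (cs$p.value < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 2)
})

test_that("config validation rejects inconsistent designs", {
  expect_error(synth_config(richness = c(10, 10), shared = 15))
  expect_error(synth_config(n_species = 10, richness = c(8, 8), shared = 2))
  expect_error(synth_config(jitter_sd = -1))
  expect_error(synth_config(length_mult = c(rbcL = 0, matK = 1, ITS = 1,
                                            ITS2 = 1, backbone = 1)))
})
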