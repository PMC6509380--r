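test_that("the model set has 24 unique specs with the ITS/ITS2 exclusion", {
  specs <- enumerate_models()
  expect_length(specs, 24)
  labels <- vapply(specs, model_label, character(1))
  expect_equal(anyDuplicated(labels), 0L)
  expect_true("~1" %in% labels)                     # intercept-only
  expect_true("~B + M + R + I" %in% labels)         # full model, ITS slot
  expect_false(any(vapply(specs, function(s)
    all(c("ITS", "ITS2") %in% s), logical(1))))
})

test_that("ML fits agree with lme4 across several specs", {
  skip_if_not_installed("lme4")
  df <- make_model_df(n_per_cell = 20,
                      effects = c(ITS = 0.4, backbone = 0.2), seed = 2)
  for (spec in list(character(0), "ITS", c("rbcL", "matK"),
                    c("rbcL", "matK", "ITS", "backbone"),
                    c("matK", "ITS2", "backbone"))) {
    f <- fit_lmm(df, spec)
    form <- if (length(spec) == 0) log(value) ~ 1 + (1 | plot) else
      stats::as.formula(paste("log(value) ~",
                              paste(spec, collapse = "+"), "+ (1|plot)"))
    m <- lme4::lmer(form, data = df, REML = FALSE)
    expect_equal(f$loglik, as.numeric(stats::logLik(m)), tolerance = 1e-6)
    expect_equal(unname(f$beta), unname(lme4::fixef(m)), tolerance = 1e-5)
    expect_equal(unname(f$se), unname(sqrt(diag(as.matrix(vcov(m))))),
                 tolerance = 1e-4)
    vc <- as.data.frame(lme4::VarCorr(m))
    expect_equal(f$sigma_b2, vc$vcov[1], tolerance = 1e-5)
    expect_equal(f$sigma_e2, vc$vcov[2], tolerance = 1e-6)
  }
})

test_that("zero between-plot variance collapses to the OLS closed form", {
  df <- make_model_df(n_per_cell = 15, effects = c(ITS = 0.5),
                      plot_offset = 0, sd = 0.1, seed = 3)
  f <- fit_lmm(df, c("rbcL", "ITS"))
  X <- cbind(1, as.numeric(df$rbcL), as.numeric(df$ITS))
  ols <- solve(crossprod(X), crossprod(X, log(df$value)))
  expect_lt(f$sigma_b2, 0.05 * f$sigma_e2)  # plot variance collapses
  expect_equal(unname(f$beta), drop(ols), tolerance = 1e-6)
})

test_that("intercept-only fit on a constant response recovers log c", {
  df <- make_model_df(n_per_cell = 5, seed = 4)
  df$value <- exp(1.25)
  f <- fit_lmm(df, character(0))
  expect_equal(unname(f$beta), 1.25)
  expect_lt(f$sigma_e2, 1e-12)
})

test_that("non-positive responses and constant terms follow policy", {
  df <- make_model_df(n_per_cell = 5, seed = 5)
  df$value[3] <- 0
  expect_error(fit_lmm(df, "ITS"), "strictly positive")
  df2 <- make_model_df(n_per_cell = 5, seed = 6)
  df2$backbone <- TRUE  # constant in the data
  expect_warning(f <- fit_lmm(df2, c("ITS", "backbone")),
                 "constant term")
  expect_false("backbone" %in% f$terms)
})

test_that("a known injected effect is recovered across seeded replicates", {
  hits <- 0
  for (s in 1:30) {
    df <- make_model_df(n_per_cell = 8, effects = c(backbone = 0.5),
                        sd = 0.3, seed = 100 + s)
    f <- fit_lmm(df, c("rbcL", "matK", "ITS", "backbone"))
    z <- abs(f$beta[["backbone"]] - 0.5) / f$se[["backbone"]]
    if (z < 3) hits <- hits + 1
  }
  expect_gte(hits, 28)  # ~3 SE coverage
})

test_that("log-likelihood never decreases when adding a term", {
  df <- make_model_df(n_per_cell = 10, effects = c(ITS = 0.3), seed = 7)
  nested <- list(character(0), "ITS", c("ITS", "matK"),
                 c("ITS", "matK", "rbcL"),
                 c("ITS", "matK", "rbcL", "backbone"))
  lls <- vapply(nested, function(sp) fit_lmm(df, sp)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("AICc, Akaike weights and R2 arithmetic match closed forms", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-9)
  expect_error(aicc(0, 9, 10), "n > k")
  # AICc -> AIC at large n
  expect_lt(abs(aicc(-10, 3, 1e9) - (20 + 6)), 1e-6)

  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))),
               tolerance = 1e-9)
  expect_equal(sum(akaike_weights(c(3, 7, 12, 4))), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(rep(5, 4)), rep(0.25, 4))

  fake <- structure(list(var_fixed = 1, sigma_b2 = 2, sigma_e2 = 1),
                    class = "lmm_fit")
  expect_equal(unname(r2_nakagawa(fake)), c(25, 75), tolerance = 1e-9)
  fake2 <- structure(list(var_fixed = 1, sigma_b2 = 0, sigma_e2 = 1),
                     class = "lmm_fit")
  r2 <- r2_nakagawa(fake2)
  expect_equal(r2[["Rm2"]], r2[["Rc2"]])
})

test_that("model comparison is sorted with coherent weights and R2 bounds", {
  df <- make_model_df(n_per_cell = 10, effects = c(ITS = 0.5), seed = 8)
  mc <- model_comparison(df)
  expect_equal(nrow(mc$table), 24)
  expect_equal(mc$table$dAICc[1], 0)
  expect_true(all(diff(mc$table$AICc) >= 0))
  expect_equal(sum(mc$table$wAICc), 1, tolerance = 1e-12)
  expect_true(all(mc$table$Rm2 <= mc$table$Rc2 + 1e-9))
  expect_true(all(mc$table$Rm2 >= 0 & mc$table$Rc2 <= 100))
  # intercept-only model explains no fixed-effect variance
  i0 <- which(mc$table$model == "~1")
  expect_equal(mc$table$Rm2[i0], 0, tolerance = 1e-12)
  # the generating term is in the top model
  expect_true("ITS" %in% mc$top_spec)
})

test_that("averaged standardized coefficients renormalize weights per term", {
  mkfit <- function(terms, beta, se) {
    b <- c(1, beta); s <- c(0.1, se)
    names(b) <- names(s) <- c("(Intercept)", terms)
    structure(list(terms = terms, beta = b, se = s), class = "lmm_fit")
  }
  fits <- list(mkfit("ITS", 2, 1), mkfit("ITS", 3, 1), mkfit("matK", 5, 1))
  out <- averaged_std_coefs(fits, weights = c(0.3, 0.2, 0.5))
  # ITS: weights renormalized to (0.6, 0.4) over its two models
  expect_equal(out$coef[out$term == "ITS"], 0.6 * 2 + 0.4 * 3)
  # matK appears once: its own beta/SE regardless of global weight
  expect_equal(out$coef[out$term == "matK"], 5)
  expect_false("rbcL" %in% out$term)

  # identical z in every model averages to itself
  fits2 <- list(mkfit("ITS", 4, 2), mkfit("ITS", 4, 2))
  out2 <- averaged_std_coefs(fits2, weights = c(0.9, 0.1))
  expect_equal(out2$coef, 2)
})

test_that("bootstrap inference is seeded, stratified and degenerate-safe", {
  df <- make_model_df(n_per_cell = 10, effects = c(ITS = 0.6), sd = 0.2,
                      seed = 9)
  b1 <- bootstrap_inference(df, B = 20, seed = 11)
  b2 <- bootstrap_inference(df, B = 20, seed = 11)
  expect_equal(b1$coefs, b2$coefs)
  expect_equal(b1$stability, b2$stability)
  expect_true(all(b1$coefs$lo <= b1$coefs$hi))

  # one replicate equals a by-hand stratified resample fed to fit_lmm
  cellid <- interaction(df$rbcL, df$matK, df$ITS, df$ITS2, df$backbone,
                        df$plot, drop = TRUE)
  idx <- with_seed(11, {
    unlist(lapply(split(seq_len(nrow(df)), cellid), function(i)
      i[sample.int(length(i), length(i), replace = TRUE)]))
  })
  mc_naive <- model_comparison(df[idx, ])
  z_naive <- averaged_std_coefs(mc_naive)
  expect_equal(unname(b1$replicates[1, "ITS"]),
               z_naive$coef[z_naive$term == "ITS"], tolerance = 1e-4)

  # zero within-cell variance -> zero-width intervals
  dfc <- df
  dfc$value <- exp(as.numeric(dfc$ITS) * 0.5 + 2 +
                     0.1 * (dfc$plot == "p1"))
  bc <- bootstrap_inference(dfc, B = 10, seed = 3)
  expect_lt(max(bc$coefs$hi - bc$coefs$lo), 1e-8)
})
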