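# Multi-model mixed-effects inference: the 24-model set over barcode and
# backbone indicators, exact maximum-likelihood fits of the plot
# random-intercept model, AICc machinery, Nakagawa R2 decomposition,
# weight-renormalized model-averaged standardized coefficients, and the
# stratified bootstrap robustness check.
#
# The fitter is an exact profiled-ML implementation specialized to the
# single-random-intercept structure: for a variance ratio gamma =
# sigma_b^2 / sigma_e^2 the GLS estimates and the profiled residual variance
# have closed forms in per-plot sufficient statistics, leaving a
# one-dimensional optimization over log(gamma). This makes the ~10^5 model
# fits of the bootstrap robustness check tractable; tests verify agreement
# with lme4's ML fits.

FIXED_TERMS <- c("rbcL", "matK", "ITS", "ITS2", "backbone")
TERM_CODES <- c(backbone = "B", matK = "M", rbcL = "R", ITS = "I", ITS2 = "I2")

#' Enumerate the candidate mixed-model specifications
#'
#' All crossings of the plastid subsets ({}, rbcL, matK, rbcL+matK), the
#' nuclear slot ({}, ITS, ITS2; ITS and ITS2 never co-occur), and the
#' backbone indicator -- 24 specifications including the intercept-only
#' model. Every spec carries the global intercept and the plot random
#' intercept implicitly.
#'
#' @return List of character vectors of fixed-effect terms (the
#'   intercept-only model is `character(0)`).
#' @export
enumerate_models <- function() {
  plastid <- list(character(0), "rbcL", "matK", c("rbcL", "matK"))
  nuclear <- list(character(0), "ITS", "ITS2")
  bb <- list(character(0), "backbone")
  specs <- list()
  for (p in plastid) for (nu in nuclear) for (b in bb)
    specs[[length(specs) + 1L]] <- c(p, nu, b)
  specs
}

#' Model label in compact term notation
#'
#' Terms are coded B (backbone), M (matK), R (rbcL), I (ITS), I2 (ITS2),
#' in that order; the intercept-only model is `~1`.
#'
#' @param spec character vector of terms.
#' @return A string such as `"~B + M + R + I"`.
#' @export
model_label <- function(spec) {
  if (length(spec) == 0) return("~1")
  codes <- TERM_CODES[intersect(names(TERM_CODES), spec)]
  paste0("~", paste(codes, collapse = " + "))
}

# ---- sufficient statistics -------------------------------------------------

# Per-plot cross-products of the full design (intercept + all indicators)
# and the log response; everything any of the 24 fits needs.
lmm_suffstats <- function(df, response = "value") {
  stopifnot(all(c(response, "plot", FIXED_TERMS) %in% names(df)))
  y <- df[[response]]
  keep <- is.finite(y)
  if (!all(keep)) {
    warning(sum(!keep), " non-finite response value(s) dropped")
    df <- df[keep, , drop = FALSE]
    y <- y[keep]
  }
  if (any(y <= 0))
    stop("response must be strictly positive for the log transform; ",
         "offset non-positive metrics (e.g. IAC zeros) before fitting")
  y <- log(y)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(sapply(df[FIXED_TERMS], as.numeric)))
  g <- as.character(df$plot)
  groups <- unique(g)
  if (length(groups) < 2) stop("at least two plots are required")
  st <- lapply(groups, function(gr) {
    i <- which(g == gr)
    Xi <- X[i, , drop = FALSE]; yi <- y[i]
    list(XtX = crossprod(Xi), Xty = drop(crossprod(Xi, yi)),
         yty = sum(yi * yi), sx = colSums(Xi), sy = sum(yi),
         n = length(i))
  })
  names(st) <- groups
  structure(list(groups = st, n = length(y), p_all = ncol(X),
                 colnames = colnames(X)),
            class = "lmm_suffstats")
}

# core profiled-ML optimization given fixed design pieces and y-statistics;
# everything the per-gamma evaluation needs is precomputed
ml_optimize <- function(pieces, ystats, tol = 1e-7) {
  XtX <- pieces$XtX; Sxx <- pieces$Sxx; sx <- pieces$sx
  ng <- pieces$ng; n <- pieces$n
  sumXtX <- pieces$sumXtX
  Xty <- ystats$Xty; sy <- ystats$sy; yty <- ystats$yty
  q <- length(ng)
  sumXty <- Xty[[1]]; for (k in seq_len(q - 1) + 1) sumXty <- sumXty + Xty[[k]]
  sumyty <- sum(yty)

  prof <- function(gamma, full = FALSE) {
    cg <- gamma / (1 + gamma * ng)
    A <- sumXtX
    b <- sumXty
    for (k in seq_len(q)) {
      A <- A - cg[k] * Sxx[[k]]
      b <- b - cg[k] * sy[k] * sx[[k]]
    }
    beta <- solve(A, b)
    rss <- sumyty - sum(cg * sy * sy) - sum(b * beta)
    sigma2 <- max(rss, 1e-300) / n
    m2ll <- n * log(2 * pi * sigma2) + n + sum(log1p(gamma * ng))
    if (!full) return(m2ll)
    list(m2ll = m2ll, beta = beta, A = A, sigma2 = sigma2)
  }
  opt <- stats::optimize(function(lg) prof(exp(lg)),
                         interval = c(-14, 10), tol = tol)
  m0 <- prof(0)
  gamma <- if (m0 <= opt$objective) 0 else exp(opt$minimum)
  sol <- prof(gamma, full = TRUE)
  sol$gamma <- gamma
  sol
}

# Exact profiled ML for y = X beta + plot intercept + noise given
# sufficient statistics and a column subset.
fit_lmm_stats <- function(st, terms) {
  cols <- c("(Intercept)", terms)
  ci <- match(cols, st$colnames)
  G <- st$groups
  n <- st$n
  # drop terms with no variation in the data (rank-deficiency guard)
  if (length(terms) > 0) {
    totXtX <- Reduce(`+`, lapply(G, `[[`, "XtX"))
    totsx <- Reduce(`+`, lapply(G, `[[`, "sx"))
    keep <- vapply(ci, function(j) {
      v <- totXtX[j, j] - totsx[j]^2 / n
      j == match("(Intercept)", st$colnames) || v > 1e-12
    }, logical(1))
    if (!all(keep)) {
      warning("dropping constant term(s): ",
              paste(cols[!keep], collapse = ", "))
      cols <- cols[keep]; ci <- ci[keep]
    }
  }
  p <- length(ci)
  pieces <- list(
    XtX = lapply(G, function(s) s$XtX[ci, ci, drop = FALSE]),
    Sxx = lapply(G, function(s) tcrossprod(s$sx[ci])),
    sx = lapply(G, function(s) s$sx[ci]),
    ng = vapply(G, `[[`, numeric(1), "n"),
    n = n)
  pieces$sumXtX <- Reduce(`+`, pieces$XtX)
  ystats <- list(Xty = lapply(G, function(s) s$Xty[ci]),
                 sy = vapply(G, `[[`, numeric(1), "sy"),
                 yty = vapply(G, `[[`, numeric(1), "yty"))
  dcheck <- tryCatch(qr(pieces$sumXtX)$rank, error = function(e) 0L)
  if (dcheck < p)
    stop("rank-deficient design for terms: ", paste(cols, collapse = ", "))
  sol <- ml_optimize(pieces, ystats)
  gamma <- sol$gamma
  vc <- sol$sigma2 * solve(sol$A)
  se <- sqrt(pmax(diag(vc), 0))
  beta <- drop(sol$beta)
  names(beta) <- names(se) <- cols
  # variance of the fixed-effect predictor over the data (for Nakagawa R2)
  quad <- drop(crossprod(beta, pieces$sumXtX %*% beta))
  lin <- sum(beta * Reduce(`+`, pieces$sx))
  var_fixed <- if (n > 1) (quad - lin^2 / n) / (n - 1) else 0
  structure(list(
    terms = setdiff(cols, "(Intercept)"),
    beta = beta, se = se,
    sigma_b2 = gamma * sol$sigma2, sigma_e2 = sol$sigma2,
    var_fixed = max(var_fixed, 0),
    loglik = -0.5 * sol$m2ll,
    n = n, k = p + 2L), class = "lmm_fit")
}

#' Fit the plot random-intercept mixed model for one specification
#'
#' Maximum-likelihood fit of `log(value)` on 0/1 barcode and backbone
#' indicators with a global intercept and a plot random intercept. ML (not
#' REML) is used throughout because the model set varies in its fixed
#' effects and is compared by AICc.
#'
#' @param df diversity table filtered to one metric (columns `value`,
#'   `plot`, and the indicator columns `rbcL`, `matK`, `ITS`, `ITS2`,
#'   `backbone`).
#' @param spec character vector of fixed terms (see [enumerate_models()]).
#' @return An `lmm_fit` with coefficients, standard errors, variance
#'   components (`sigma_b2` plot intercept, `sigma_e2` residual),
#'   log-likelihood, `n` and parameter count `k` (fixed coefficients plus
#'   two variance components).
#' @export
fit_lmm <- function(df, spec = character(0)) {
  stopifnot(all(spec %in% FIXED_TERMS))
  fit_lmm_stats(lmm_suffstats(df), spec)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("ML random-intercept fit:", length(x$beta), "fixed coefficients, n =",
      x$n, "\n  logLik =", format(x$loglik),
      " sigma_b2 =", format(x$sigma_b2),
      " sigma_e2 =", format(x$sigma_e2), "\n")
  print(rbind(beta = x$beta, se = x$se))
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return `-2*loglik + 2k + 2k(k+1)/(n-k-1)`.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc requires n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights (model probabilities)
#'
#' @param aiccs numeric vector of AICc values.
#' @return Weights `exp(-delta/2)` normalized to sum to 1, where delta is
#'   each model's AICc minus the minimum.
#' @export
akaike_weights <- function(aiccs) {
  stopifnot(length(aiccs) >= 1, all(is.finite(aiccs)))
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Marginal and conditional R-squared (Nakagawa decomposition)
#'
#' Marginal: variance explained by the fixed effects alone; conditional:
#' by fixed plus random effects. Both as percentages of the total
#' (fixed-predictor + plot-intercept + residual) variance.
#'
#' @param fit an `lmm_fit`.
#' @return Named vector `c(Rm2, Rc2)` in percent.
#' @export
r2_nakagawa <- function(fit) {
  tot <- fit$var_fixed + fit$sigma_b2 + fit$sigma_e2
  if (tot <= 0) stop("total variance is zero; R2 undefined")
  c(Rm2 = 100 * fit$var_fixed / tot,
    Rc2 = 100 * (fit$var_fixed + fit$sigma_b2) / tot)
}

#' Fit and rank the full model set for one metric
#'
#' Fits every specification from [enumerate_models()] by ML, computes AICc,
#' delta-AICc, Akaike weights and the Nakagawa R2 components, and sorts by
#' AICc.
#'
#' @param df diversity table filtered to one metric (see [fit_lmm()]).
#' @param specs model list; defaults to the full 24-model set.
#' @return A `model_comparison`: list with `table` (data.frame of model
#'   label, AICc, dAICc, wAICc, Rm2, Rc2 sorted by AICc), `fits`, `specs`
#'   and `weights` aligned with `fits`.
#' @export
model_comparison <- function(df, specs = enumerate_models()) {
  st <- lmm_suffstats(df)
  model_comparison_stats(st, specs)
}

model_comparison_stats <- function(st, specs = enumerate_models()) {
  fits <- lapply(specs, function(sp) fit_lmm_stats(st, sp))
  ic <- vapply(fits, function(f) aicc(f$loglik, f$k, f$n), numeric(1))
  w <- akaike_weights(ic)
  r2 <- t(vapply(fits, r2_nakagawa, numeric(2)))
  tab <- data.frame(
    model = vapply(specs, model_label, character(1)),
    AICc = ic, dAICc = ic - min(ic), wAICc = w,
    Rm2 = r2[, 1], Rc2 = r2[, 2], stringsAsFactors = FALSE)
  ord <- order(ic)
  structure(list(table = tab[ord, , drop = FALSE],
                 fits = fits, specs = specs, weights = w,
                 top_spec = specs[[ord[1]]]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("model_comparison:", length(x$fits), "models; top:",
      x$table$model[1], "(wAICc =", format(x$table$wAICc[1], digits = 3),
      ")\n")
  print(utils::head(x$table, 5), row.names = FALSE)
  invisible(x)
}

#' Model-averaged standardized coefficients
#'
#' For each term, the standardized coefficient beta/SE is averaged over the
#' models containing that term, with the Akaike weights renormalized to sum
#' to 1 over exactly those models.
#'
#' @param mc a `model_comparison`, or a list of fits plus `weights`.
#' @param weights Akaike weights aligned with the fits (taken from `mc` when
#'   a `model_comparison` is given).
#' @return data.frame with columns `term` and `coef` (averaged beta/SE).
#' @export
averaged_std_coefs <- function(mc, weights = NULL) {
  if (inherits(mc, "model_comparison")) {
    fits <- mc$fits; weights <- mc$weights
  } else {
    fits <- mc
    stopifnot(!is.null(weights), length(weights) == length(fits))
  }
  out <- lapply(FIXED_TERMS, function(tm) {
    has <- vapply(fits, function(f) tm %in% f$terms, logical(1))
    if (!any(has)) return(NULL)
    w <- weights[has] / sum(weights[has])
    z <- vapply(fits[has], function(f) f$beta[[tm]] / f$se[[tm]], numeric(1))
    data.frame(term = tm, coef = sum(w * z), stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# ---- bootstrap robustness check -------------------------------------------

# cell decomposition used for stratified resampling: one cell per
# (condition x plot); X is constant within a cell, so only the y-statistics
# change under resampling
boot_cells <- function(df, response = "value") {
  y <- df[[response]]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("response must be finite and strictly positive")
  y <- log(y)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(sapply(df[FIXED_TERMS], as.numeric)))
  g <- as.character(df$plot)
  cell <- interaction(df$rbcL, df$matK, df$ITS, df$ITS2, df$backbone, g,
                      drop = TRUE)
  idx <- split(seq_len(nrow(df)), cell)
  if (any(lengths(idx) == 0)) stop("empty (condition x plot) cell")
  cells <- lapply(idx, function(i) {
    list(x = X[i[1], ], y = y[i], g = g[i[1]], n = length(i))
  })
  groups <- unique(g)
  list(cells = cells, groups = groups, colnames = colnames(X))
}

# averaged standardized coefficients as a plain named vector (fast path)
avg_std_vec <- function(betas, ses, has, weights) {
  # betas/ses: list per model of named vectors; has: logical matrix
  # models x terms
  out <- rep(NA_real_, ncol(has))
  names(out) <- colnames(has)
  for (j in seq_len(ncol(has))) {
    m <- which(has[, j])
    if (length(m) == 0) next
    w <- weights[m] / sum(weights[m])
    tm <- colnames(has)[j]
    z <- vapply(m, function(i) betas[[i]][[tm]] / ses[[i]][[tm]], numeric(1))
    out[j] <- sum(w * z)
  }
  out
}

#' Bootstrap robustness check of the multi-model inference
#'
#' Resamples records with replacement within each (condition x plot) cell,
#' reruns the full model comparison per replicate, and summarizes the
#' model-averaged standardized coefficients (mean and 95 percent percentile
#' interval per term) together with the fraction of replicates in which the
#' original top-ranked model stays top-ranked.
#'
#' @param df diversity table filtered to one metric.
#' @param B number of bootstrap replicates (default 100).
#' @param seed integer seed.
#' @param specs model list; defaults to the full 24-model set.
#' @return List with `coefs` (data.frame: term, mean, lo, hi), `stability`
#'   (fraction of replicates preserving the original top model),
#'   `top_model` (original top label) and `replicates` (B x term matrix).
#' @export
bootstrap_inference <- function(df, B = 100, seed = NULL,
                                specs = enumerate_models()) {
  stopifnot(B >= 2)
  bc <- boot_cells(df)
  orig <- model_comparison(df, specs)
  top_label <- orig$table$model[1]
  labels <- vapply(specs, model_label, character(1))

  # design pieces are identical across replicates; precompute per spec
  st0 <- lmm_suffstats(df)
  G <- st0$groups
  ci_all <- lapply(specs, function(sp) {
    match(c("(Intercept)", intersect(FIXED_TERMS, sp)), st0$colnames)
  })
  pieces_all <- lapply(ci_all, function(ci) {
    p <- list(XtX = lapply(G, function(s) s$XtX[ci, ci, drop = FALSE]),
              Sxx = lapply(G, function(s) tcrossprod(s$sx[ci])),
              sx = lapply(G, function(s) s$sx[ci]),
              ng = vapply(G, `[[`, numeric(1), "n"),
              n = st0$n)
    p$sumXtX <- Reduce(`+`, p$XtX)
    p
  })
  ks <- vapply(ci_all, function(ci) length(ci) + 2, numeric(1))
  n_obs <- st0$n
  term_names <- st0$colnames[-1]
  has <- t(vapply(specs, function(sp) term_names %in% sp,
                  logical(length(term_names))))
  colnames(has) <- term_names
  cell_g <- vapply(bc$cells, `[[`, character(1), "g")
  gsel <- lapply(names(G), function(gr) which(cell_g == gr))
  cell_x <- lapply(bc$cells, `[[`, "x")

  run_rep <- function(ydraw) {
    # full-design y-statistics per group from cell draws
    s1 <- vapply(ydraw, sum, numeric(1))
    s2 <- vapply(ydraw, function(y) sum(y * y), numeric(1))
    Xty_g <- lapply(gsel, function(sel) {
      v <- 0
      for (k in sel) v <- v + cell_x[[k]] * s1[k]
      v
    })
    sy_g <- vapply(gsel, function(sel) sum(s1[sel]), numeric(1))
    yty_g <- vapply(gsel, function(sel) sum(s2[sel]), numeric(1))
    ics <- numeric(length(specs))
    betas <- vector("list", length(specs))
    ses <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      ci <- ci_all[[i]]
      sol <- ml_optimize(pieces_all[[i]],
                         list(Xty = lapply(Xty_g, `[`, ci),
                              sy = sy_g, yty = yty_g), tol = 1e-6)
      ll <- -0.5 * sol$m2ll
      ics[i] <- aicc(ll, ks[i], n_obs)
      se <- sqrt(pmax(diag(sol$sigma2 * solve(sol$A)), 0))
      b <- drop(sol$beta)
      names(b) <- names(se) <- st0$colnames[ci]
      betas[[i]] <- b; ses[[i]] <- se
    }
    w <- akaike_weights(ics)
    list(coefs = avg_std_vec(betas, ses, has, w),
         top = labels[which.min(ics)])
  }

  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      ydraw <- lapply(bc$cells, function(cl) {
        cl$y[sample.int(cl$n, cl$n, replace = TRUE)]
      })
      run_rep(ydraw)
    })
  })
  mat <- t(vapply(reps, `[[`, numeric(length(term_names)), "coefs"))
  colnames(mat) <- term_names
  mat <- mat[, colSums(!is.na(mat)) > 0, drop = FALSE]
  qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  coefs <- data.frame(term = colnames(mat),
                      mean = colMeans(mat, na.rm = TRUE),
                      lo = qs[1, ], hi = qs[2, ],
                      stringsAsFactors = FALSE, row.names = NULL)
  stability <- mean(vapply(reps, `[[`, character(1), "top") == top_label)
  list(coefs = coefs, stability = stability, top_model = top_label,
       replicates = mat)
}
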