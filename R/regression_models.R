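# Compound-level regression screens: OLS with cluster-robust (CR1) standard
# errors and DFFITS exclusion against phylogenetic diversity, and
# random-intercept mixed models with Satterthwaite inference and
# leave-one-out influence exclusion against individual taxa.

#' Z-score a vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1, so slope
#' estimates are comparable across compounds.
#'
#' @param x numeric vector with at least two distinct values.
#' @export
zscore <- function(x) {
  if (length(unique(x[!is.na(x)])) < 2L) stop("constant vector",
                                              call. = FALSE)
  (x - mean(x)) / sd(x)
}

#' Arcsinh transform of a relative abundance on the percent scale
#'
#' `arcsinh(100 x) = ln(100x + sqrt((100x)^2 + 1))`; variance-stabilizing,
#' maps 0 to exactly 0.
#'
#' @param relative_abundance value(s) in `[0, 1]`.
#' @export
arcsinh_percent <- function(relative_abundance) {
  if (any(!is.finite(relative_abundance) | relative_abundance < 0 |
          relative_abundance > 1)) {
    stop("relative abundance must lie in [0, 1]", call. = FALSE)
  }
  asinh(100 * relative_abundance)
}

#' Convert a count table to sample-wise relative abundances
#' @param table a [feature_table()].
#' @return matrix of row-wise proportions.
#' @export
relative_abundance <- function(table) {
  table <- feature_table(table)
  sweep(table, 1, rowSums(table), "/")
}

new_regression_result <- function(beta = NA_real_, se = NA_real_,
                                  df = NA_real_, p_value = NA_real_,
                                  n_used = NA_integer_, excluded = FALSE,
                                  reason = NA_character_) {
  structure(list(beta = beta, se = se, df = df, p_value = p_value,
                 n_used = n_used, excluded = excluded, reason = reason),
            class = "regression_result")
}

#' Simple regression with cluster-robust (CR1) standard errors
#'
#' OLS slope of `y` on `x` with a sandwich variance summing score
#' contributions within clusters, small-sample factor
#' `G/(G-1) * (n-1)/(n-k)` (CR1), and a t reference distribution with
#' `G - 1` degrees of freedom.  Valid when observations within a treatment
#' unit are correlated (replicate mice sharing a donor microbiome).
#'
#' @param y,x aligned numeric vectors.
#' @param clusters cluster labels, one per observation; at least 2 clusters.
#' @return a `regression_result` list: `beta`, `se`, `df`, `p_value`,
#'   `n_used`.
#' @export
ols_cluster_robust <- function(y, x, clusters) {
  clusters <- as.character(clusters)
  n <- length(y)
  stopifnot(length(x) == n, length(clusters) == n)
  G <- length(unique(clusters))
  if (G < 2L) stop("need at least 2 clusters", call. = FALSE)
  X <- cbind(1, x)
  k <- ncol(X)
  XtXi <- solve(crossprod(X))
  beta <- drop(XtXi %*% crossprod(X, y))
  e <- y - drop(X %*% beta)
  meat <- matrix(0, k, k)
  for (g in unique(clusters)) {
    sel <- clusters == g
    sg <- crossprod(X[sel, , drop = FALSE], e[sel])
    meat <- meat + tcrossprod(sg)
  }
  adj <- G / (G - 1) * (n - 1) / (n - k)
  V <- adj * XtXi %*% meat %*% XtXi
  se <- sqrt(max(V[2L, 2L], 0))
  df <- G - 1
  b1 <- unname(beta[2L])
  tval <- if (se > 0) b1 / se else Inf * sign(b1 + (b1 == 0))
  p <- if (se > 0) 2 * pt(-abs(tval), df) else 0
  new_regression_result(beta = b1, se = se, df = df, p_value = p, n_used = n)
}

#' DFFITS influence diagnostics for a simple regression
#'
#' Per observation, the studentized change in its fitted value upon
#' deletion, `e_i sqrt(h_i) / (s_(i) (1 - h_i))`.  A regression in the
#' diversity screen is excluded outright when any `|DFFITS| > 1`.
#'
#' @param y,x aligned numeric vectors, `n >= 4`.
#' @return numeric vector of DFFITS values.
#' @export
dffits_simple <- function(y, x) {
  if (length(y) < 4L) stop("DFFITS needs n >= 4", call. = FALSE)
  fit <- lm(y ~ x)
  if (fit$qr$rank < 2L) stop("exact collinearity (constant x)", call. = FALSE)
  if (max(abs(resid(fit))) < 1e-10 * max(1, sd(y))) {
    return(rep(0, length(y)))   # perfect fit: deletion changes nothing
  }
  unname(dffits(fit))
}

#' Diversity screen: each compound against Faith's phylogenetic diversity
#'
#' Per compound: the z-scored abundance is regressed on PD; the regression
#' is excluded when any observation has `|DFFITS| > 1`; otherwise inference
#' uses cluster-robust standard errors with clusters = treatment unit; BH
#' adjustment runs across the surviving compounds.
#'
#' @param compounds a [compound_table()] (samples x compounds).
#' @param pd named numeric vector of Faith PD values (see [faith_pd()]).
#' @param metadata metadata with `sample_id` and `treatment_unit` (see
#'   [sample_metadata()]).
#' @param dffits_threshold exclusion threshold on `|DFFITS|` (default 1).
#' @return data frame: `compound_id`, `fraction`, `beta` (SD of compound per
#'   PD unit), `se`, `df`, `p_value`, `p_adj`, `n_used`, `excluded`,
#'   `reason`.
#' @export
diversity_screen <- function(compounds, pd, metadata, dffits_threshold = 1) {
  ids <- rownames(compounds)
  stopifnot(all(ids %in% names(pd)), all(ids %in% metadata$sample_id))
  x <- pd[ids]
  cl <- metadata$treatment_unit[match(ids, metadata$sample_id)]
  fr <- compound_fractions(compounds)
  areas <- unclass(compounds)
  rows <- lapply(seq_len(ncol(areas)), function(j) {
    res <- tryCatch({
      y <- zscore(areas[, j])
      dff <- dffits_simple(y, x)
      if (any(abs(dff) > dffits_threshold)) {
        new_regression_result(n_used = length(y), excluded = TRUE,
                              reason = sprintf("max |DFFITS| = %.2f > %g",
                                               max(abs(dff)),
                                               dffits_threshold))
      } else {
        ols_cluster_robust(y, x, cl)
      }
    }, error = function(e) {
      new_regression_result(excluded = TRUE, reason = conditionMessage(e))
    })
    data.frame(compound_id = colnames(areas)[j], fraction = fr[j],
               beta = res$beta, se = res$se, df = res$df,
               p_value = res$p_value, n_used = res$n_used,
               excluded = res$excluded, reason = res$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  keep <- !out$excluded
  out$p_adj[keep] <- bh_adjust(out$p_value[keep])
  rownames(out) <- NULL
  out[, c("compound_id", "fraction", "beta", "se", "df", "p_value", "p_adj",
          "n_used", "excluded", "reason")]
}

#' Random-intercept linear mixed model for one compound-taxon pair
#'
#' REML fit of `y ~ x + (1 | unit)` with Wald-t inference on the slope using
#' Satterthwaite's degrees of freedom.  When the intercept-variance estimate
#' is zero the fit coincides with OLS (Satterthwaite df then approaches the
#' residual df).  Non-convergence yields a flagged result, never an abort.
#'
#' @param y response (typically a z-scored compound abundance).
#' @param x fixed predictor (typically `arcsinh_percent` of a relative
#'   abundance).
#' @param unit random-intercept grouping labels (>= 3 units).
#' @return a `regression_result`; the fitted `lmerMod` is attached as
#'   attribute `fit` for downstream influence computation.
#' @export
lmm_random_intercept <- function(y, x, unit) {
  unit <- factor(as.character(unit))
  if (nlevels(unit) < 3L) stop("need at least 3 units", call. = FALSE)
  dat <- data.frame(y = y, x = x, unit = unit)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ x + (1 | unit), data = dat, REML = TRUE))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(new_regression_result(excluded = TRUE,
                                 reason = paste("lmm failed:",
                                                conditionMessage(fit))))
  }
  co <- tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  if (is.null(co) || !"x" %in% rownames(co) || ncol(co) < 5L) {
    return(new_regression_result(excluded = TRUE,
                                 reason = "no slope inference available"))
  }
  df <- co["x", "df"]
  reason <- NA_character_
  if (!is.finite(df) || df <= 0) {
    # Satterthwaite failure: fall back to between-unit df, flagged
    df <- nlevels(unit) - 1
    reason <- "Satterthwaite df unavailable; between-unit df used"
  }
  tval <- co["x", "Estimate"] / co["x", "Std. Error"]
  res <- new_regression_result(beta = co["x", "Estimate"],
                               se = co["x", "Std. Error"], df = df,
                               p_value = 2 * pt(-abs(tval), df),
                               n_used = nrow(dat), reason = reason)
  attr(res, "fit") <- fit
  res
}

# Leave-one-observation-out influence on the fixed slope: max over i of
# |beta_hat - beta_hat(-i)| / se(beta_hat), computed by exact refits.
lmm_max_influence <- function(y, x, unit, beta, se) {
  if (!is.finite(se) || se <= 0) return(Inf)
  n <- length(y)
  delta <- numeric(n)
  for (i in seq_len(n)) {
    ui <- factor(as.character(unit[-i]))
    fit_i <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(yy ~ xx + (1 | uu),
                   data = data.frame(yy = y[-i], xx = x[-i], uu = ui),
                   REML = TRUE))),
      error = function(e) NULL)
    delta[i] <- if (is.null(fit_i)) Inf else
      abs(beta - lme4::fixef(fit_i)[["xx"]])
  }
  max(delta) / se
}

#' Taxon screen: mixed-effects models for every compound-taxon pair
#'
#' For every (compound, taxon) pair fits
#' `zscore(compound) ~ arcsinh(100 * relative abundance) + (1 | treatment unit)`
#' by REML, excludes pairs whose maximum leave-one-out influence on the slope
#' (change in the fixed-effect estimate over its standard error, by exact
#' refit) reaches `influence_threshold`, and BH-adjusts across retained
#' pairs.  `hu_only` restricts to humanized (HU) mice, dropping the
#' low-complexity controls whose distinct community architecture can distort
#' the random-effect assumption.
#'
#' @param compounds a [compound_table()].
#' @param taxa samples x taxa matrix of **relative abundances** (see
#'   [relative_abundance()]).
#' @param metadata metadata with `sample_id`, `group`, `treatment_unit`.
#' @param hu_only logical; restrict to group HU.
#' @param influence_threshold exclusion threshold (default 4).
#' @return data frame: `compound_id`, `taxon_id`, `beta`, `se`, `df`,
#'   `p_value`, `p_adj`, `max_influence`, `n_used`, `excluded`, `reason`.
#' @export
taxon_screen <- function(compounds, taxa, metadata, hu_only = FALSE,
                         influence_threshold = 4) {
  ids <- rownames(compounds)
  stopifnot(all(ids %in% rownames(taxa)), all(ids %in% metadata$sample_id))
  md <- metadata[match(ids, metadata$sample_id), ]
  if (hu_only) {
    ids <- ids[md$group == "HU"]
    md <- md[md$group == "HU", ]
  }
  areas <- unclass(compounds)[ids, , drop = FALSE]
  taxa <- as.matrix(taxa)[ids, , drop = FALSE]
  unit <- md$treatment_unit
  rows <- list()
  for (j in seq_len(ncol(areas))) {
    y_raw <- areas[, j]
    for (t in seq_len(ncol(taxa))) {
      x <- arcsinh_percent(taxa[, t])
      res <- tryCatch({
        if (length(unique(x)) < 2L) stop("constant taxon abundance")
        y <- zscore(y_raw)
        fit <- lmm_random_intercept(y, x, unit)
        if (!fit$excluded) {
          infl <- lmm_max_influence(y, x, unit, fit$beta, fit$se)
          if (infl >= influence_threshold) {
            fit <- new_regression_result(
              beta = fit$beta, se = fit$se, df = fit$df, n_used = fit$n_used,
              excluded = TRUE,
              reason = sprintf("max influence %.2f >= %g", infl,
                               influence_threshold))
          }
          attr(fit, "max_influence") <- infl
        }
        fit
      }, error = function(e) {
        new_regression_result(excluded = TRUE, reason = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = colnames(areas)[j], taxon_id = colnames(taxa)[t],
        beta = res$beta, se = res$se, df = res$df, p_value = res$p_value,
        max_influence = if (is.null(attr(res, "max_influence"))) NA_real_
                        else attr(res, "max_influence"),
        n_used = res$n_used, excluded = res$excluded, reason = res$reason,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  keep <- !out$excluded & !is.na(out$p_value)
  out$p_adj[keep] <- bh_adjust(out$p_value[keep])
  rownames(out) <- NULL
  out[, c("compound_id", "taxon_id", "beta", "se", "df", "p_value", "p_adj",
          "max_influence", "n_used", "excluded", "reason")]
}
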