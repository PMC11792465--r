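# Transformations, cluster-robust OLS, DFFITS, mixed models and the two
# compound-level screens.

test_that("zscore and arcsinh_percent match their closed forms", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(rnorm(20))
  expect_equal(zscore(z), z, tolerance = 1e-12)     # idempotent
  expect_error(zscore(rep(2, 5)), "constant")

  expect_equal(arcsinh_percent(0), 0)
  expect_equal(arcsinh_percent(0.01), log(1 + sqrt(2)), tolerance = 1e-10)
  x <- seq(0, 1, 0.05)
  expect_true(all(diff(arcsinh_percent(x)) > 0))    # monotone
  expect_error(arcsinh_percent(1.5), "\\[0, 1\\]")
})

test_that("cluster-robust variance equals the block-sandwich oracle", {
  set.seed(6)
  for (i in 1:10) {
    G <- sample(2:4, 1)
    sizes <- sample(2:4, G, replace = TRUE)
    n <- sum(sizes)
    cl <- rep(paste0("g", seq_len(G)), sizes)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- ols_cluster_robust(y, x, cl)
    want <- oracle_cr1(y, x, cl)
    expect_equal(got$beta, want$beta, tolerance = 1e-10)
    expect_equal(got$se, want$se, tolerance = 1e-10)
    expect_equal(got$df, G - 1)
  }
  # all-singleton clusters reduce to HC1
  x <- rnorm(8); y <- x + rnorm(8)
  got <- ols_cluster_robust(y, x, paste0("g", 1:8))
  V <- sandwich::vcovHC(lm(y ~ x), type = "HC1")
  expect_equal(got$se, sqrt(V[2, 2]), tolerance = 1e-10)
  # perfect line: zero residual variance
  yy <- 2 + 3 * x
  fit <- ols_cluster_robust(yy, x, rep(c("a", "b"), 4))
  expect_equal(fit$beta, 3); expect_equal(fit$se, 0)
  expect_error(ols_cluster_robust(y, x, rep("a", 8)), "clusters")
})

test_that("DFFITS equals leave-one-out brute force", {
  set.seed(9)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- x + rnorm(n)
    expect_equal(dffits_simple(y, x), oracle_dffits(y, x),
                 tolerance = 1e-10)
  }
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(dffits_simple(2 * x + 1, x), rep(0, 6), tolerance = 1e-10)
  # a gross outlier in a tight design exceeds the |DFFITS| > 1 rule
  x2 <- c(0, 1, 2, 3, 4, 10)
  y2 <- c(0, 1.1, 1.9, 3.2, 3.9, 40)
  expect_gt(max(abs(dffits_simple(y2, x2))), 1)
  expect_error(dffits_simple(rnorm(6), rep(1, 6)), "collinearity")
  expect_error(dffits_simple(rnorm(3), rnorm(3)), "n >= 4")
})

test_that("the mixed model reduces to OLS without unit variance and matches
           an independent REML implementation", {
  set.seed(10)
  x <- rnorm(24)
  unit <- rep(paste0("u", 1:8), each = 3)
  y0 <- 0.7 * x + rnorm(24)                 # no unit effect at all
  fit <- lmm_random_intercept(y0, x, unit)
  ols <- lm(y0 ~ x)
  expect_equal(fit$beta, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(vcov(ols)))[2]), tolerance = 1e-4)

  y1 <- 0.7 * x + rep(rnorm(8, 0, 1), each = 3) + rnorm(24, 0, 0.5)
  fit1 <- lmm_random_intercept(y1, x, unit)
  ref <- nlme::lme(yy ~ xx, random = ~ 1 | uu,
                   data = data.frame(yy = y1, xx = x, uu = unit),
                   method = "REML")
  expect_equal(fit1$beta, unname(nlme::fixef(ref)[2]), tolerance = 1e-4)
  expect_equal(fit1$se, unname(sqrt(diag(ref$varFix))[2]), tolerance = 1e-4)
  expect_error(lmm_random_intercept(y1, x, rep("a", 24)), "units")
})

test_that("the diversity screen recovers a planted PD slope and excludes
           influential regressions", {
  set.seed(14)
  n <- 29
  ids <- paste0("m", 1:n)
  md <- sample_metadata(data.frame(
    sample_id = ids, group = c(rep("HU", 20), rep("LCM", 9)),
    donor_id = c(rep(paste0("D", 1:10), each = 2), rep("", 9)),
    cohort_id = rep(c("c1", "c2", "c3"), length.out = n)))
  pd <- setNames(c(runif(20, 8, 16), runif(9, 3, 5)), ids)
  slope <- -1
  z <- slope * (pd - mean(pd)) / sd(pd) + rnorm(n, 0, 0.3)
  areas <- cbind(planted = 2e5 * (4 + (z - mean(z)) / sd(z)),
                 matrix(rlnorm(n * 5, log(4e5), 0.2), n,
                        dimnames = list(NULL, paste0("noise", 1:5))))
  # one compound with a gross planted outlier
  out_area <- rlnorm(n, log(4e5), 0.1); out_area[1] <- 50 * out_area[1]
  areas <- cbind(areas, outlier = out_area)
  rownames(areas) <- ids
  tab <- compound_table(areas, setNames(rep("aqueous", ncol(areas)),
                                        colnames(areas)))
  scr <- diversity_screen(tab, pd, md)
  planted <- scr[scr$compound_id == "planted", ]
  expect_false(planted$excluded)
  expect_lt(planted$p_adj, 0.05)
  # recovered slope within 20% of the construct's realized PD slope
  eff <- unname(coef(lm(scale(areas[, "planted"]) ~ pd))[2])
  expect_equal(planted$beta, eff, tolerance = 0.2)
  expect_true(scr$excluded[scr$compound_id == "outlier"])
  expect_match(scr$reason[scr$compound_id == "outlier"], "DFFITS")
})

test_that("the taxon screen finds a planted pair and applies the influence
           rule", {
  set.seed(15)
  n <- 29
  ids <- paste0("m", 1:n)
  md <- sample_metadata(data.frame(
    sample_id = ids, group = c(rep("HU", 20), rep("LCM", 9)),
    donor_id = c(rep(paste0("D", 1:10), each = 2), rep("", 9)),
    cohort_id = rep(c("c1", "c2", "c3"), length.out = n)))
  taxa <- matrix(runif(n * 4, 0, 0.2), n,
                 dimnames = list(ids, paste0("t", 1:4)))
  x <- arcsinh_percent(taxa[, "t1"])
  z <- (x - mean(x)) / sd(x) + rnorm(n, 0, 0.3)
  areas <- cbind(planted = 2e5 * (4 + z),
                 matrix(rlnorm(n * 3, log(4e5), 0.2), n,
                        dimnames = list(NULL, paste0("noise", 1:3))))
  rownames(areas) <- ids
  tab <- compound_table(areas, setNames(rep("lipid", 4), colnames(areas)))
  scr <- taxon_screen(tab, taxa, md)
  expect_equal(nrow(scr), 16L)
  kept <- scr[!scr$excluded & !is.na(scr$p_adj), ]
  best <- kept[which.min(kept$p_adj), ]
  expect_equal(best$compound_id, "planted")
  expect_equal(best$taxon_id, "t1")
  expect_lt(best$p_adj, 0.05)
  # hu_only drops the LCM samples
  scr_hu <- taxon_screen(tab, taxa, md, hu_only = TRUE)
  expect_true(all(scr_hu$n_used[!scr_hu$excluded] == 20))
})
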