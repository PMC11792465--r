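# PERMANOVA, centroid collapsing, group averaging, BH adjustment, and the
# per-compound composition screen.

test_that("PERMANOVA separates well-separated groups and matches vegan", {
  set.seed(31)
  pts <- rbind(matrix(rnorm(6, 0, 0.1), 3), matrix(rnorm(6, 10, 0.1), 3))
  rownames(pts) <- paste0("s", 1:6)
  D <- distance_matrix(as.matrix(dist(pts)))
  grp <- rep(c("a", "b"), each = 3)
  res <- permanova(D, grp, n_perm = 999, seed = 2)
  expect_gt(res$r_squared, 0.9)
  expect_lte(res$p_value, 0.15)       # 10 distinct splits at n=6
  ref <- vegan::adonis2(as.dist(D) ~ grp, permutations = 999)
  expect_equal(res$pseudo_F, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-10)

  x <- rnorm(6)
  resc <- permanova(D, x, n_perm = 99, seed = 2)
  refc <- vegan::adonis2(as.dist(D) ~ x, permutations = 99)
  expect_equal(resc$pseudo_F, refc$F[1], tolerance = 1e-10)
  expect_equal(resc$r_squared, refc$R2[1], tolerance = 1e-10)
  expect_error(permanova(D, rep(1, 6), n_perm = 9, seed = 1), "constant")
})

test_that("Monte-Carlo p agrees with exhaustive permutation at n = 6", {
  set.seed(41)
  pts <- matrix(rnorm(12), 6, 2, dimnames = list(paste0("s", 1:6), NULL))
  D <- distance_matrix(as.matrix(dist(pts)))
  x <- rnorm(6)
  # exhaustive oracle: F recomputed through vegan for every permutation
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 6L), ,
                 drop = FALSE]
  expect_equal(nrow(perms), 720L)
  f_obs <- vegan::adonis2(as.dist(D) ~ x, permutations = 2)$F[1]
  f_all <- apply(perms, 1, function(idx) {
    xp <- x[idx]
    vegan::adonis2(as.dist(D) ~ xp, permutations = 2)$F[1]
  })
  p_exact <- mean(f_all >= f_obs - 1e-12)
  res <- permanova(D, x, n_perm = 9999, seed = 3)
  # Monte-Carlo error at 9999 draws
  expect_equal(res$p_value, p_exact,
               tolerance = 4 * sqrt(p_exact * (1 - p_exact) / 9999) + 1e-3)
})

test_that("centroid collapsing matches coordinate-space centroids", {
  set.seed(13)
  for (i in 1:10) {
    k <- sample(3:5, 1)
    sizes <- sample(1:4, k, replace = TRUE)
    pts <- matrix(rnorm(2 * sum(sizes)), ncol = 2)
    groups <- rep(paste0("g", seq_len(k)), sizes)
    ids <- paste0("s", seq_len(sum(sizes)))
    rownames(pts) <- ids
    D <- distance_matrix(as.matrix(dist(pts)))
    got <- collapse_to_centroids(D, setNames(groups, ids))
    cent <- do.call(rbind, lapply(split(seq_along(groups), groups)[
      unique(groups)], function(ii) colMeans(pts[ii, , drop = FALSE])))
    want <- as.matrix(dist(cent))
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
  # singleton groups: identity; duplicated points: the point distance
  pts <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
  D <- distance_matrix(as.matrix(dist(pts)))
  expect_equal(unname(collapse_to_centroids(D, c(a = "a", b = "b"))),
               unname(D))
  dup <- rbind(pts, pts); rownames(dup) <- c("a1", "b1", "a2", "b2")
  Dd <- distance_matrix(as.matrix(dist(dup)))
  got <- collapse_to_centroids(Dd, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  expect_equal(got["A", "B"], 5, tolerance = 1e-10)
})

test_that("abundance collapsing takes arithmetic unit means", {
  x <- matrix(c(2, 4, 6, 8), 2, 2, dimnames = list(c("s1", "s2"),
                                                   c("v1", "v2")))
  g <- c(s1 = "u", s2 = "u")
  expect_equal(unname(collapse_abundances(x, g)["u", ]), c(3, 7))
  g2 <- c(s1 = "a", s2 = "b")
  expect_equal(collapse_abundances(x, g2), x, ignore_attr = TRUE)
  v <- c(s1 = 2, s2 = 4)
  expect_equal(collapse_abundances(v, g)[["u"]], 3)
  # equal-sized groups: mean of means is the grand mean
  y <- setNames(rnorm(6), paste0("s", 1:6))
  gg <- setNames(rep(c("a", "b", "c"), each = 2), names(y))
  expect_equal(mean(collapse_abundances(y, gg)), mean(y))
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(20)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))                      # never decreases
  expect_equal(adj[which.min(p)], min(adj))       # min identity preserved
})

test_that("the composition screen ranks a planted driver first", {
  set.seed(19)
  n <- 13
  ids <- paste0("u", 1:n)
  driver <- rnorm(n)
  pts <- cbind(driver, rnorm(n, 0, 0.2))          # dm structured by driver
  rownames(pts) <- ids
  dm <- distance_matrix(as.matrix(dist(pts)))
  areas <- cbind(planted = 1e5 * (4 + driver),
                 matrix(rlnorm(n * 6, log(4e5), 0.3), n,
                        dimnames = list(NULL, paste0("noise", 1:6))))
  rownames(areas) <- ids
  tab <- compound_table(areas, setNames(rep("lipid", 7), colnames(areas)))
  scr <- compound_composition_screen(dm, tab, n_perm = 499, seed = 11)
  expect_equal(scr$compound_id[which.max(scr$pseudo_F)], "planted")
  expect_true(scr$raw_significant[scr$compound_id == "planted"])
  scr2 <- compound_composition_screen(dm, tab, n_perm = 499, seed = 11)
  expect_equal(scr, scr2)                         # deterministic given seed
  # constant compound flagged, not fatal
  areas2 <- cbind(areas, flat = rep(1e5, n))
  tab2 <- compound_table(areas2, setNames(rep("lipid", 8),
                                          colnames(areas2)))
  scr3 <- compound_composition_screen(dm, tab2, n_perm = 99, seed = 1)
  expect_true(scr3$excluded[scr3$compound_id == "flat"])
})
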