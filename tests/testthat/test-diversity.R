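# Rarefaction, Faith PD, unweighted UniFrac, Bray-Curtis, Jaccard.

test_that("rarefaction conserves depth, is deterministic, and validates", {
  tab <- toy_table(list(c(10, 20, 30, 40), c(25, 25, 25, 25)))
  r1 <- rarefy(tab, 50, seed = 3)
  expect_equal(unname(rowSums(r1)), c(50, 50))
  expect_equal(rarefy(tab, 50, seed = 3), r1)          # same seed
  expect_false(identical(rarefy(tab, 50, seed = 4), r1))
  expect_equal(rarefy(tab, 100, seed = 1)["s2", ], tab["s2", ]) # at depth
  expect_error(rarefy(tab, 101, seed = 1), "s1, s2")
  expect_true(all(rarefy(tab, 50, seed = 3) <= tab))   # subsample w/o repl.
})

test_that("Faith PD matches hand-enumerated spanning branches", {
  tr <- toy_tree()
  tab <- toy_table(list(c(1, 1, 0, 0), c(1, 0, 0, 0), c(1, 1, 1, 1)))
  pd <- faith_pd(tab, tr)
  expect_equal(unname(pd), c(3, 2, 6))    # {A,B}=3; {A}=2; all tips = total
  bad <- feature_table(matrix(c(1, 1), 1, 2,
                              dimnames = list("s1", c("A", "ZZ"))))
  expect_error(faith_pd(bad, tr), "ZZ")
})

test_that("Faith PD is monotone in taxon addition and matches picante", {
  set.seed(11)
  for (i in 1:10) {
    tr <- random_tree(sample(4:12, 1))
    tab <- random_presence_table(4, tr$tip.label)
    pd <- faith_pd(tab, tr)
    expect_equal(unname(pd), oracle_faith_pd(tab, tr), tolerance = 1e-10)
    # adding one absent taxon never decreases PD
    i0 <- which(tab[1, ] == 0)
    if (length(i0)) {
      tab2 <- tab; tab2[1, i0[1]] <- 1
      expect_gte(faith_pd(tab2, tr)[1], pd[1])
    }
  }
  # independent implementation (picante includes the root by default)
  tr <- random_tree(10)
  tab <- random_presence_table(5, tr$tip.label)
  ref <- picante::pd(tab, tr, include.root = TRUE)$PD
  expect_equal(unname(faith_pd(tab, tr)), ref, tolerance = 1e-10)
})

test_that("unweighted UniFrac matches hand values and bounds", {
  tr <- toy_tree()
  tab <- toy_table(list(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 0)))
  d <- unweighted_unifrac(tab, tr)
  expect_equal(d["s1", "s2"], 1 / 3)       # unique B over union 3
  expect_equal(d["s2", "s3"], 1)           # disjoint clades
  expect_equal(d["s1", "s1"], 0)
  expect_true(all(d >= 0 & d <= 1))
  zero <- toy_table(list(c(1, 0, 0, 0), c(1, 0, 0, 0)))
  expect_equal(unweighted_unifrac(zero, tr)["s1", "s2"], 0)
})

test_that("unweighted UniFrac agrees with branch-set enumeration", {
  set.seed(23)
  for (i in 1:10) {
    tr <- random_tree(sample(4:16, 1))
    tab <- random_presence_table(sample(3:6, 1), tr$tip.label)
    expect_equal(unweighted_unifrac(tab, tr), oracle_unifrac(tab, tr),
                 tolerance = 1e-10)
  }
})

test_that("Bray-Curtis matches its definition and ignores zero columns", {
  m <- matrix(c(2, 2, 1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("x", "y")))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.25)                      # (1+1)/8
  disj <- matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(disj)["a", "b"], 1)
  expect_equal(bray_curtis(rbind(a = c(1, 2), b = c(1, 2)))["a", "b"], 0)
  expect_equal(bray_curtis(cbind(m, z = c(0, 0))), d)  # zero-column invariant
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 2))), "all-zero")
  # independent implementation
  set.seed(5)
  mm <- matrix(runif(24, 0, 10), 4, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(unname(bray_curtis(mm)),
               unname(as.matrix(vegan::vegdist(mm, "bray"))),
               tolerance = 1e-12)
})

test_that("Jaccard similarity handles identity, disjoint, and overlap", {
  expect_equal(jaccard_similarity(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard_similarity(c("A"), c("B")), 0)
  expect_equal(jaccard_similarity(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_message(out <- jaccard_similarity(character(0), character(0)),
                 "empty")
  expect_equal(out, 1)
})
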