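# Domain types and delimited-text round trips.

test_that("feature tables round-trip through TSV and preserve order", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  tab <- feature_table(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  expect_equal(read_feature_table(path), tab)

  set.seed(42)
  for (i in 1:5) {
    n <- sample(2:6, 1); k <- sample(2:8, 1)
    tab <- feature_table(matrix(rpois(n * k, 5) + 1, n, k,
                                dimnames = list(paste0("s", 1:n),
                                                paste0("f", 1:k))))
    write_feature_table(tab, path)
    expect_equal(read_feature_table(path), tab)
  }
})

test_that("invalid feature tables are rejected with the offending label", {
  m <- matrix(c(1, -1, 3, 4), 2, 2,
              dimnames = list(c("s1", "s2"), c("f1", "f2")))
  expect_error(feature_table(m), "s2.*f1|f1.*s2")
  m2 <- matrix(1, 2, 2, dimnames = list(c("a", "a"), c("f1", "f2")))
  expect_error(feature_table(m2), "duplicate sample id: a")
  m3 <- matrix(c(0, 0, 1, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("f1", "f2")))
  expect_error(feature_table(m3), "no positive counts: s1")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#SampleID\tf1\tf2", "s1\t1\t2", "s2\t-1\t4"), path)
  expect_error(read_feature_table(path), "s2")
})

test_that("newick trees load with mandatory branch lengths", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,(C:1,D:1):1):0;", path)
  tr <- read_tree(path)
  expect_equal(sort(tr$tip.label), c("A", "B", "C", "D"))
  expect_equal(sum(tr$edge.length), 6)   # non-root branch length total

  writeLines("(A:1);", path)
  expect_equal(length(read_tree(path)$tip.label), 1L)

  writeLines("((A:1,B));", path)
  expect_error(read_tree(path), "branch length")
})

test_that("metadata derives treatment units and enforces the HU donor rule", {
  df <- data.frame(sample_id = c("m1", "m9"), group = c("HU", "LCM"),
                   donor_id = c("D3", ""), cohort_id = c("c1", "c2"))
  md <- sample_metadata(df)
  expect_equal(md$treatment_unit, c("D3", "c2"))
  df$group <- c("HU", "HU"); df$donor_id <- c("D3", "")
  expect_error(sample_metadata(df), "m9")

  path <- withr::local_tempfile(fileext = ".tsv")
  md <- sample_metadata(data.frame(sample_id = c("m1", "m9"),
                                   group = c("HU", "LCM"),
                                   donor_id = c("D3", ""),
                                   cohort_id = c("c1", "c2")))
  write_metadata(md, path)
  expect_equal(read_metadata(path)$treatment_unit, c("D3", "c2"))
})

test_that("compound tables keep fraction labels through IO and subsetting", {
  areas <- matrix(c(0, 2.5, 3, 4), 2, 2,
                  dimnames = list(c("s1", "s2"), c("c1", "c2")))
  tab <- compound_table(areas, c(c1 = "lipid", c2 = "aqueous"))
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_compound_table(tab, p1, p2)
  back <- read_compound_table(p1, p2)
  expect_equal(unclass(back), unclass(tab), ignore_attr = TRUE)
  expect_equal(compound_fractions(back), compound_fractions(tab))
  sub <- subset_compounds(tab, "c2")
  expect_equal(compound_fractions(sub), c(c2 = "aqueous"))
  expect_error(compound_table(areas, c(c1 = "lipid", c2 = "oil")),
               "unknown fraction")
})

test_that("distance matrices validate their contract", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_silent(distance_matrix(d))
  d2 <- d; d2[1, 2] <- 2
  expect_error(distance_matrix(d2), "symmetric")
  d3 <- d; diag(d3) <- 0.5
  expect_error(distance_matrix(d3), "diagonal")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(distance_matrix(d), path)
  expect_equal(read_distance_matrix(path), distance_matrix(d))
})
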