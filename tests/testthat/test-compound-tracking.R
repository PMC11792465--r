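# Targeted-extraction logic: ppm matching, consensus definition, detection
# filters, baseline subtraction and accounting.

test_that("mass_match applies the ppm window symmetrically and inclusively", {
  expect_true(mass_match(500.0000, 500.0049, 10))    # 9.8 ppm
  expect_false(mass_match(500.0000, 500.0060, 10))   # 12 ppm
  expect_true(mass_match(500.0000, 500.0000, 10))
  expect_error(mass_match(-1, 500, 10), "positive")
  expect_error(mass_match(500, 0, 10), "positive")
})

test_that("extract compounds require 100% replicate presence and no blanks", {
  ex <- rbind(
    do.call(rbind, lapply(1:4, function(i)
      rec("kept", paste0("E", i), 400.0000, 5.0))),
    do.call(rbind, lapply(1:3, function(i)
      rec("partial", paste0("E", i), 500.0000, 4.0))),
    do.call(rbind, lapply(1:4, function(i)
      rec("blanky", paste0("E", i), 600.0000, 3.0))),
    do.call(rbind, lapply(1:4, function(i)
      rec("late", paste0("E", i), 700.0000, 11.0))))
  blanks <- rec("b1", "BLK", 600.0010, 3.05)
  out <- define_extract_compounds(ex, blanks)
  expect_equal(out$compound_id, "kept")
  # consensus mass/rt are arithmetic means over replicates
  ex2 <- do.call(rbind, lapply(1:2, function(i)
    rec("k", paste0("E", i), 400 + (i - 1) * 4e-4, 5.0 + (i - 1) * 0.1)))
  out2 <- define_extract_compounds(ex2, NULL)
  expect_equal(out2$mass, 400.0002)
  expect_equal(out2$rt, 5.05)
  expect_error(define_extract_compounds(ex[0, ], NULL), "extract")
})

test_that("plasma matching honors rt outlier and isotope-ratio qualifiers", {
  ext <- data.frame(compound_id = "c1", annotation = NA, mass = 400.0000,
                    rt = 3.00, fraction = "aqueous", area_m1 = 1e6,
                    m2_over_m1 = 0.2, adduct_mass = NA)
  p <- match_params()
  ok <- rec("f1", "P1", 400.0020, 3.10, area_m1 = 5e5, area_m2 = 5e5 * 0.21)
  tab <- match_to_plasma(ext, ok, p)
  expect_equal(unname(unclass(tab)["P1", "c1"]), 5e5)

  outlier <- rec("f1", "P1", 400.0020, 3.35, area_m1 = 5e5)
  expect_equal(unname(unclass(match_to_plasma(ext, outlier, p))["P1", "c1"]),
               0)

  bad_iso <- rec("f1", "P1", 400.0020, 3.10, area_m1 = 5e5,
                 area_m2 = 5e5 * 0.26)           # 30% off the 0.2 ratio
  expect_equal(unname(unclass(match_to_plasma(ext, bad_iso, p))["P1", "c1"]),
               0)
  no_m2 <- rec("f1", "P1", 400.0020, 3.10, area_m1 = 5e5)  # M1-only: allowed
  expect_equal(unname(unclass(match_to_plasma(ext, no_m2, p))["P1", "c1"]),
               5e5)
})

test_that("ties resolve to the nearest mass, then nearest rt", {
  ext <- data.frame(compound_id = "c1", annotation = NA, mass = 400.0000,
                    rt = 3.00, fraction = "aqueous", area_m1 = 1e6,
                    m2_over_m1 = NA, adduct_mass = NA)
  two <- rbind(rec("near", "P1", 400.0004, 3.15, area_m1 = 111),
               rec("far", "P1", 400.0020, 3.01, area_m1 = 222))
  expect_equal(unname(unclass(match_to_plasma(ext, two,
                                              match_params()))["P1", "c1"]),
               111)
})

test_that("detection filters count threshold hits per fraction inclusively", {
  mk_tab <- function(v, fraction) {
    areas <- matrix(c(v, rep(0, 6 - length(v))), ncol = 1,
                    dimnames = list(paste0("P", 1:6), "c1"))
    compound_table(areas, c(c1 = fraction))
  }
  p <- match_params()
  expect_equal(ncol(apply_detection_filters(
    mk_tab(c(25000, 21000, 20000), "aqueous"), p)), 1L)
  expect_equal(ncol(apply_detection_filters(
    mk_tab(c(25000, 21000, 19999), "aqueous"), p)), 0L)
  expect_equal(ncol(apply_detection_filters(
    mk_tab(c(55000, 55000, 55000), "lipid"), p)), 1L)
  expect_equal(ncol(apply_detection_filters(
    mk_tab(c(55000, 55000, 54999), "lipid"), p)), 0L)
})

test_that("baseline subtraction preserves the conservation identity", {
  ext <- data.frame(compound_id = c("c1", "c2"), annotation = NA,
                    mass = c(400, 500), rt = c(3, 4),
                    fraction = c("lipid", "aqueous"), area_m1 = 1e6,
                    m2_over_m1 = NA, adduct_mass = NA)
  areas <- matrix(6e4, 3, 2, dimnames = list(paste0("P", 1:3),
                                             c("c1", "c2")))
  tracked <- compound_table(areas, c(c1 = "lipid", c2 = "aqueous"))
  attr(tracked, "reference") <- ext

  base <- rec("b", "B1", 400.001, 3.05, fraction = "lipid")
  rep <- remove_baseline(tracked, base)
  expect_equal(rep$n_detected[["total"]], 2)
  expect_equal(rep$n_baseline_removed[["lipid"]], 1)
  expect_equal(rep$n_retained[["total"]], 1)
  expect_equal(colnames(rep$retained), "c2")
  expect_equal(rep$n_retained[["total"]],
               rep$n_detected[["total"]] - rep$n_baseline_removed[["total"]])

  rep0 <- remove_baseline(tracked, NULL)
  expect_equal(rep0$n_baseline_removed[["total"]], 0)
  expect_equal(colnames(rep0$retained), c("c1", "c2"))
})

test_that("widening the windows never loses matches (monotonicity)", {
  set.seed(7)
  ext <- data.frame(compound_id = paste0("c", 1:8), annotation = NA,
                    mass = runif(8, 200, 800), rt = runif(8, 1, 9),
                    fraction = "aqueous", area_m1 = 1e6, m2_over_m1 = NA,
                    adduct_mass = NA)
  plasma <- do.call(rbind, lapply(1:4, function(s) {
    rec(paste0("f", 1:8), paste0("P", s),
        ext$mass * (1 + runif(8, -12, 12) * 1e-6),
        ext$rt + runif(8, -0.35, 0.35), area_m1 = runif(8, 1e4, 1e6))
  }))
  count_matches <- function(ppm, rtw) {
    p <- match_params(ppm_window = ppm, rt_window = rtw,
                      rt_outlier = max(rtw, 0.3))
    sum(unclass(match_to_plasma(ext, plasma, p)) > 0)
  }
  n_narrow <- count_matches(5, 0.1)
  n_default <- count_matches(10, 0.2)
  n_wide <- count_matches(20, 0.4)
  expect_true(n_narrow <= n_default)
  expect_true(n_default <= n_wide)
})

test_that("tracking recovers exactly the planted compounds on synthetic data", {
  world <- simulate_world(small_sim(seed = 9))
  res <- run_tracking(world)
  gt <- world$ground_truth
  expect_true(all(gt$true_ids %in% colnames(res$detected)))       # recall 1
  expect_equal(sum(gt$decoy_ids %in% colnames(res$detected)), 0L) # no decoys
  expect_equal(sum(gt$contaminant_ids %in% res$extract$compound_id), 0L)
  expect_setequal(colnames(res$report$retained),
                  setdiff(gt$true_ids, gt$baseline_ids))
  expect_equal(res$report$n_baseline_removed[["total"]],
               length(gt$baseline_ids))
})
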