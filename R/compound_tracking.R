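# Targeted extraction of extract-derived compounds from plasma feature lists:
# consensus extract compound definition, ppm / retention-time matching with
# isotope-ratio qualification, detection filters, and baseline subtraction.

#' Matching and filtering parameters for compound tracking
#'
#' Defaults follow the targeted data-extraction settings used throughout the
#' workflow: a 10 ppm mass window, a +/-0.2 min retention-time extraction
#' window with a 0.3 min outlier cut, a 20% qualifier relative uncertainty on
#' the M2/M1 isotope ratio, detection in at least three plasma samples with
#' area >= 20,000 counts (aqueous) or >= 55,000 counts (lipid), extract
#' features restricted to < 10 min, and plasma features to < 10.4 min (lipid)
#' or < 13 min (aqueous).
#'
#' @param ppm_window mass tolerance, ppm of the query mass.
#' @param rt_window retention-time match window, minutes.
#' @param rt_outlier retention-time outlier cut, minutes.
#' @param qualifier_rel_uncertainty maximum relative deviation of the observed
#'   M2/M1 ratio from the extract's ratio.
#' @param min_samples minimum number of plasma samples a compound must be
#'   detected in.
#' @param min_area_aqueous,min_area_lipid per-fraction minimum peak area
#'   (counts) for a sample to count as a detection.
#' @param extract_rt_max retention-time ceiling for extract compounds, minutes.
#' @param plasma_rt_max_lipid,plasma_rt_max_aqueous retention-time ceilings
#'   applied to plasma features on loading, minutes.
#' @return a validated parameter list of class `match_params`.
#' @export
match_params <- function(ppm_window = 10, rt_window = 0.2, rt_outlier = 0.3,
                         qualifier_rel_uncertainty = 0.20, min_samples = 3L,
                         min_area_aqueous = 20000, min_area_lipid = 55000,
                         extract_rt_max = 10, plasma_rt_max_lipid = 10.4,
                         plasma_rt_max_aqueous = 13) {
  p <- list(ppm_window = ppm_window, rt_window = rt_window,
            rt_outlier = rt_outlier,
            qualifier_rel_uncertainty = qualifier_rel_uncertainty,
            min_samples = as.integer(min_samples),
            min_area_aqueous = min_area_aqueous,
            min_area_lipid = min_area_lipid,
            extract_rt_max = extract_rt_max,
            plasma_rt_max_lipid = plasma_rt_max_lipid,
            plasma_rt_max_aqueous = plasma_rt_max_aqueous)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L || x <= 0,
                 logical(1L)))) {
    stop("all matching parameters must be single positive numbers",
         call. = FALSE)
  }
  if (p$ppm_window > 100) stop("ppm_window must be <= 100", call. = FALSE)
  structure(p, class = "match_params")
}

#' Test whether two neutral masses agree within a ppm window
#'
#' @param query_mass,candidate_mass neutral masses in Da (> 0).
#' @param ppm_window tolerance in parts per million of the query mass.
#' @return logical: `|candidate - query| / query * 1e6 <= ppm_window`.
#'   Vectorized over `candidate_mass`.
#' @examples
#' mass_match(500.0000, 500.0049, 10)  # 9.8 ppm -> TRUE
#' mass_match(500.0000, 500.0060, 10)  # 12 ppm  -> FALSE
#' @export
mass_match <- function(query_mass, candidate_mass, ppm_window) {
  if (any(!is.finite(query_mass) | query_mass <= 0) ||
      any(!is.finite(candidate_mass) | candidate_mass <= 0)) {
    stop("masses must be positive", call. = FALSE)
  }
  abs(candidate_mass - query_mass) / query_mass * 1e6 <= ppm_window
}

# Per-record M2/M1 ratio; NA when M2 absent or M1 zero.
m2_ratio <- function(records) {
  ifelse(!is.na(records$area_m2) & records$area_m1 > 0,
         records$area_m2 / records$area_m1, NA_real_)
}

#' Define the consensus extract compound list
#'
#' A compound enters the tracked list only if a feature matching it (mass
#' within the ppm window and retention time within the rt window) is present
#' in **every** extract replicate, elutes before `extract_rt_max`, and is
#' absent from every blank.  The representative mass and retention time are
#' arithmetic means over the extract replicates; the representative M2/M1
#' ratio (used later for qualification) is the mean over replicates where
#' both peaks were observed.
#'
#' @param extract_records long-format records from the extract replicates
#'   (see [compound_records()]); `sample_id` distinguishes replicates.
#' @param blank_records records from preparatory blanks (may have zero rows).
#' @param params a [match_params()] list.
#' @return data frame of consensus records with columns `compound_id`,
#'   `annotation`, `mass`, `rt`, `fraction`, `area_m1`, `m2_over_m1`,
#'   `adduct_mass`.
#' @export
define_extract_compounds <- function(extract_records, blank_records = NULL,
                                     params = match_params()) {
  extract_records <- compound_records(extract_records)
  if (nrow(extract_records) == 0L) stop("no extract records", call. = FALSE)
  samples <- unique(extract_records$sample_id)
  if (length(samples) == 0L) stop("empty extract sample set", call. = FALSE)
  if (!is.null(blank_records) && nrow(blank_records) > 0L) {
    blank_records <- compound_records(blank_records)
  } else {
    blank_records <- compound_records(extract_records[0L, ])
  }

  by_sample <- split(extract_records, extract_records$sample_id)
  seed_set <- by_sample[[samples[1L]]]
  out <- vector("list", nrow(seed_set))
  for (i in seq_len(nrow(seed_set))) {
    rec <- seed_set[i, ]
    hits <- list(rec)
    ok <- TRUE
    for (s in samples[-1L]) {
      cand <- by_sample[[s]]
      sel <- cand$fraction == rec$fraction &
        mass_match(rec$mass, cand$mass, params$ppm_window) &
        abs(cand$rt - rec$rt) <= params$rt_window
      if (!any(sel)) { ok <- FALSE; break }
      cand <- cand[sel, , drop = FALSE]
      dppm <- abs(cand$mass - rec$mass) / rec$mass * 1e6
      cand <- cand[order(dppm, abs(cand$rt - rec$rt), cand$compound_id), ]
      hits[[length(hits) + 1L]] <- cand[1L, ]
    }
    if (!ok) next
    hits <- do.call(rbind, hits)
    cons_mass <- mean(hits$mass)
    cons_rt <- mean(hits$rt)
    if (cons_rt >= params$extract_rt_max) next
    if (nrow(blank_records) > 0L) {
      in_blank <- blank_records$fraction == rec$fraction &
        mass_match(cons_mass, blank_records$mass, params$ppm_window) &
        abs(blank_records$rt - cons_rt) <= params$rt_window
      if (any(in_blank)) next
    }
    ratios <- m2_ratio(hits)
    out[[i]] <- data.frame(
      compound_id = rec$compound_id,
      annotation = rec$annotation,
      mass = cons_mass, rt = cons_rt, fraction = rec$fraction,
      area_m1 = mean(hits$area_m1),
      m2_over_m1 = if (all(is.na(ratios))) NA_real_ else
        mean(ratios, na.rm = TRUE),
      adduct_mass = rec$adduct_mass,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out)) out <- data.frame(compound_id = character(),
                                      annotation = character(),
                                      mass = numeric(), rt = numeric(),
                                      fraction = character(),
                                      area_m1 = numeric(),
                                      m2_over_m1 = numeric(),
                                      adduct_mass = numeric())
  rownames(out) <- NULL
  out
}

# Drop plasma features eluting past the per-fraction ceiling.
apply_plasma_rt_ceiling <- function(records, params) {
  ceil <- ifelse(records$fraction == "lipid", params$plasma_rt_max_lipid,
                 params$plasma_rt_max_aqueous)
  records[records$rt < ceil, , drop = FALSE]
}

#' Match the extract compound list into per-sample plasma feature lists
#'
#' For each extract compound and each plasma sample the best candidate
#' feature (same fraction, mass within the ppm window, retention time within
#' the rt window and not beyond the outlier cut from the extract consensus)
#' is quantified by its M1 area.  Candidates carrying an M2 peak must agree
#' with the extract's M2/M1 ratio within the qualifier relative uncertainty;
#' a candidate with no M2 peak is not disqualified.  When both records carry
#' a secondary adduct mass it must agree within the ppm window (qualifier
#' only, never quantified).  Ties break by smallest ppm deviation, then
#' smallest rt deviation, then compound id.  Unmatched cells get area 0.
#'
#' @param extract consensus list from [define_extract_compounds()].
#' @param plasma_records long-format plasma records across samples.
#' @param params a [match_params()] list.
#' @return a [compound_table()] (samples x extract compounds) carrying the
#'   consensus list as attribute `reference`.
#' @export
match_to_plasma <- function(extract, plasma_records, params = match_params()) {
  if (nrow(extract) == 0L) stop("empty extract compound list", call. = FALSE)
  plasma_records <- compound_records(plasma_records)
  plasma_records <- apply_plasma_rt_ceiling(plasma_records, params)
  samples <- unique(plasma_records$sample_id)
  areas <- matrix(0, length(samples), nrow(extract),
                  dimnames = list(samples, extract$compound_id))
  by_sample <- split(plasma_records, plasma_records$sample_id)
  for (s in samples) {
    feats <- by_sample[[s]]
    for (j in seq_len(nrow(extract))) {
      ex <- extract[j, ]
      drt <- abs(feats$rt - ex$rt)
      sel <- feats$fraction == ex$fraction &
        mass_match(ex$mass, feats$mass, params$ppm_window) &
        drt <= params$rt_window & drt <= params$rt_outlier
      if (!any(sel)) next
      cand <- feats[sel, , drop = FALSE]
      # isotope-ratio qualification against the extract's observed ratio
      if (!is.na(ex$m2_over_m1)) {
        obs <- m2_ratio(cand)
        pass <- is.na(obs) |
          abs(obs - ex$m2_over_m1) / ex$m2_over_m1 <=
            params$qualifier_rel_uncertainty
        cand <- cand[pass, , drop = FALSE]
      }
      if (!is.na(ex$adduct_mass) && nrow(cand) > 0L) {
        pass <- is.na(cand$adduct_mass) |
          mass_match(ex$adduct_mass, pmax(cand$adduct_mass, 1e-12),
                     params$ppm_window)
        cand <- cand[pass, , drop = FALSE]
      }
      if (nrow(cand) == 0L) next
      dppm <- abs(cand$mass - ex$mass) / ex$mass * 1e6
      cand <- cand[order(dppm, abs(cand$rt - ex$rt), cand$compound_id), ]
      areas[s, j] <- cand$area_m1[1L]
    }
  }
  out <- compound_table(areas, setNames(extract$fraction, extract$compound_id))
  attr(out, "reference") <- extract
  out
}

#' Apply the per-fraction detection filters
#'
#' Retains compounds detected in at least `min_samples` plasma samples with
#' an area at or above the fraction's threshold (>= 20,000 counts aqueous,
#' >= 55,000 counts lipid by default; boundaries inclusive).  Sub-threshold
#' areas of surviving compounds are preserved as-is.
#'
#' @param matched a [compound_table()] from [match_to_plasma()].
#' @param params a [match_params()] list.
#' @return the filtered `compound_table`.
#' @export
apply_detection_filters <- function(matched, params = match_params()) {
  fr <- compound_fractions(matched)
  thr <- c(lipid = params$min_area_lipid, aqueous = params$min_area_aqueous)
  if (!all(fr %in% names(thr))) {
    stop("unknown fraction label: ",
         paste(setdiff(unique(fr), names(thr)), collapse = ", "),
         call. = FALSE)
  }
  n_hits <- colSums(unclass(matched) >= rep(thr[fr], each = nrow(matched)))
  keep <- names(fr)[n_hits >= params$min_samples]
  out <- subset_compounds(matched, keep)
  ref <- attr(matched, "reference")
  if (!is.null(ref)) {
    attr(out, "reference") <- ref[ref$compound_id %in% keep, , drop = FALSE]
  }
  out
}

#' Build a tracking report from per-fraction counts
#'
#' Encodes the conservation identity of compound accounting: per fraction and
#' in total, `n_retained = n_detected - n_baseline_removed`.
#'
#' @param n_detected named numeric, detected compounds per fraction
#'   (names `lipid`, `aqueous`).
#' @param n_baseline_removed named numeric, baseline-removed per fraction.
#' @param n_extract_compounds size of the consensus extract list (optional).
#' @param retained the retained [compound_table()] (optional).
#' @return a list of class `tracking_report` with per-fraction and total
#'   counts.
#' @export
tracking_report <- function(n_detected, n_baseline_removed,
                            n_extract_compounds = NA_integer_,
                            retained = NULL) {
  frs <- c("lipid", "aqueous")
  stopifnot(all(frs %in% names(n_detected)),
            all(frs %in% names(n_baseline_removed)))
  n_detected <- n_detected[frs]
  n_baseline_removed <- n_baseline_removed[frs]
  if (any(n_baseline_removed > n_detected)) {
    stop("cannot remove more compounds than were detected", call. = FALSE)
  }
  n_retained <- n_detected - n_baseline_removed
  rep <- list(n_extract_compounds = n_extract_compounds,
              n_detected = c(n_detected, total = sum(n_detected)),
              n_baseline_removed = c(n_baseline_removed,
                                     total = sum(n_baseline_removed)),
              n_retained = c(n_retained, total = sum(n_retained)),
              retained = retained)
  stopifnot(rep$n_retained[["total"]] ==
              rep$n_detected[["total"]] - rep$n_baseline_removed[["total"]])
  structure(rep, class = "tracking_report")
}

#' @export
print.tracking_report <- function(x, ...) {
  cat("compound tracking report\n")
  cat(sprintf("  extract compounds: %s\n", x$n_extract_compounds))
  for (f in c("lipid", "aqueous", "total")) {
    cat(sprintf("  %-7s detected %4d  baseline-removed %4d  retained %4d\n",
                f, x$n_detected[[f]], x$n_baseline_removed[[f]],
                x$n_retained[[f]]))
  }
  invisible(x)
}

#' Remove baseline compounds and account for them
#'
#' A tracked compound matched (same fraction, mass within the ppm window,
#' retention time within the rt window of the extract consensus) in **any**
#' plasma sample from animals never given the extract is a baseline compound
#' and is removed.
#'
#' @param tracked filtered [compound_table()] from [apply_detection_filters()]
#'   (must carry the consensus list as attribute `reference`, or pass it).
#' @param baseline_records long-format plasma records from unexposed animals;
#'   may have zero rows.
#' @param params a [match_params()] list.
#' @param reference consensus extract list; defaults to
#'   `attr(tracked, "reference")`.
#' @param n_extract size of the full consensus extract list, for the report
#'   (defaults to `nrow(reference)`, which may already be filtered).
#' @return a [tracking_report()] whose `retained` element is the surviving
#'   `compound_table`.
#' @export
remove_baseline <- function(tracked, baseline_records = NULL,
                            params = match_params(),
                            reference = attr(tracked, "reference"),
                            n_extract = nrow(reference)) {
  if (is.null(reference)) {
    stop("`tracked` carries no reference extract list; pass `reference`",
         call. = FALSE)
  }
  fr <- compound_fractions(tracked)
  ref <- reference[match(colnames(tracked), reference$compound_id), ]
  in_baseline <- rep(FALSE, ncol(tracked))
  if (!is.null(baseline_records) && nrow(baseline_records) > 0L) {
    baseline_records <- compound_records(baseline_records)
    baseline_records <- apply_plasma_rt_ceiling(baseline_records, params)
    for (j in seq_len(ncol(tracked))) {
      sel <- baseline_records$fraction == ref$fraction[j] &
        mass_match(ref$mass[j], baseline_records$mass, params$ppm_window) &
        abs(baseline_records$rt - ref$rt[j]) <= params$rt_window
      in_baseline[j] <- any(sel)
    }
  }
  count_by_fraction <- function(mask) {
    c(lipid = sum(mask & fr == "lipid"), aqueous = sum(mask & fr == "aqueous"))
  }
  retained <- subset_compounds(tracked, colnames(tracked)[!in_baseline])
  attr(retained, "reference") <-
    ref[!in_baseline, , drop = FALSE]
  tracking_report(
    n_detected = count_by_fraction(rep(TRUE, ncol(tracked))),
    n_baseline_removed = count_by_fraction(in_baseline),
    n_extract_compounds = n_extract,
    retained = retained)
}
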