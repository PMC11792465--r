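#' foodtrace: from dietary extract to plasma to microbiome
#'
#' Tools for tracking diet-derived compounds from an extract into host plasma
#' via targeted LC-MS feature matching, and for relating their plasma
#' abundances to gut microbiome composition and diversity.  See the package
#' vignette `vignette("foodtrace-methods")` for the statistical models and
#' the design of the synthetic study worlds used for validation.
#'
#' @importFrom stats aggregate anova coef dffits lm model.matrix optimize
#'   p.adjust pnorm pt qt quantile resid rexp rgamma rlnorm rmultinom rnorm
#'   runif sd setNames var
#' @importFrom utils read.delim write.table read.csv write.csv
#' @keywords internal
"_PACKAGE"

# ---- internal seed handling -------------------------------------------------

# Evaluate `expr` under a locally-set RNG seed, restoring the caller's RNG
# state afterwards.  Keeps every stochastic routine deterministic per seed
# without clobbering the session stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# ---- FeatureTable -----------------------------------------------------------

#' Construct and validate a microbiome feature table
#'
#' A feature table is a samples x features matrix of non-negative integer
#' counts (rows are samples, columns are features such as ASVs), the basic
#' microbiome observation unit.
#'
#' @param counts numeric matrix, samples in rows, features in columns, with
#'   `rownames` (sample ids) and `colnames` (feature ids).
#' @return the validated integer-mode matrix, invisibly classed as written.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("f1", "f2")))
#' feature_table(m)
#' @export
feature_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("feature table must carry sample (row) and feature (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample id: ",
         rownames(counts)[duplicated(rownames(counts))][1L], call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate feature id: ",
         colnames(counts)[duplicated(colnames(counts))][1L], call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("invalid count at sample '%s', feature '%s': %s",
                 rownames(counts)[bad[1L, 1L]], colnames(counts)[bad[1L, 2L]],
                 format(counts[bad[1L, , drop = FALSE]])), call. = FALSE)
  }
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    stop("sample(s) with no positive counts: ",
         paste(rownames(counts)[empty], collapse = ", "), call. = FALSE)
  }
  storage.mode(counts) <- "double"
  counts
}

# ---- CompoundTable ----------------------------------------------------------

#' Construct a compound table
#'
#' Samples x compounds matrix of non-negative peak areas, plus a per-compound
#' LC-MS fraction label (`"lipid"` or `"aqueous"`).  The fraction vector is
#' stored as an attribute and travels with the table through subsetting by
#' [subset_compounds()].
#'
#' @param areas numeric matrix (samples x compounds) with dimnames.
#' @param fraction character vector, one of `"lipid"`/`"aqueous"` per
#'   compound; recycled names are matched against `colnames(areas)`.
#' @return the matrix with a `fraction` attribute and class `compound_table`.
#' @export
compound_table <- function(areas, fraction) {
  areas <- as.matrix(areas)
  if (ncol(areas) == 0L) {
    dimnames(areas) <- list(rownames(areas), character(0))
  }
  if (is.null(rownames(areas)) ||
      (ncol(areas) > 0L && is.null(colnames(areas)))) {
    stop("compound table must carry sample and compound names", call. = FALSE)
  }
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("compound areas must be finite and >= 0", call. = FALSE)
  }
  if (is.null(names(fraction))) names(fraction) <- colnames(areas)
  fraction <- fraction[colnames(areas)]
  if (anyNA(fraction)) {
    stop("fraction label missing for compound(s): ",
         paste(colnames(areas)[is.na(fraction)], collapse = ", "),
         call. = FALSE)
  }
  if (!all(fraction %in% c("lipid", "aqueous"))) {
    stop("unknown fraction label: ",
         paste(unique(fraction[!fraction %in% c("lipid", "aqueous")]),
               collapse = ", "), call. = FALSE)
  }
  structure(areas, fraction = fraction, class = c("compound_table", "matrix"))
}

#' Per-compound fraction labels of a compound table
#' @param x a `compound_table`.
#' @return named character vector.
#' @export
compound_fractions <- function(x) {
  fr <- attr(x, "fraction")
  if (is.null(fr)) stop("object has no fraction labels", call. = FALSE)
  fr
}

#' Subset a compound table by compound, keeping fraction labels aligned
#' @param x a `compound_table`.
#' @param compounds compound ids or column index.
#' @export
subset_compounds <- function(x, compounds) {
  fr <- compound_fractions(x)
  m <- unclass(x)[, compounds, drop = FALSE]
  compound_table(m, fr[colnames(m)])
}

#' @export
print.compound_table <- function(x, ...) {
  fr <- attr(x, "fraction")
  cat(sprintf("compound_table: %d samples x %d compounds (%d lipid, %d aqueous)\n",
              nrow(x), ncol(x), sum(fr == "lipid"), sum(fr == "aqueous")))
  invisible(x)
}

# ---- CompoundRecord sets ----------------------------------------------------

record_cols <- c("compound_id", "annotation", "mass", "rt", "fraction",
                 "sample_id", "area_m1", "area_m2", "adduct_mass")

#' Construct a set of LC-MS compound records
#'
#' Long-format feature list as exported per sample from LC-MS software: one
#' row per (sample, feature) with neutral mass (Da), retention time (min),
#' fraction, monoisotopic (M1) and first-isotope (M2) peak areas and an
#' optional secondary adduct mass used only for qualification.
#'
#' @param df data frame with columns `compound_id`, `annotation`, `mass`,
#'   `rt`, `fraction`, `sample_id`, `area_m1`, `area_m2`, `adduct_mass`
#'   (the last three may hold `NA`).
#' @return validated data frame.
#' @export
compound_records <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(setdiff(record_cols, c("annotation", "area_m2",
                                                 "adduct_mass")), names(df))
  if (length(missing_cols)) {
    stop("compound records missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (opt in c("annotation", "area_m2", "adduct_mass")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  if (any(!is.finite(df$mass) | df$mass <= 0)) {
    stop("neutral mass must be > 0", call. = FALSE)
  }
  if (any(!is.finite(df$rt) | df$rt < 0)) stop("rt must be >= 0", call. = FALSE)
  na_area <- is.na(df$area_m1)
  if (any(na_area)) {
    warning(sum(na_area), " missing M1 area(s) read as 0 (non-detection)")
    df$area_m1[na_area] <- 0
  }
  if (any(df$area_m1 < 0)) stop("area_m1 must be >= 0", call. = FALSE)
  df[, record_cols]
}

# ---- SampleMetadata ---------------------------------------------------------

#' Construct sample metadata with derived treatment units
#'
#' Each sample belongs to group `"HU"` (humanized, colonized from a human
#' donor) or `"LCM"` (low-complexity-microbiome control).  The treatment unit
#' -- the grouping used to avoid pseudoreplication -- is the donor for HU
#' samples and the experimental cohort for LCM samples.
#'
#' @param df data frame with columns `sample_id`, `group`, `donor_id`,
#'   `cohort_id` (empty string or `NA` allowed for donor of LCM samples).
#' @return data frame with an added `treatment_unit` column.
#' @export
sample_metadata <- function(df) {
  df <- as.data.frame(df)
  need <- c("sample_id", "group", "donor_id", "cohort_id")
  if (!all(need %in% names(df))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L],
         call. = FALSE)
  }
  if (!all(df$group %in% c("HU", "LCM"))) {
    stop("group must be 'HU' or 'LCM'", call. = FALSE)
  }
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
  hu_bad <- df$group == "HU" & blank(df$donor_id)
  if (any(hu_bad)) {
    stop("HU sample(s) without donor_id: ",
         paste(df$sample_id[hu_bad], collapse = ", "), call. = FALSE)
  }
  lcm_bad <- df$group == "LCM" & blank(df$cohort_id)
  if (any(lcm_bad)) {
    stop("LCM sample(s) without cohort_id: ",
         paste(df$sample_id[lcm_bad], collapse = ", "), call. = FALSE)
  }
  df$treatment_unit <- ifelse(df$group == "HU", as.character(df$donor_id),
                              as.character(df$cohort_id))
  stopifnot(all(nzchar(df$treatment_unit)))
  df
}

# ---- DistanceMatrix ---------------------------------------------------------

#' Validate a labeled distance matrix
#'
#' Checks the contract every distance-consuming stage relies on: square,
#' labeled, symmetric to 1e-10, zero diagonal, non-negative.
#'
#' @param d numeric matrix with identical row and column labels.
#' @return the matrix, symmetrized exactly (averaging the numerically
#'   symmetric halves).
#' @export
distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("distance matrix must be square", call. = FALSE)
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop("distance matrix must have identical row and column labels",
         call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-10) {
    stop("distance matrix not symmetric within 1e-10", call. = FALSE)
  }
  if (max(abs(diag(d))) > 1e-12) {
    stop("distance matrix diagonal must be zero", call. = FALSE)
  }
  if (any(d < 0)) stop("distances must be >= 0", call. = FALSE)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

# ---- Tree -------------------------------------------------------------------

#' Validate a rooted phylogenetic tree
#'
#' @param tree an [ape::phylo] object.
#' @return the tree, after checking rootedness, unique tip labels and
#'   finite non-negative branch lengths on every edge.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object",
                                     call. = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L], call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (length(tree$edge.length) != nrow(tree$edge) ||
      any(!is.finite(tree$edge.length))) {
    stop("every branch must carry a finite length (no silent defaults)",
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  tree
}
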