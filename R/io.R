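# Reading and writing the delimited-text formats every stage touches.
# TSV dialect: UTF-8, tab-separated, header row, first header cell "#SampleID".

#' Read a feature table from TSV
#'
#' Expects a header row of feature ids whose first cell is `#SampleID`, and
#' a first column of sample ids.  Use `transpose = TRUE` for files written
#' features-in-rows.
#'
#' @param path file path.
#' @param transpose logical; if `TRUE` the file stores features in rows.
#' @return validated feature table (see [feature_table()]).
#' @export
read_feature_table <- function(path, transpose = FALSE) {
  df <- read.delim(path, check.names = FALSE, comment.char = "",
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))),
                 arr.ind = TRUE)
    storage.mode(m) <- "double"
    if (nrow(bad)) {
      stop(sprintf("non-numeric count at row '%s', column '%s'",
                   rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]),
           call. = FALSE)
    }
  }
  if (transpose) m <- t(m)
  feature_table(m)
}

#' Write a feature table as TSV
#' @param table feature table matrix.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame("#SampleID" = rownames(table), table,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a compound table (areas TSV plus fraction column file)
#'
#' The areas file follows the feature-table dialect; the companion fractions
#' file is a two-column TSV `compound_id`, `fraction`.
#'
#' @param path areas TSV.
#' @param fraction_path fractions TSV.
#' @return a [compound_table()].
#' @export
read_compound_table <- function(path, fraction_path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    warning(sum(is.na(m)), " missing area(s) read as 0 (non-detection)")
    m[is.na(m)] <- 0
  }
  fr <- read.delim(fraction_path, stringsAsFactors = FALSE)
  compound_table(m, setNames(fr$fraction, fr$compound_id))
}

#' Write a compound table (areas TSV plus fraction TSV)
#' @param table a `compound_table`.
#' @param path areas TSV path.
#' @param fraction_path fractions TSV path.
#' @export
write_compound_table <- function(table, path, fraction_path) {
  df <- data.frame("#SampleID" = rownames(table), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  fr <- compound_fractions(table)
  write.table(data.frame(compound_id = names(fr), fraction = unname(fr)),
              fraction_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id` (header may be `#SampleID`), `group`,
#' `donor_id`, `cohort_id`; the derived `treatment_unit` column is populated
#' on load (donor for HU, cohort for LCM).
#'
#' @param path TSV path.
#' @return metadata data frame (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  names(df)[names(df) == "#SampleID"] <- "sample_id"
  sample_metadata(df)
}

#' Write sample metadata as TSV
#' @param metadata metadata data frame.
#' @param path output path.
#' @export
write_metadata <- function(metadata, path) {
  out <- metadata[, c("sample_id", "group", "donor_id", "cohort_id")]
  names(out)[1] <- "#SampleID"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Every non-root branch must carry a length; a missing root edge length is
#' treated as 0.
#'
#' @param path newick file.
#' @return validated [ape::phylo] tree.
#' @export
read_tree <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("unparseable newick file: ", path, call. = FALSE)
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge) ||
      anyNA(tree$edge.length)) {
    stop("missing branch length in newick (lengths are mandatory off the root)",
         call. = FALSE)
  }
  validate_tree(tree)
}

#' Write a tree as newick
#' @param tree `phylo` object.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read LC-MS compound records from a vendor-style export CSV
#'
#' Long format: one row per (sample, feature) with columns `compound_id`,
#' `annotation`, `mass`, `rt`, `fraction`, `sample_id`, `area_m1`, `area_m2`,
#' `adduct_mass`.
#'
#' @param path CSV path.
#' @return validated records data frame (see [compound_records()]).
#' @export
read_compound_records <- function(path) {
  compound_records(read.csv(path, stringsAsFactors = FALSE))
}

#' Write LC-MS compound records as CSV
#' @param records records data frame.
#' @param path output path.
#' @export
write_compound_records <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a labeled square distance matrix as TSV
#' @param d distance matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame("#SampleID" = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix from TSV
#' @param path TSV path.
#' @export
read_distance_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  distance_matrix(m)
}
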