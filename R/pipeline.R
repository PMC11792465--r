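# End-to-end orchestration: simulate -> track -> diversity -> collapse ->
# ordinate/Procrustes -> screens -> balances -> report, with logging, seed
# control and auditable on-disk intermediates at every stage.

#' Assemble a pipeline run configuration
#'
#' Either supply paths to all inputs, or a [sim_config()] in `sim`, in which
#' case the world is generated, written under `out_dir/inputs/` and read
#' back so the run exercises the same file formats as a real study.
#'
#' @param out_dir output directory (created if needed).
#' @param feature_table,tree,metadata,extract,blanks,plasma,baseline input
#'   file paths (ignored when `sim` is given).
#' @param sim optional [sim_config()].
#' @param params a [match_params()] list.
#' @param rarefaction_depth reads per sample for the diversity stage.
#' @param n_perm permutations for PERMANOVA and the Procrustes test.
#' @param seed master seed for every stochastic stage.
#' @param n_top_balances how many composition-ranked compounds get a balance
#'   search (default 12).
#' @param screen_n_compounds,screen_n_taxa problem size of the mixed-model
#'   taxon screen: the most variable compounds x the most prevalent taxa.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, feature_table = NULL, tree = NULL,
                       metadata = NULL, extract = NULL, blanks = NULL,
                       plasma = NULL, baseline = NULL, sim = NULL,
                       params = match_params(), rarefaction_depth = 40625L,
                       n_perm = 999L, seed = 1L, n_top_balances = 12L,
                       screen_n_compounds = 8L, screen_n_taxa = 8L) {
  structure(as.list(environment()), class = "run_config")
}

log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  invisible(msg)
}

#' Run the full workflow
#'
#' Executes all stages in dependency order, writing every intermediate
#' artifact plus a `summary.json` with seven sections: `tracking`,
#' `diversity`, `centroids`, `procrustes`, `composition_screen`,
#' `diversity_screen`, `taxon_screen` (and `balances`).  Any stage error
#' aborts with the stage name.  Outputs are pure functions of (inputs,
#' config, seed); the summary records the input file hashes and the seed.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with every stage result and the summary.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  cat("", file = log_path)
  log_line(log_path, "pipeline start; seed = ", config$seed,
           "; ppm_window = ", config$params$ppm_window,
           "; rarefaction depth = ", config$rarefaction_depth,
           "; permutations = ", config$n_perm)

  if (!is.null(config$sim)) {
    log_line(log_path, "stage simulate: generating synthetic world")
    world <- simulate_world(config$sim)
    inp <- file.path(out, "inputs")
    dir.create(inp, showWarnings = FALSE)
    config$feature_table <- write_feature_table(
      world$table, file.path(inp, "feature_table.tsv"))
    config$tree <- write_tree(world$tree, file.path(inp, "tree.nwk"))
    config$metadata <- write_metadata(world$metadata,
                                      file.path(inp, "metadata.tsv"))
    for (nm in c("extract", "blanks", "plasma", "baseline")) {
      config[[nm]] <- write_compound_records(
        world$lcms[[nm]], file.path(inp, paste0(nm, ".csv")))
    }
    jsonlite::write_json(world$ground_truth,
                         file.path(inp, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  paths <- config[c("feature_table", "tree", "metadata", "extract",
                    "blanks", "plasma", "baseline")]
  missing <- names(paths)[!vapply(paths, function(p)
    !is.null(p) && file.exists(p), logical(1L))]
  if (length(missing)) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing,
                       vapply(paths[missing], function(p)
                         if (is.null(p)) "not set" else p, character(1L))),
               collapse = ", "), call. = FALSE)
  }
  hashes <- as.list(tools::md5sum(unlist(paths)))

  stage <- function(name, expr) {
    log_line(log_path, "stage ", name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  table <- stage("load", read_feature_table(config$feature_table))
  tree <- read_tree(config$tree)
  metadata <- read_metadata(config$metadata)

  report <- stage("track", {
    extract_list <- define_extract_compounds(
      read_compound_records(config$extract),
      read_compound_records(config$blanks), config$params)
    matched <- match_to_plasma(extract_list,
                               read_compound_records(config$plasma),
                               config$params)
    detected <- apply_detection_filters(matched, config$params)
    remove_baseline(detected, read_compound_records(config$baseline),
                    config$params, n_extract = nrow(extract_list))
  })
  retained <- report$retained
  write_compound_table(retained, file.path(out, "retained_compounds.tsv"),
                       file.path(out, "retained_fractions.tsv"))

  div <- stage("diversity", {
    rt <- rarefy(table, config$rarefaction_depth, seed = config$seed)
    list(rarefied = rt, pd = faith_pd(rt, tree),
         unifrac = unweighted_unifrac(rt, tree))
  })
  write_distance_matrix(div$unifrac, file.path(out, "unifrac.tsv"))
  write.table(data.frame(sample_id = names(div$pd), faith_pd = div$pd),
              file.path(out, "faith_pd.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  units <- setNames(metadata$treatment_unit, metadata$sample_id)
  cent <- stage("collapse", {
    list(dm = collapse_to_centroids(div$unifrac, units),
         compounds = collapse_abundances(retained, units),
         pd = collapse_abundances(div$pd, units))
  })
  write_distance_matrix(cent$dm, file.path(out, "unifrac_centroids.tsv"))

  proc <- stage("ordinate", {
    micro <- pcoa(cent$dm)
    res <- list()
    for (f in c("lipid", "aqueous")) {
      cols <- names(compound_fractions(retained))[
        compound_fractions(retained) == f]
      if (length(cols) < 2L) next
      met <- pcoa(bray_curtis(unclass(cent$compounds)[, cols, drop = FALSE]))
      pr <- procrustes_randomization_test(
        micro$coordinates, met$coordinates[rownames(micro$coordinates), ,
                                           drop = FALSE],
        n_perm = config$n_perm, seed = config$seed + 101L)
      res[[f]] <- list(m_squared = pr$m_squared, p_value = pr$p_value,
                       n_permutations = pr$n_permutations)
    }
    write.table(micro$coordinates, file.path(out, "pcoa_unifrac.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    res
  })

  comp_screen <- stage("screen-composition", {
    compound_composition_screen(cent$dm, cent$compounds,
                                n_perm = config$n_perm,
                                seed = config$seed + 202L)
  })
  write.table(comp_screen, file.path(out, "composition_screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  div_screen <- stage("screen-diversity", {
    diversity_screen(retained, div$pd, metadata)
  })
  write.table(div_screen, file.path(out, "diversity_screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  tax_screen <- stage("screen-taxa", {
    relab <- relative_abundance(div$rarefied)
    # prevalent taxa first (defined across >= 60% of samples), then the most
    # variable on the arcsinh-percent scale the models use
    prevalent <- colMeans(relab > 0) >= 0.6
    if (sum(prevalent) < config$screen_n_taxa) prevalent[] <- TRUE
    v <- apply(arcsinh_percent(relab), 2, var) * prevalent
    taxa_sel <- names(sort(v, decreasing = TRUE))[
      seq_len(min(config$screen_n_taxa, ncol(relab)))]
    cv <- apply(unclass(retained), 2, function(a) sd(a) / mean(a))
    comp_sel <- names(sort(cv, decreasing = TRUE))[
      seq_len(min(config$screen_n_compounds, ncol(retained)))]
    comp_sub <- subset_compounds(retained, comp_sel)
    list(all = taxon_screen(comp_sub, relab[, taxa_sel, drop = FALSE],
                            metadata, hu_only = FALSE),
         hu_only = taxon_screen(comp_sub, relab[, taxa_sel, drop = FALSE],
                                metadata, hu_only = TRUE))
  })
  write.table(tax_screen$all, file.path(out, "taxon_screen_all.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tax_screen$hu_only, file.path(out, "taxon_screen_hu.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  balances <- stage("balances", {
    ranked <- comp_screen[!comp_screen$excluded, ]
    ranked <- ranked[order(ranked$p_value, ranked$compound_id), ]
    top <- utils::head(ranked$compound_id, config$n_top_balances)
    relab_cent <- collapse_abundances(
      relative_abundance(div$rarefied), units)
    prev <- colMeans(relab_cent > 0)
    taxa_sel <- names(sort(prev, decreasing = TRUE))[
      seq_len(min(20L, ncol(relab_cent)))]
    lapply(setNames(top, top), function(cid) {
      b <- select_balance(relab_cent[, taxa_sel, drop = FALSE],
                          unclass(cent$compounds)[, cid],
                          seed = config$seed + 303L)
      list(numerator = b$numerator, denominator = b$denominator,
           coefficient = b$coefficient, r_squared = b$r_squared,
           cv_r_squared = b$cv_r_squared)
    })
  })

  summary <- list(
    seed = config$seed, input_md5 = hashes,
    tracking = list(n_extract_compounds = report$n_extract_compounds,
                    n_detected = as.list(report$n_detected),
                    n_baseline_removed = as.list(report$n_baseline_removed),
                    n_retained = as.list(report$n_retained)),
    diversity = list(
      faith_pd_mean_hu =
        mean(div$pd[metadata$sample_id[metadata$group == "HU"]]),
      faith_pd_mean_lcm =
        mean(div$pd[metadata$sample_id[metadata$group == "LCM"]]),
      rarefaction_depth = config$rarefaction_depth),
    centroids = list(n_samples = nrow(div$unifrac), n_units = nrow(cent$dm)),
    procrustes = proc,
    composition_screen = list(
      n_tested = sum(!comp_screen$excluded),
      n_raw_significant = sum(comp_screen$raw_significant),
      n_fdr_significant = sum(comp_screen$fdr_significant)),
    diversity_screen = list(
      n_tested = sum(!div_screen$excluded),
      n_excluded_dffits = sum(div_screen$excluded),
      n_fdr_significant = sum(div_screen$p_adj < 0.05, na.rm = TRUE)),
    taxon_screen = list(
      n_pairs_all = nrow(tax_screen$all),
      n_fdr_significant_all = sum(tax_screen$all$p_adj < 0.05, na.rm = TRUE),
      n_pairs_hu = nrow(tax_screen$hu_only),
      n_fdr_significant_hu = sum(tax_screen$hu_only$p_adj < 0.05,
                                 na.rm = TRUE)),
    balances = balances)
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(log_path, "pipeline done")
  invisible(list(summary = summary, report = report, diversity = div,
                 centroids = cent, procrustes = proc,
                 composition_screen = comp_screen,
                 diversity_screen = div_screen, taxon_screen = tax_screen,
                 balances = balances, metadata = metadata))
}
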