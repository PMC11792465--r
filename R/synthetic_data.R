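# Synthetic study worlds: a phylogeny, donor-structured mouse microbiomes
# (10 humanized donors x 2 replicate mice + 9 low-complexity controls in 3
# cohorts), plasma compound tables with planted taxon-, diversity- and
# balance-linked effects, and LC-MS feature lists with decoys, blanks and
# baseline compounds -- plus a machine-readable ground-truth ledger.

#' Simulation configuration
#'
#' Defaults emulate the study design: 10 donor microbiomes x 2 replicate
#' mice plus 9 low-complexity (LCM) mice across 3 cohorts; a low-complexity
#' community in which 6 ASVs carry >= 90% of reads; sequencing depths drawn
#' uniformly above the 40,625-read rarefaction depth so rarefaction never
#' excludes a sample.  Dirichlet concentrations were calibrated once so that
#' replicate mice sharing a donor sit at unweighted UniFrac ~ 0.25 while
#' different donors sit near 0.5.
#'
#' @param n_donors,replicates_per_donor,n_lcm,n_cohorts design sizes.
#' @param n_asv tips in the phylogeny / ASV pool.
#' @param donor_support_size ASVs present in a donor's base community.
#' @param n_core core ASVs shared by every community (hosts for planted
#'   effects).
#' @param donor_alpha Dirichlet concentration of a donor base composition.
#' @param mouse_tau concentration of the per-mouse Dirichlet resample of its
#'   donor base (smaller = more replicate-to-replicate turnover).
#' @param lcm_tau per-mouse concentration for LCM communities.
#' @param n_lcm_dominant,lcm_dominant_mass the low-complexity dominant ASV
#'   block and its base relative-abundance mass.
#' @param n_lcm_tail minor ASVs in the LCM tail (in addition to the core).
#' @param depth_min,depth_max sequencing depth range (uniform integer).
#' @param rarefaction_depth reads per sample after rarefaction.
#' @param n_compounds total plasma compounds.
#' @param n_taxon_linked,taxon_beta planted taxon-linked compounds and their
#'   slope (z-scale per standardized arcsinh-abundance unit).
#' @param n_diversity_linked,diversity_slope planted PD-linked compounds and
#'   their slope sign/magnitude on the standardized scale.
#' @param n_balance_linked,balance_coef planted balance-linked compounds.
#' @param n_baseline compounds also present in unexposed-animal plasma.
#' @param noise_sd Gaussian noise sd on the standardized signal scale.
#' @param n_extract_only extract compounds never reaching plasma.
#' @param n_decoys decoy extract compounds whose plasma features are
#'   displaced > 15 ppm or > 0.5 min.
#' @param n_blank_contaminants compounds present in blanks (removed from the
#'   extract list).
#' @param n_extract_reps,n_baseline_samples extract replicates and
#'   unexposed-animal plasma samples.
#' @param seed master RNG seed; stage seeds derive from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_donors = 10L, replicates_per_donor = 2L, n_lcm = 9L,
                       n_cohorts = 3L, n_asv = 120L, donor_support_size = 45L,
                       n_core = 12L, donor_alpha = 0.35, mouse_tau = 8,
                       lcm_tau = 300, n_lcm_dominant = 6L,
                       lcm_dominant_mass = 0.99, n_lcm_tail = 10L,
                       depth_min = 40625L, depth_max = 80000L,
                       rarefaction_depth = 40625L, n_compounds = 60L,
                       n_taxon_linked = 3L, taxon_beta = 1,
                       n_diversity_linked = 3L, diversity_slope = -1,
                       n_balance_linked = 2L, balance_coef = 2,
                       n_baseline = 8L, noise_sd = 0.3,
                       n_extract_only = 10L, n_decoys = 10L,
                       n_blank_contaminants = 5L, n_extract_reps = 4L,
                       n_baseline_samples = 6L, seed = 1L) {
  cfg <- as.list(environment())
  num <- vapply(cfg, is.numeric, logical(1L))
  stopifnot(all(num), all(unlist(cfg[num]) >= 0 | names(cfg[num]) ==
                            "diversity_slope"))
  if (cfg$n_lcm %% cfg$n_cohorts != 0L) {
    stop("n_lcm must divide evenly into n_cohorts", call. = FALSE)
  }
  n_planted <- cfg$n_taxon_linked + cfg$n_diversity_linked +
    cfg$n_balance_linked
  if (n_planted + cfg$n_baseline > cfg$n_compounds) {
    stop("more planted + baseline compounds than n_compounds", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a random rooted phylogeny
#'
#' Random bifurcating topology with exponential branch lengths and tip
#' labels `ASV001, ASV002, ...`; deterministic per seed.
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer RNG seed.
#' @return a rooted `phylo` tree.
#' @export
generate_tree <- function(n_tips, seed) {
  if (n_tips < 2L) stop("need at least 2 tips", call. = FALSE)
  with_seed(seed, {
    tree <- ape::rtree(n_tips, rooted = TRUE, br = function(n) rexp(n, 1))
    tree$tip.label <- sprintf("ASV%03d", seq_len(n_tips))
    validate_tree(tree)
  })
}

# Dirichlet draw via independent gammas; shapes of exactly 0 give exact 0s.
rdirichlet1 <- function(shape) {
  g <- ifelse(shape > 0, rgamma(length(shape), shape = shape), 0)
  if (sum(g) == 0) g[which.max(shape)] <- 1
  g / sum(g)
}

#' Generate donor-structured mouse microbiomes
#'
#' Each humanized donor gets a sparse Dirichlet base composition over a
#' random ASV support (always including the shared core); each replicate
#' mouse resamples that base (Dirichlet with concentration `mouse_tau`) and
#' is observed multinomially at its sequencing depth, so replicate pairs
#' stay phylogenetically closer to each other than to other donors while
#' still differing in rare-taxon presence.  LCM mice draw from a cohort base
#' in which the 6 dominant ASVs carry `lcm_dominant_mass` of the reads.
#'
#' @param config a [sim_config()].
#' @param tree phylogeny whose tips are the ASV pool.
#' @param seed integer RNG seed.
#' @return list with `table` (a [feature_table()]), `metadata` (a
#'   [sample_metadata()] frame) and `core_asvs`, `lcm_dominant` id vectors.
#' @export
generate_microbiomes <- function(config, tree, seed) {
  tips <- sort(tree$tip.label)
  stopifnot(length(tips) == config$n_asv)
  with_seed(seed, {
    core <- sort(sample(tips, config$n_core))
    lcm_dom <- sort(sample(setdiff(tips, core), config$n_lcm_dominant))
    lcm_tail <- sort(sample(setdiff(tips, c(core, lcm_dom)),
                            config$n_lcm_tail))

    samples <- character(0); rows <- list(); meta <- list()
    draw_mouse <- function(base_p, tau) {
      p <- rdirichlet1(tau * base_p)
      depth <- sample(seq(config$depth_min, config$depth_max), 1L)
      drop(rmultinom(1L, depth, p))
    }

    donors <- sprintf("D%02d", seq_len(config$n_donors))
    cohorts <- sprintf("c%d", seq_len(config$n_cohorts))
    for (d in seq_along(donors)) {
      extra <- sample(setdiff(tips, core),
                      config$donor_support_size - config$n_core)
      shape <- setNames(rep(0, length(tips)), tips)
      shape[extra] <- config$donor_alpha
      shape[core] <- config$donor_alpha * 8    # core stays prevalent
      base_p <- rdirichlet1(shape)
      for (r in seq_len(config$replicates_per_donor)) {
        id <- sprintf("HU_%s_r%d", donors[d], r)
        samples <- c(samples, id)
        rows[[id]] <- draw_mouse(base_p, config$mouse_tau)
        meta[[id]] <- data.frame(sample_id = id, group = "HU",
                                 donor_id = donors[d],
                                 cohort_id = cohorts[(d - 1L) %%
                                                       config$n_cohorts + 1L])
      }
    }
    per_cohort <- config$n_lcm / config$n_cohorts
    for (ci in seq_along(cohorts)) {
      shape <- setNames(rep(0, length(tips)), tips)
      # base masses: dominant block vs small tail (incl. core at trace level)
      shape[lcm_dom] <- config$lcm_dominant_mass / config$n_lcm_dominant
      minor <- c(lcm_tail, core)
      shape[minor] <- (1 - config$lcm_dominant_mass) / length(minor)
      base_p <- rdirichlet1(shape * 300)  # mild cohort-level variation
      for (m in seq_len(per_cohort)) {
        id <- sprintf("LCM_%s_m%d", cohorts[ci], m)
        samples <- c(samples, id)
        rows[[id]] <- draw_mouse(base_p, config$lcm_tau)
        meta[[id]] <- data.frame(sample_id = id, group = "LCM",
                                 donor_id = "", cohort_id = cohorts[ci])
      }
    }
    counts <- do.call(rbind, rows[samples])
    colnames(counts) <- tips
    list(table = feature_table(counts),
         metadata = sample_metadata(do.call(rbind, meta[samples])),
         core_asvs = core, lcm_dominant = lcm_dom)
  })
}

#' Generate plasma compound tables with planted effects
#'
#' Compounds are built on a standardized signal scale and mapped affinely to
#' positive peak areas (so z-scoring in the screens recovers the construct):
#' taxon-linked compounds are linear in the standardized
#' `arcsinh(100 * relative abundance)` of a prevalent core ASV with slope
#' `taxon_beta`; diversity-linked compounds are linear in standardized Faith
#' PD; balance-linked compounds are linear in a planted two-taxon log-ratio;
#' the rest are pure lognormal noise.  All planted parameters, the per-
#' compound effective slopes on the screens' scales, and the baseline-
#' compound ids are recorded in the ground-truth ledger.
#'
#' @param config a [sim_config()].
#' @param microbiomes result of [generate_microbiomes()].
#' @param tree the phylogeny.
#' @param seed integer RNG seed.
#' @return list with `compounds` (a [compound_table()]) and `ground_truth`.
#' @export
generate_compounds <- function(config, microbiomes, tree, seed) {
  table <- microbiomes$table
  relab <- relative_abundance(table)
  pd <- faith_pd(table, tree)
  n <- nrow(table)
  n_planted <- config$n_taxon_linked + config$n_diversity_linked +
    config$n_balance_linked
  if (n_planted + config$n_baseline > config$n_compounds) {
    stop("more planted compounds than n_compounds", call. = FALSE)
  }
  with_seed(seed, {
    # hosts: prevalent ASVs (>= 60% of samples) with the most variable
    # arcsinh abundance -- the taxa a screen would actually interrogate
    prevalent <- colnames(relab)[colMeans(relab > 0) >= 0.6]
    xprev <- arcsinh_percent(relab[, prevalent, drop = FALSE])
    hosts <- prevalent[order(-apply(xprev, 2, var))]
    taxon_hosts <- hosts[seq_len(config$n_taxon_linked)]
    bal_taxa <- hosts[config$n_taxon_linked + 1:2]

    ids <- sprintf("C%03d", seq_len(config$n_compounds))
    areas <- matrix(NA_real_, n, config$n_compounds,
                    dimnames = list(rownames(table), ids))
    std <- function(v) (v - mean(v)) / sd(v)
    affine_area <- function(z) {
      scale_j <- exp(runif(1, log(2e5), log(2e6)))
      scale_j * (4 + z)
    }
    gt_taxon <- list(); gt_div <- list(); gt_bal <- list()
    j <- 0L
    for (tx in taxon_hosts) {
      j <- j + 1L
      x <- arcsinh_percent(relab[, tx])
      z <- std(config$taxon_beta * std(x) + rnorm(n, 0, config$noise_sd))
      areas[, j] <- affine_area(z)
      gt_taxon[[length(gt_taxon) + 1L]] <- data.frame(
        compound_id = ids[j], taxon_id = tx, beta = config$taxon_beta,
        effective_slope = unname(coef(lm(z ~ x))[2L]))
    }
    for (k in seq_len(config$n_diversity_linked)) {
      j <- j + 1L
      z <- std(config$diversity_slope * std(pd) +
                 rnorm(n, 0, config$noise_sd))
      areas[, j] <- affine_area(z)
      gt_div[[k]] <- data.frame(
        compound_id = ids[j], slope = config$diversity_slope,
        effective_slope = unname(coef(lm(z ~ pd))[2L]))
    }
    pc <- min(relab[relab > 0]) / 2
    for (k in seq_len(config$n_balance_linked)) {
      j <- j + 1L
      b <- balance_value(relab, bal_taxa[1L], bal_taxa[2L], pc)
      z <- std(config$balance_coef * std(b) + rnorm(n, 0, config$noise_sd))
      areas[, j] <- affine_area(z)
      gt_bal[[k]] <- data.frame(
        compound_id = ids[j], numerator = bal_taxa[1L],
        denominator = bal_taxa[2L], coefficient = config$balance_coef)
    }
    for (k in (j + 1L):config$n_compounds) {
      areas[, k] <- rlnorm(n, log(4e5), 0.15)
    }
    noise_ids <- ids[(j + 1L):config$n_compounds]
    baseline_ids <- sort(sample(noise_ids, config$n_baseline))
    fraction <- sample(c("lipid", "aqueous"), config$n_compounds,
                       replace = TRUE, prob = c(0.7, 0.3))
    ground_truth <- list(
      taxon_pairs = do.call(rbind, gt_taxon),
      diversity_compounds = do.call(rbind, gt_div),
      balance_compounds = do.call(rbind, gt_bal),
      baseline_ids = baseline_ids,
      noise_ids = setdiff(noise_ids, baseline_ids))
    list(compounds = compound_table(areas, setNames(fraction, ids)),
         ground_truth = ground_truth)
  })
}

#' Generate LC-MS feature lists for the tracking stage
#'
#' Builds extract replicates, blanks, plasma and unexposed-baseline feature
#' lists such that targeted tracking at default [match_params()] recovers
#' exactly the non-baseline true compounds: true plasma features are
#' displaced from the extract consensus by at most 5 ppm and 0.1 min with
#' consistent M2/M1 ratios; decoy features are displaced by more than
#' 15 ppm or 0.5 min; blank contaminants appear in every extract replicate
#' and in the blanks; baseline compounds also appear in unexposed plasma.
#'
#' @param config a [sim_config()].
#' @param compounds the plasma [compound_table()].
#' @param ground_truth ledger from [generate_compounds()].
#' @param seed integer RNG seed.
#' @return list of long-format record frames: `extract`, `blanks`, `plasma`,
#'   `baseline`, plus `decoy_ids` and `extract_only_ids` appended to the
#'   ground truth.
#' @export
generate_lcms_features <- function(config, compounds, ground_truth, seed) {
  ids <- colnames(compounds)
  fr <- compound_fractions(compounds)
  with_seed(seed, {
    extra_n <- config$n_extract_only + config$n_decoys +
      config$n_blank_contaminants
    extra_ids <- sprintf("X%03d", seq_len(extra_n))
    extract_only <- extra_ids[seq_len(config$n_extract_only)]
    decoys <- extra_ids[config$n_extract_only + seq_len(config$n_decoys)]
    contam <- extra_ids[config$n_extract_only + config$n_decoys +
                          seq_len(config$n_blank_contaminants)]
    all_ids <- c(ids, extra_ids)
    all_fr <- c(fr, setNames(sample(c("lipid", "aqueous"), extra_n,
                                    replace = TRUE, prob = c(0.7, 0.3)),
                             extra_ids))
    # well-separated true masses so a decoy offset can never alias another
    mass <- setNames(seq(150, 900, length.out = length(all_ids)) +
                       runif(length(all_ids), -0.01, 0.01), all_ids)
    rt <- setNames(runif(length(all_ids), 1.5, 9.0), all_ids)
    ratio <- setNames(runif(length(all_ids), 0.05, 0.35), all_ids)

    mk <- function(cid, sample_id, m, r, a1, rat) {
      data.frame(compound_id = cid, annotation = NA_character_, mass = m,
                 rt = r, fraction = all_fr[cid], sample_id = sample_id,
                 area_m1 = a1, area_m2 = rat * a1, adduct_mass = NA_real_,
                 stringsAsFactors = FALSE)
    }
    ppm_shift <- function(m, ppm) m * (1 + ppm * 1e-6)

    extract <- do.call(rbind, lapply(seq_len(config$n_extract_reps),
                                     function(rp) {
      cid <- all_ids
      mk(cid, sprintf("EX%d", rp),
         ppm_shift(mass[cid], runif(length(cid), -2, 2)),
         rt[cid] + runif(length(cid), -0.02, 0.02),
         exp(runif(length(cid), log(5e5), log(5e6))),
         ratio[cid] * runif(length(cid), 0.97, 1.03))
    }))
    blanks <- mk(contam, "BLK1",
                 ppm_shift(mass[contam], runif(length(contam), -2, 2)),
                 rt[contam] + runif(length(contam), -0.02, 0.02),
                 exp(runif(length(contam), log(1e5), log(1e6))),
                 ratio[contam])

    plasma <- do.call(rbind, lapply(rownames(compounds), function(s) {
      true <- mk(ids, s, ppm_shift(mass[ids], runif(length(ids), -5, 5)),
                 rt[ids] + runif(length(ids), -0.1, 0.1),
                 unclass(compounds)[s, ids],
                 ratio[ids] * runif(length(ids), 0.9, 1.1))
      off_mass <- runif(length(decoys)) < 0.5
      dk <- mk(decoys, s,
               ppm_shift(mass[decoys],
                         ifelse(off_mass, sample(c(-1, 1), length(decoys),
                                                 TRUE) *
                                  runif(length(decoys), 20, 60), 0)),
               rt[decoys] + ifelse(off_mass, 0,
                                   sample(c(-1, 1), length(decoys), TRUE) *
                                     runif(length(decoys), 0.6, 1.2)),
               exp(runif(length(decoys), log(1e5), log(1e6))),
               ratio[decoys])
      rbind(true, dk)
    }))
    baseline_ids <- ground_truth$baseline_ids
    baseline <- do.call(rbind,
                        lapply(seq_len(config$n_baseline_samples),
                               function(b) {
      mk(baseline_ids, sprintf("BASE%d", b),
         ppm_shift(mass[baseline_ids],
                   runif(length(baseline_ids), -5, 5)),
         rt[baseline_ids] + runif(length(baseline_ids), -0.1, 0.1),
         exp(runif(length(baseline_ids), log(1e5), log(1e6))),
         ratio[baseline_ids])
    }))
    list(extract = compound_records(extract),
         blanks = compound_records(blanks),
         plasma = compound_records(plasma),
         baseline = compound_records(baseline),
         decoy_ids = decoys, extract_only_ids = extract_only,
         contaminant_ids = contam)
  })
}

#' Generate a complete synthetic study world
#'
#' Runs [generate_tree()], [generate_microbiomes()], [generate_compounds()]
#' and [generate_lcms_features()] with stage seeds derived from
#' `config$seed`, and assembles the full ground-truth ledger.
#'
#' @param config a [sim_config()].
#' @return list: `tree`, `table`, `metadata`, `compounds`, `lcms`,
#'   `ground_truth`, `config`.
#' @export
simulate_world <- function(config = sim_config()) {
  seed <- as.integer(config$seed)
  tree <- generate_tree(config$n_asv, seed = seed * 4L + 1L)
  mb <- generate_microbiomes(config, tree, seed = seed * 4L + 2L)
  cmp <- generate_compounds(config, mb, tree, seed = seed * 4L + 3L)
  lcms <- generate_lcms_features(config, cmp$compounds, cmp$ground_truth,
                                 seed = seed * 4L + 4L)
  gt <- cmp$ground_truth
  gt$decoy_ids <- lcms$decoy_ids
  gt$extract_only_ids <- lcms$extract_only_ids
  gt$contaminant_ids <- lcms$contaminant_ids
  gt$true_ids <- colnames(cmp$compounds)
  gt$core_asvs <- mb$core_asvs
  gt$lcm_dominant <- mb$lcm_dominant
  list(tree = tree, table = mb$table, metadata = mb$metadata,
       compounds = cmp$compounds,
       lcms = lcms[c("extract", "blanks", "plasma", "baseline")],
       ground_truth = gt, config = config)
}
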