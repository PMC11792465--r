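# Shared fixtures and independent oracles used across test files.
# Oracles deliberately re-derive each quantity from its definition, not by
# calling the implementation under test.

toy_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1):0;")
}

toy_table <- function(rows, features = c("A", "B", "C", "D")) {
  m <- do.call(rbind, rows)
  dimnames(m) <- list(paste0("s", seq_len(nrow(m))), features)
  feature_table(m)
}

random_tree <- function(n_tips) {
  tr <- ape::rtree(n_tips, rooted = TRUE, br = function(n) runif(n, 0.1, 2))
  tr$tip.label <- sprintf("t%02d", seq_len(n_tips))
  tr
}

# presence table with every sample non-empty
random_presence_table <- function(n_samples, tips) {
  m <- matrix(rbinom(n_samples * length(tips), 1, 0.5), n_samples,
              dimnames = list(paste0("s", seq_len(n_samples)), tips))
  empty <- rowSums(m) == 0
  m[cbind(which(empty), sample(length(tips), sum(empty), replace = TRUE))] <- 1
  feature_table(m)
}

# Brute-force unweighted UniFrac: enumerate, for every edge, the tip set
# below it (by walking tip-to-root paths), then apply the definition.
oracle_unifrac <- function(table, tree) {
  n_tip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_len <- setNames(tree$edge.length, tree$edge[, 2L])  # by child node
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  # edges (by child node) on the root path of each tip
  path_edges <- lapply(seq_len(n_tip), function(tip) {
    nodes <- integer(0); v <- tip
    while (v != root) { nodes <- c(nodes, v); v <- parent_of[v] }
    nodes
  })
  names(path_edges) <- tree$tip.label
  spanned_set <- function(present_tips) {
    unique(unlist(path_edges[present_tips]))
  }
  n <- nrow(table)
  d <- matrix(0, n, n, dimnames = list(rownames(table), rownames(table)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      si <- spanned_set(colnames(table)[table[i, ] > 0])
      sj <- spanned_set(colnames(table)[table[j, ] > 0])
      uniq <- sum(edge_len[as.character(setdiff(union(si, sj),
                                                intersect(si, sj)))])
      tot <- sum(edge_len[as.character(union(si, sj))])
      d[i, j] <- uniq / tot
    }
  }
  d
}

oracle_faith_pd <- function(table, tree) {
  # reuse the path enumeration: PD = total length of the union of root paths
  n_tip <- length(tree$tip.label)
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_len <- setNames(tree$edge.length, tree$edge[, 2L])
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])
  path_edges <- lapply(seq_len(n_tip), function(tip) {
    nodes <- integer(0); v <- tip
    while (v != root) { nodes <- c(nodes, v); v <- parent_of[v] }
    nodes
  })
  names(path_edges) <- tree$tip.label
  vapply(seq_len(nrow(table)), function(i) {
    sum(edge_len[as.character(unique(unlist(
      path_edges[colnames(table)[table[i, ] > 0]])))])
  }, numeric(1L))
}

# Direct block-sandwich CR1 variance for y ~ 1 + x.
oracle_cr1 <- function(y, x, clusters) {
  X <- cbind(1, x)
  n <- nrow(X); k <- ncol(X)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% y
  e <- y - X %*% beta
  groups <- unique(clusters)
  G <- length(groups)
  meat <- Reduce(`+`, lapply(groups, function(g) {
    Xg <- X[clusters == g, , drop = FALSE]
    eg <- e[clusters == g]
    (t(Xg) %*% eg) %*% (t(eg) %*% Xg)
  }))
  V <- (G / (G - 1)) * ((n - 1) / (n - k)) * XtXi %*% meat %*% XtXi
  list(beta = beta[2L], se = sqrt(V[2L, 2L]))
}

# Leave-one-out DFFITS: (yhat_i - yhat_i^(-i)) / (s_(i) sqrt(h_i)).
oracle_dffits <- function(y, x) {
  n <- length(y)
  X <- cbind(1, x)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  fit <- lm(y ~ x)
  vapply(seq_len(n), function(i) {
    fit_i <- lm(y[-i] ~ x[-i])
    pred_i <- coef(fit_i)[1L] + coef(fit_i)[2L] * x[i]
    s_i <- summary(fit_i)$sigma
    (fitted(fit)[i] - pred_i) / (s_i * sqrt(H[i, i]))
  }, numeric(1L))
}

# Small, fast synthetic world for tracking tests.
small_sim <- function(seed = 1) {
  sim_config(n_compounds = 20L, n_taxon_linked = 2L, n_diversity_linked = 2L,
             n_balance_linked = 1L, n_baseline = 4L, n_extract_only = 4L,
             n_decoys = 5L, n_blank_contaminants = 3L, seed = seed)
}

run_tracking <- function(world, params = match_params()) {
  ext <- define_extract_compounds(world$lcms$extract, world$lcms$blanks,
                                  params)
  matched <- match_to_plasma(ext, world$lcms$plasma, params)
  detected <- apply_detection_filters(matched, params)
  list(extract = ext, detected = detected,
       report = remove_baseline(detected, world$lcms$baseline, params,
                                n_extract = nrow(ext)))
}

# One long-format compound record row with defaults.
rec <- function(compound_id, sample_id, mass, rt, fraction = "aqueous",
                area_m1 = 1e6, area_m2 = NA, adduct_mass = NA,
                annotation = NA) {
  data.frame(compound_id = compound_id, annotation = annotation, mass = mass,
             rt = rt, fraction = fraction, sample_id = sample_id,
             area_m1 = area_m1, area_m2 = area_m2, adduct_mass = adduct_mass,
             stringsAsFactors = FALSE)
}
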