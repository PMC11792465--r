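# Rarefaction, Faith's phylogenetic diversity, unweighted UniFrac,
# Bray-Curtis and Jaccard, implemented from first principles on the
# edge-incidence structure of the tree.
#
# Root convention (shared by faith_pd and unweighted_unifrac): a branch is
# spanned by a community iff its subtree contains at least one present tip,
# so the stem from the root down to a community's most recent common
# ancestor is included.

# edges x tips logical incidence: entry (e, t) is TRUE when tip t descends
# from edge e.  Computed once per tree by accumulating tip sets in postorder.
edge_tip_incidence <- function(tree) {
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- matrix(FALSE, n_node, n_tip,
                  dimnames = list(NULL, tree$tip.label))
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  edge <- tree$edge
  for (i in ape::postorder(tree)) {
    parent <- edge[i, 1L]; child <- edge[i, 2L]
    below[parent, ] <- below[parent, ] | below[child, ]
  }
  inc <- below[edge[, 2L], , drop = FALSE]
  rownames(inc) <- NULL
  inc
}

#' Rarefy a feature table to even depth
#'
#' Subsamples every sample's reads without replacement to exactly `depth`,
#' deterministically for a given seed.  Samples are processed in table row
#' order.
#'
#' @param table a [feature_table()].
#' @param depth target reads per sample; every sample total must be at least
#'   `depth` (choose the largest depth that excludes no sample).
#' @param seed integer RNG seed.
#' @return the rarefied feature table (row sums all equal `depth`).
#' @export
rarefy <- function(table, depth, seed) {
  table <- feature_table(table)
  totals <- rowSums(table)
  short <- totals < depth
  if (any(short)) {
    stop("sample(s) below rarefaction depth ", depth, ": ",
         paste(rownames(table)[short], collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    out <- table
    for (i in seq_len(nrow(table))) {
      if (totals[i] == depth) next
      pool <- rep.int(seq_len(ncol(table)), table[i, ])
      draw <- sample(pool, depth, replace = FALSE)
      out[i, ] <- tabulate(draw, nbins = ncol(table))
    }
    out
  })
}

#' Faith's phylogenetic diversity
#'
#' Per sample, the total branch length of the minimal subtree connecting the
#' root and every tip with a positive count (the root stem is included).
#'
#' @param table a [feature_table()]; features with positive counts must all
#'   be tips of `tree`.
#' @param tree rooted `phylo` tree with branch lengths.
#' @return named numeric vector of PD values (summed branch length units).
#' @export
faith_pd <- function(table, tree) {
  table <- feature_table(table)
  present_features <- colnames(table)[colSums(table) > 0]
  missing <- setdiff(present_features, tree$tip.label)
  if (length(missing)) {
    stop("feature(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  inc <- edge_tip_incidence(tree)
  pres <- table[, colnames(inc), drop = FALSE] > 0
  # spanned[e, s]: edge e subtends >= 1 present tip of sample s
  spanned <- inc %*% t(pres) > 0
  setNames(as.numeric(crossprod(spanned, tree$edge.length)), rownames(table))
}

#' Unweighted UniFrac distance matrix
#'
#' Presence/absence phylogenetic beta diversity:
#' `d(i, j)` is the branch length spanned by exactly one of the two samples
#' divided by the branch length spanned by their union, under the same
#' root-inclusive spanning rule as [faith_pd()].
#'
#' @param table a [feature_table()] (counts; presence is `count > 0`).
#' @param tree rooted `phylo` tree with branch lengths.
#' @return a labeled [distance_matrix()] with entries in `[0, 1]`.
#' @export
unweighted_unifrac <- function(table, tree) {
  table <- feature_table(table)
  if (any(rowSums(table) == 0)) stop("sample with zero total", call. = FALSE)
  missing <- setdiff(colnames(table)[colSums(table) > 0], tree$tip.label)
  if (length(missing)) {
    stop("feature(s) not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  inc <- edge_tip_incidence(tree)
  pres <- table[, colnames(inc), drop = FALSE] > 0
  spanned <- inc %*% t(pres) > 0                      # edges x samples
  len <- tree$edge.length
  # shared[i,j] = spanned-branch length common to i and j;
  # total[i] = PD_i; union = total_i + total_j - shared
  shared <- crossprod(spanned * len, spanned)
  total <- as.numeric(crossprod(spanned, len))
  union <- outer(total, total, "+") - shared
  d <- ifelse(union > 0, 1 - shared / union, 0)
  d <- pmin(pmax(d, 0), 1)   # clamp floating-point residue at the bounds
  diag(d) <- 0
  dimnames(d) <- list(rownames(table), rownames(table))
  distance_matrix(d)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum |x_i - x_j| / sum (x_i + x_j)` over features, on raw
#' abundances (peak areas or counts).
#'
#' @param table numeric samples x features matrix with non-negative entries;
#'   all-zero samples are rejected.
#' @return labeled [distance_matrix()] with entries in `[0, 1]`.
#' @export
bray_curtis <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(m < 0)) stop("abundances must be >= 0", call. = FALSE)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("all-zero sample(s): ", paste(rownames(m)[zero], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
    }
  }
  distance_matrix(d)
}

#' Jaccard similarity of two presence sets
#'
#' `|a intersect b| / |a union b|`; both sets empty gives 1 by convention
#' (with a message).
#'
#' @param a,b character vectors of present feature ids.
#' @return similarity in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  u <- union(a, b)
  if (length(u) == 0L) {
    message("both sets empty; Jaccard similarity 1 by convention")
    return(1)
  }
  length(intersect(a, b)) / length(u)
}
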