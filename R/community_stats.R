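# PERMANOVA with categorical or continuous predictors, distance-matrix
# centroid collapsing, group averaging and BH adjustment, plus the
# per-compound composition screen built from them.

#' PERMANOVA on a distance matrix
#'
#' McArdle-Anderson partition of the Gower-centered matrix `G = -1/2 J D^2 J`:
#' with `H` the hat matrix of the design (intercept plus the predictor,
#' dummy-coded for factors), `pseudo-F = [tr(HGH)/q] / [tr((I-H)G(I-H))/(n-q-1)]`
#' and `R^2 = tr(HGH)/tr(G)`.  The p-value permutes the predictor rows
#' (unrestricted), counting permuted F at or above the observed.
#'
#' @param dm labeled [distance_matrix()].
#' @param predictor factor/character (categorical) or numeric vector aligned
#'   with `rownames(dm)`; names, if present, are checked against the labels.
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return list of class `permanova_result`: `pseudo_F`, `r_squared`,
#'   `p_value`, `n_permutations`, `df`.
#' @export
permanova <- function(dm, predictor, n_perm = 10000L, seed) {
  dm <- distance_matrix(dm)
  n <- nrow(dm)
  if (length(predictor) != n) stop("predictor length != number of samples",
                                   call. = FALSE)
  if (!is.null(names(predictor))) {
    if (!setequal(names(predictor), rownames(dm))) {
      stop("predictor names do not match distance labels", call. = FALSE)
    }
    predictor <- predictor[rownames(dm)]
  }
  if (is.numeric(predictor)) {
    if (var(predictor) == 0) stop("constant predictor", call. = FALSE)
    X <- cbind(1, predictor - mean(predictor))
  } else {
    predictor <- factor(predictor)
    if (nlevels(predictor) < 2L) stop("constant predictor", call. = FALSE)
    X <- model.matrix(~predictor)
  }
  q <- ncol(X) - 1L
  if (n - q - 1L <= 0L) stop("not enough residual degrees of freedom",
                             call. = FALSE)
  H <- X %*% solve(crossprod(X), t(X))
  G <- gower_center(dm)
  tr_G <- sum(diag(G))
  f_from_trH <- function(s) (s / q) / ((tr_G - s) / (n - q - 1L))
  s_obs <- sum(H * G)        # = tr(HG) = tr(HGH) since H idempotent symmetric
  F_obs <- f_from_trH(s_obs)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      if (f_from_trH(sum(H * G[idx, idx])) >= F_obs) h <- h + 1L
    }
    h
  })
  structure(list(pseudo_F = F_obs, r_squared = s_obs / tr_G,
                 p_value = (hits + 1L) / (n_perm + 1L),
                 n_permutations = as.integer(n_perm), df = q),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R^2 = %.3f, p = %.4g (%d perms)\n",
              x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Collapse a distance matrix to group centroids
#'
#' Between-centroid distances computed from the distances alone via the
#' standard identity on squared distances:
#' `d^2(C_A, C_B) = mean over (a,b) of d^2(a,b)
#'   - 1/2 mean over (a,a') of d^2(a,a') - 1/2 mean over (b,b') of d^2(b,b')`.
#' For non-Euclidean inputs the identity can go slightly negative; such
#' values are clipped to 0 with a warning.  Used to avoid pseudoreplication:
#' replicate mice collapse to one centroid per treatment unit before
#' permutation tests.
#'
#' @param dm labeled [distance_matrix()].
#' @param groups named character vector mapping every sample label to its
#'   treatment unit.
#' @return a [distance_matrix()] labeled by treatment unit (order of first
#'   appearance among `rownames(dm)`).
#' @export
collapse_to_centroids <- function(dm, groups) {
  dm <- distance_matrix(dm)
  if (is.null(names(groups)) || !all(rownames(dm) %in% names(groups))) {
    stop("`groups` must name every sample in the distance matrix",
         call. = FALSE)
  }
  groups <- as.character(groups[rownames(dm)])
  units <- unique(groups)
  if (any(!nzchar(units)) || anyNA(units)) stop("empty group label",
                                                call. = FALSE)
  D2 <- dm^2
  k <- length(units)
  idx <- lapply(units, function(u) which(groups == u))
  within <- vapply(idx, function(ia) mean(D2[ia, ia, drop = FALSE]),
                   numeric(1L))
  out <- matrix(0, k, k, dimnames = list(units, units))
  clipped <- FALSE
  for (a in seq_len(k - 1L)) {
    for (b in (a + 1L):k) {
      d2 <- mean(D2[idx[[a]], idx[[b]], drop = FALSE]) -
        within[a] / 2 - within[b] / 2
      if (d2 < 0) { clipped <- TRUE; d2 <- 0 }
      out[a, b] <- out[b, a] <- sqrt(d2)
    }
  }
  if (clipped) {
    warning("negative squared centroid distance(s) clipped to 0 ",
            "(non-Euclidean input)")
  }
  distance_matrix(out)
}

#' Collapse abundances or diversity values to group means
#'
#' Arithmetic mean within each treatment unit, the non-distance counterpart
#' of [collapse_to_centroids()].
#'
#' @param x samples x variables matrix (including a [compound_table()]) or a
#'   named numeric vector.
#' @param groups named character vector mapping sample labels to units.
#' @return same type as `x`, one row/entry per unit (order of first
#'   appearance).
#' @export
collapse_abundances <- function(x, groups) {
  if (is.null(dim(x))) {
    ids <- names(x)
    if (is.null(ids)) stop("vector input must be named", call. = FALSE)
    g <- as.character(groups[ids])
    if (anyNA(g) || any(!nzchar(g))) stop("every sample needs a group",
                                          call. = FALSE)
    units <- unique(g)
    return(setNames(vapply(units, function(u) mean(x[g == u]), numeric(1L)),
                    units))
  }
  ids <- rownames(x)
  g <- as.character(groups[ids])
  if (anyNA(g) || any(!nzchar(g))) stop("every sample needs a group",
                                        call. = FALSE)
  units <- unique(g)
  m <- do.call(rbind, lapply(units, function(u) {
    colMeans(unclass(x)[g == u, , drop = FALSE])
  }))
  dimnames(m) <- list(units, colnames(x))
  if (inherits(x, "compound_table")) m <- compound_table(m,
                                                         compound_fractions(x))
  m
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]` (`NA` allowed
#'   and propagated).
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "BH")
}

#' Per-compound composition screen (PERMANOVA against a distance matrix)
#'
#' For each compound, a PERMANOVA of the (centroid-collapsed) community
#' distance matrix on that compound's abundance as a continuous covariate;
#' BH adjustment across compounds.  Compounds whose test fails (for example
#' a constant abundance) are returned as excluded rows, never aborts.
#'
#' @param dm_centroids treatment-unit-level [distance_matrix()].
#' @param compounds_centroids treatment-unit-level [compound_table()] with
#'   matching labels.
#' @param n_perm permutations per compound (default 10000).
#' @param seed integer RNG seed; compound `j` uses `seed + j`.
#' @return data frame (one row per compound): `compound_id`, `fraction`,
#'   `pseudo_F`, `r_squared`, `p_value`, `p_adj`, `raw_significant`,
#'   `fdr_significant`, `excluded`, `reason`.
#' @export
compound_composition_screen <- function(dm_centroids, compounds_centroids,
                                        n_perm = 10000L, seed) {
  dm <- distance_matrix(dm_centroids)
  tab <- compounds_centroids
  if (!setequal(rownames(tab), rownames(dm))) {
    stop("compound table and distance matrix labels differ", call. = FALSE)
  }
  tab_m <- unclass(tab)[rownames(dm), , drop = FALSE]
  fr <- compound_fractions(tab)
  res <- lapply(seq_len(ncol(tab_m)), function(j) {
    fit <- tryCatch(
      permanova(dm, tab_m[, j], n_perm = n_perm, seed = seed + j),
      error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(compound_id = colnames(tab_m)[j], fraction = fr[j],
                 pseudo_F = NA_real_, r_squared = NA_real_,
                 p_value = NA_real_, excluded = TRUE,
                 reason = conditionMessage(fit), stringsAsFactors = FALSE)
    } else {
      data.frame(compound_id = colnames(tab_m)[j], fraction = fr[j],
                 pseudo_F = fit$pseudo_F, r_squared = fit$r_squared,
                 p_value = fit$p_value, excluded = FALSE, reason = NA_character_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_value)
  out$raw_significant <- !is.na(out$p_value) & out$p_value < 0.05
  out$fdr_significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  rownames(out) <- NULL
  out[, c("compound_id", "fraction", "pseudo_F", "r_squared", "p_value",
          "p_adj", "raw_significant", "fdr_significant", "excluded", "reason")]
}
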