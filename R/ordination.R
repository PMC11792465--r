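# Principal coordinates analysis, least-squares Procrustes superimposition
# with Gower's m^2 statistic, and its permutation test (PROTEST-style).

#' Principal coordinates analysis of a distance matrix
#'
#' Eigendecomposition of the Gower-centered matrix `-1/2 J D^2 J` with
#' `J = I - 11'/n`.  Coordinates are eigenvectors scaled by the square root
#' of their (positive) eigenvalues; axes with eigenvalues at or below the
#' numerical tolerance are dropped and the total magnitude of negative
#' eigenvalues is reported.
#'
#' @param dm a labeled [distance_matrix()], `n >= 3`.
#' @param tol eigenvalues with absolute value below `tol * max(|eigenvalue|)`
#'   are treated as zero.
#' @return list of class `pcoa_result` with `sample_ids`, `coordinates`
#'   (samples x axes), `eigenvalues` (positive, descending),
#'   `proportion_explained` (relative to the total absolute eigenvalue mass),
#'   and `negative_eigenvalue_magnitude`.
#' @export
pcoa <- function(dm, tol = 1e-9) {
  dm <- distance_matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("PCoA needs at least 3 samples", call. = FALSE)
  G <- gower_center(dm)
  eig <- eigen(G, symmetric = TRUE)
  scale_ref <- max(abs(eig$values), 1e-300)
  pos <- eig$values > tol * scale_ref
  neg <- eig$values < -tol * scale_ref
  vals <- eig$values[pos]
  coords <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals), sum(pos))
  dimnames(coords) <- list(rownames(dm),
                           if (ncol(coords)) paste0("PCo",
                                                    seq_len(ncol(coords))))
  denom <- sum(abs(eig$values[pos | neg]))
  structure(list(
    sample_ids = rownames(dm),
    coordinates = coords,
    eigenvalues = vals,
    proportion_explained = if (denom > 0) vals / denom else rep(0, length(vals)),
    negative_eigenvalue_magnitude = sum(abs(eig$values[neg]))),
    class = "pcoa_result")
}

# -1/2 J D^2 J, the doubly-centered squared-distance (Gower) matrix.
gower_center <- function(dm) {
  A <- -0.5 * dm^2
  n <- nrow(A)
  rm_ <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1, rm_), 2, rm_) + gm
}

# Center rows, pad columns with zeros to a common width, scale to unit
# sum of squares.
procrustes_prepare <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("configurations differ in row count",
                               call. = FALSE)
  if (!is.null(rownames(x)) && !is.null(rownames(y)) &&
      !identical(rownames(x), rownames(y))) {
    stop("row labels of the two configurations do not match", call. = FALSE)
  }
  k <- max(ncol(x), ncol(y))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  x <- pad(x); y <- pad(y)
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0) stop("degenerate configuration (all points equal)",
                               call. = FALSE)
  list(x = x / sx, y = y / sy)
}

#' Procrustes superimposition and Gower's m-squared
#'
#' Centers both configurations, scales each to unit sum of squares, and
#' finds the orthogonal transformation (reflections allowed) plus
#' least-squares scale of the target minimizing the residual sum of squares.
#' The minimized residual is Gower's statistic
#' `m^2 = 1 - (sum of singular values of X'Y)^2`, in `[0, 1]`: 0 for
#' configurations identical up to rotation/translation/scaling.
#'
#' @param reference,target samples x axes coordinate matrices with aligned
#'   rows (e.g. `$coordinates` of two [pcoa()] results); columns are
#'   zero-padded to a common width.
#' @return list of class `procrustes_result` with `m_squared`,
#'   `transformed_target` (rotated and scaled onto the reference),
#'   `p_value = NULL`, `n_permutations = NULL`.
#' @export
procrustes <- function(reference, target) {
  p <- procrustes_prepare(reference, target)
  sv <- svd(crossprod(p$x, p$y))
  trace_w <- sum(sv$d)
  rot <- sv$v %*% t(sv$u)
  structure(list(
    m_squared = max(0, 1 - trace_w^2),
    transformed_target = trace_w * p$y %*% rot,
    p_value = NULL, n_permutations = NULL),
    class = "procrustes_result")
}

# m^2 only, on pre-prepared (unit-scaled) configurations; used in the
# permutation loop where re-centering the permuted target is still required.
m2_stat <- function(x, y) {
  y <- scale(y, center = TRUE, scale = FALSE)
  y <- y / sqrt(sum(y^2))
  max(0, 1 - sum(svd(crossprod(x, y))$d)^2)
}

#' Procrustes randomization test
#'
#' Permutes the row order of the target configuration `n_perm` times,
#' recomputing `m^2` for each permutation;
#' `p = (#{permuted m^2 <= observed m^2} + 1) / (n_perm + 1)`.
#' Equal-or-better permuted fits count against the null.
#'
#' @param reference,target as in [procrustes()].
#' @param n_perm number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return a `procrustes_result` with `p_value` and `n_permutations` filled.
#' @export
procrustes_randomization_test <- function(reference, target, n_perm = 10000L,
                                          seed) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs <- procrustes(reference, target)
  p <- procrustes_prepare(reference, target)
  n <- nrow(p$x)
  hits <- with_seed(seed, {
    h <- 0L
    for (b in seq_len(n_perm)) {
      m2 <- m2_stat(p$x, p$y[sample.int(n), , drop = FALSE])
      if (m2 <= obs$m_squared) h <- h + 1L
    }
    h
  })
  obs$p_value <- (hits + 1L) / (n_perm + 1L)
  obs$n_permutations <- as.integer(n_perm)
  obs
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes m^2 = %.4f", x$m_squared))
  if (!is.null(x$p_value)) {
    cat(sprintf("  (p = %.4g, %d permutations)", x$p_value, x$n_permutations))
  }
  cat("\n")
  invisible(x)
}
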