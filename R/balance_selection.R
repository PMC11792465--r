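# Greedy selection of a two-part (extendable) log-ratio balance of taxa
# that best explains a continuous response, with cross-validated R^2.

#' Value of a log-ratio balance
#'
#' For a numerator set of size `p` and denominator set of size `q`,
#' `B = sqrt(pq / (p + q)) * [mean ln(x + c) over numerator
#'                            - mean ln(x + c) over denominator]`,
#' the isometric log-ratio contrast between the two groups' geometric means.
#' Scale-invariant in the composition when `pseudocount = 0`.
#'
#' @param composition named non-negative vector (or samples x taxa matrix) of
#'   relative abundances.
#' @param num,den disjoint character vectors of taxon ids.
#' @param pseudocount added inside the log to admit zeros.
#' @return numeric balance value(s), one per sample.
#' @export
balance_value <- function(composition, num, den, pseudocount = 0) {
  if (length(intersect(num, den))) stop("numerator and denominator overlap",
                                        call. = FALSE)
  if (length(num) < 1L || length(den) < 1L) stop("both parts need >= 1 taxon",
                                                 call. = FALSE)
  m <- if (is.null(dim(composition))) matrix(composition, 1L,
    dimnames = list(NULL, names(composition))) else as.matrix(composition)
  missing <- setdiff(c(num, den), colnames(m))
  if (length(missing)) stop("taxa not in composition: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  lg <- log(m + pseudocount)
  p <- length(num); q <- length(den)
  b <- sqrt(p * q / (p + q)) *
    (rowMeans(lg[, num, drop = FALSE]) - rowMeans(lg[, den, drop = FALSE]))
  if (is.null(dim(composition))) unname(b) else b
}

# R^2 of a simple linear regression of response on b.
.r2 <- function(response, b) {
  if (var(b) == 0) return(-Inf)
  suppressWarnings(cor(response, b))^2
}

#' Greedy balance search with cross-validation
#'
#' Evaluates every taxon pair as a singleton balance, scoring by the R^2 of
#' a linear regression of the response on the balance; then forward-adds, to
#' either side, the single taxon that most improves R^2, stopping at
#' `max_size` total taxa or when no addition improves the fit.  Ties break
#' lexicographically on taxon id, and the numerator is oriented so the
#' regression slope is non-negative.  The cross-validated R^2 re-estimates
#' the regression coefficients per fold for the selected balance
#' (out-of-fold predicted R^2); fold assignment is deterministic per seed.
#' With fewer samples than folds the scheme degrades gracefully toward
#' leave-one-out.
#'
#' @param taxa samples x taxa relative-abundance matrix (>= 2 taxa); zeros
#'   handled by a pseudocount of half the smallest nonzero entry.
#' @param response aligned numeric vector, non-constant.
#' @param n_folds cross-validation folds (default 10).
#' @param max_size maximum total number of taxa in the balance (default 2,
#'   i.e. a plain two-taxon log ratio).
#' @param seed integer RNG seed (fold assignment).
#' @return list of class `balance`: `numerator`, `denominator`,
#'   `coefficient` (response units per balance unit), `intercept`,
#'   `r_squared`, `cv_r_squared`, `pseudocount`.
#' @export
select_balance <- function(taxa, response, n_folds = 10L, max_size = 2L,
                           seed = 1L) {
  taxa <- as.matrix(taxa)
  if (ncol(taxa) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (var(response) == 0) stop("constant response", call. = FALSE)
  if (nrow(taxa) != length(response)) stop("response misaligned",
                                           call. = FALSE)
  nz <- taxa[taxa > 0]
  pc <- if (any(taxa == 0)) min(nz) / 2 else 0
  ids <- sort(colnames(taxa))
  lg <- log(taxa + pc)

  # stage 1: all unordered pairs as singleton balances (R^2 is sign-invariant)
  best <- list(num = NULL, den = NULL, r2 = -Inf)
  for (a in seq_along(ids)[-length(ids)]) {
    for (b in (a + 1L):length(ids)) {
      bal <- sqrt(0.5) * (lg[, ids[a]] - lg[, ids[b]])
      r2 <- .r2(response, bal)
      if (r2 > best$r2 + 1e-12) best <- list(num = ids[a], den = ids[b],
                                             r2 = r2)
    }
  }
  # orient: numerator carries the positively-associated taxon
  bal <- balance_value(taxa, best$num, best$den, pc)
  if (coef(lm(response ~ bal))[2L] < 0) {
    best[c("num", "den")] <- best[c("den", "num")]
  }

  # stage 2: forward addition to either side while R^2 improves
  repeat {
    if (length(best$num) + length(best$den) >= max_size) break
    cand <- setdiff(ids, c(best$num, best$den))
    step <- list(r2 = best$r2)
    for (tx in cand) {
      for (side in c("num", "den")) {
        num <- if (side == "num") c(best$num, tx) else best$num
        den <- if (side == "den") c(best$den, tx) else best$den
        r2 <- .r2(response, balance_value(taxa, num, den, pc))
        if (r2 > step$r2 + 1e-12) step <- list(num = num, den = den, r2 = r2)
      }
    }
    if (is.null(step$num)) break
    best <- step
  }

  b <- balance_value(taxa, best$num, best$den, pc)
  fit <- lm(response ~ b)
  n <- length(response)
  folds <- with_seed(seed, sample(rep_len(seq_len(min(n_folds, n)), n)))
  press <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    cf <- coef(lm(response[!hold] ~ b[!hold]))
    press <- press + sum((response[hold] - (cf[1L] + cf[2L] * b[hold]))^2)
  }
  structure(list(
    numerator = best$num, denominator = best$den,
    coefficient = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
    r_squared = summary(fit)$r.squared,
    cv_r_squared = 1 - press / sum((response - mean(response))^2),
    pseudocount = pc), class = "balance")
}

#' @export
print.balance <- function(x, ...) {
  cat(sprintf("balance ln[g(%s) / g(%s)]: R^2 = %.3f, CV R^2 = %.3f\n",
              paste(x$numerator, collapse = ","),
              paste(x$denominator, collapse = ","),
              x$r_squared, x$cv_r_squared))
  invisible(x)
}
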