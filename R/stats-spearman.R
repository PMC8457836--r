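#' Spearman rank correlation via the S statistic
#'
#' Computes Spearman's rank correlation reporting the S statistic (the sum of
#' squared rank differences), rho, and a two-sided p-value. Ties receive
#' average ranks. With no ties rho comes from the classical formula
#' `rho = 1 - 6 S / (n (n^2 - 1))`; with ties rho is the Pearson correlation
#' of the rank vectors and S is still the literal sum of squared rank
#' differences. The p-value uses the t approximation with `n - 2` degrees of
#' freedom; for `n <= 9` an exact permutation p-value over all `n!` orderings
#' is available.
#'
#' @param x,y numeric vectors of equal length (n >= 3), finite values.
#' @param method `"t"` (default) or `"exact"` (n <= 9 only).
#' @return object of class `spearman_result`: list with `S`, `rho`, `p`, `n`,
#'   `ties` (logical), `method`.
#' @examples
#' spearman_rank(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_rank <- function(x, y, method = c("t", "exact")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop_("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_("inputs must be finite")
  rx <- rank(x); ry <- rank(y)
  if (var(rx) == 0 || var(ry) == 0)
    stop_("zero variance in ranks (all values tied)")
  S <- sum((rx - ry)^2)
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  rho <- if (ties) {
    sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  } else {
    1 - 6 * S / (n * (n^2 - 1))
  }
  if (method == "exact") {
    if (n > 9) stop_("exact permutation p-value only for n <= 9")
    p <- spearman_exact_p(rx, ry, S)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(S = S, rho = rho, p = p, n = n, ties = ties, method = method),
            class = "spearman_result")
}

# exact two-sided permutation p-value: tail probability of |rho| as extreme,
# enumerating all permutations of the y-ranks
spearman_exact_p <- function(rx, ry, S_obs) {
  n <- length(rx)
  perms <- permutations_all(n)
  ry_s <- sort(ry)
  rho_of <- function(ryv) {
    sum((rx - mean(rx)) * (ryv - mean(ryv))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ryv - mean(ryv))^2))
  }
  rho_obs <- abs(rho_of(rank(ry)))
  cnt <- 0L
  for (i in seq_len(nrow(perms))) {
    if (abs(rho_of(ry_s[perms[i, ]])) >= rho_obs - 1e-12) cnt <- cnt + 1L
  }
  cnt / nrow(perms)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), 1L] <- k
    out[row:(row + nrow(sub) - 1L), -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: S = %g, rho = %.4f, p = %.4g (n = %d%s)\n",
              x$S, x$rho, x$p, x$n, if (x$ties) ", ties" else ""))
  invisible(x)
}
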