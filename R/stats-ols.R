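#' Ordinary least squares with R-squared and overall F test
#'
#' Fits `y ~ 1 + X` by QR decomposition and reports coefficients with
#' standard errors, R-squared, and the overall F-test p-value. Rows with any
#' missing value are dropped listwise (count reported).
#'
#' @param y numeric response.
#' @param x numeric predictor vector, matrix, or data frame of numeric
#'   columns.
#' @return object of class `ols_result`: `coefficients` (matrix with
#'   estimate, se, t, p), `r_squared`, `f`, `p`, `n`, `df_residual`,
#'   `n_dropped`.
#' @examples
#' f <- ols_fit(c(1, 3, 5, 7, 9.1), 0:4)
#' f$coefficients
#' @export
ols_fit <- function(y, x) {
  X <- if (is.data.frame(x)) as.matrix(x) else if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (!is.numeric(X)) stop_("predictors must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop_("'y' and predictors must have equal length")
  keep <- complete.cases(y, X)
  n_dropped <- sum(!keep)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y); p <- ncol(X)
  if (n <= p + 1) stop_("need n > number of predictors + 1")
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
    stop_("singular design matrix; offending column(s): ", paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  fit <- drop(Xd %*% beta)
  res <- y - fit
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sse / sst
  df_res <- n - p - 1
  sigma2 <- sse / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  coef_tab <- cbind(estimate = beta, se = se, t = tval,
                    p = 2 * pt(-abs(tval), df = df_res))
  fstat <- if (sst == 0 || r2 >= 1) {
    if (sse < 1e-25 * max(sst, 1)) Inf else (r2 / p) / ((1 - r2) / df_res)
  } else (r2 / p) / ((1 - r2) / df_res)
  pval <- if (is.infinite(fstat)) 0 else pf(fstat, p, df_res, lower.tail = FALSE)
  structure(list(coefficients = coef_tab, r_squared = r2, f = fstat, p = pval,
                 n = n, df_residual = df_res, n_dropped = n_dropped),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R^2 = %.4f, F = %.3f, p = %.4g\n",
              x$n, x$r_squared, x$f, x$p))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with the F test. If every group
#' has zero internal variance the result is flagged degenerate and the
#' p-value is reported as the limit (0 when group means differ, 1 when they
#' do not).
#'
#' @param values numeric vector, or a list of numeric vectors (one per
#'   group, in which case `groups` is ignored).
#' @param groups grouping factor/vector parallel to `values`.
#' @return object of class `anova_result` with `f`, `p`, `df_between`,
#'   `df_within`, `group_means`, `degenerate`.
#' @export
oneway_anova <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (is.null(groups)) stop_("'groups' required when 'values' is a vector")
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  k <- nlevels(groups); n <- length(values)
  if (k < 2) stop_("need at least 2 groups")
  if (n <= k) stop_("need total n greater than the number of groups")
  gm <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  grand <- mean(values)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[as.integer(groups)])^2)
  dfb <- as.integer(k - 1); dfw <- as.integer(n - k)
  degenerate <- ssw < 1e-12 * max(ssb, 1)
  f <- if (degenerate) { if (ssb > 1e-12) Inf else 0 } else (ssb / dfb) / (ssw / dfw)
  p <- if (is.infinite(f)) 0 else pf(f, dfb, dfw, lower.tail = FALSE)
  structure(list(f = f, p = p, df_between = dfb, df_within = dfw,
                 group_means = gm, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n", x$df_between,
              x$df_within, x$f, x$p, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Within-reef versus overall variability of a trait
#'
#' The within-group component is the unweighted mean of per-group sample
#' standard deviations over groups with at least two members (groups with
#' fewer are skipped and counted); the overall component is the sample sd of
#' the pooled data.
#'
#' @param values numeric vector (e.g. control symbiont loads).
#' @param groups grouping vector (e.g. reef ids).
#' @return list with `within_sd`, `overall_sd`, `n_groups_used`,
#'   `n_groups_skipped`.
#' @export
load_variance_decomposition <- function(values, groups) {
  keep <- complete.cases(values, groups)
  values <- values[keep]; groups <- factor(groups[keep])
  sds <- tapply(values, groups, function(v) if (length(v) >= 2) sd(v) else NA_real_)
  used <- sum(!is.na(sds))
  if (used == 0) stop_("no group has at least 2 members")
  list(within_sd = mean(sds, na.rm = TRUE),
       overall_sd = sd(values),
       n_groups_used = used,
       n_groups_skipped = sum(is.na(sds)))
}
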