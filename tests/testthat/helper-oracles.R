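# Independent oracles used by the test-suite. These deliberately use
# different algorithms from the package implementations.

# ---- dip statistic: exhaustive modal-candidate oracle -----------------------
# dip(F_n) = min sup-norm distance to a unimodal CDF. Bisection on the
# sup-error T with an exhaustive feasibility scan: the mode is either shared
# at a data point (a convex band path left of it and a concave one right of
# it agree on a value there) or an atom at a data point (left path's
# left-limit value <= right path's value). Convex band feasibility uses the
# greatest convex minorant of the upper bounds; extreme endpoint values come
# from an inner bisection.

oracle_hull_vals <- function(x, y) {
  K <- length(x)
  if (K <= 2) return(y)
  hull <- c(1L, 2L)
  for (i in 3:K) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  vals <- numeric(K); seg <- 1L
  for (m in 1:K) {
    while (seg < length(hull) && x[hull[seg + 1]] < x[m]) seg <- seg + 1L
    a <- hull[seg]; b <- hull[min(seg + 1L, length(hull))]
    vals[m] <- if (a == b || m == a) y[a]
               else y[a] + (y[b] - y[a]) * (x[m] - x[a]) / (x[b] - x[a])
  }
  vals[hull] <- y[hull]
  vals
}

oracle_conv_feasible <- function(x, lo, hi, eps = 1e-9) {
  if (length(x) == 0) return(TRUE)
  all(oracle_hull_vals(x, hi) >= lo - eps)
}
oracle_conc_feasible <- function(x, lo, hi) {
  oracle_conv_feasible(-rev(x), -rev(hi), -rev(lo))
}
oracle_conv_min_end <- function(x, lo, hi) {
  K <- length(x)
  if (K == 0) return(-Inf)
  if (!oracle_conv_feasible(x, lo, hi)) return(Inf)
  a <- lo[K]; b <- oracle_hull_vals(x, hi)[K]
  for (it in 1:50) {
    v <- (a + b) / 2
    lo2 <- lo; hi2 <- hi; lo2[K] <- v; hi2[K] <- v
    if (oracle_conv_feasible(x, lo2, hi2)) b <- v else a <- v
  }
  b
}
oracle_conc_max_start <- function(x, lo, hi) {
  -oracle_conv_min_end(-rev(x), -rev(hi), -rev(lo))
}

dip_oracle <- function(x) {
  x <- sort(x)
  u <- unique(x)
  K <- length(u); n <- length(x)
  if (K == 1) return(0.5 / n)
  cc <- cumsum(tabulate(match(x, u)))
  c0 <- c(0, cc[-K])
  feasible <- function(T) {
    lo <- pmax(cc - T, 0); hi <- pmin(c0 + T, n)
    for (k in 1:K) {  # shared-point mode
      iL <- 1:k; iR <- k:K
      if (!oracle_conv_feasible(u[iL], lo[iL], hi[iL])) next
      if (!oracle_conc_feasible(u[iR], lo[iR], hi[iR])) next
      A <- oracle_conv_min_end(u[iL], lo[iL], hi[iL])
      D <- oracle_conc_max_start(u[iR], lo[iR], hi[iR])
      if (A <= D + 1e-7) return(TRUE)
    }
    for (k in 1:K) {  # atom-at-mode
      xl <- c(u[seq_len(k - 1)], u[k])
      lol <- c(lo[seq_len(k - 1)], max(0, c0[k] - T))
      hil <- c(hi[seq_len(k - 1)], min(n, c0[k] + T))
      if (!oracle_conv_feasible(xl, lol, hil)) next
      xr <- c(u[k], if (k < K) u[(k + 1):K])
      lor <- c(max(0, cc[k] - T), if (k < K) lo[(k + 1):K])
      hir <- c(min(n, cc[k] + T), if (k < K) hi[(k + 1):K])
      if (!oracle_conc_feasible(xr, lor, hir)) next
      A <- oracle_conv_min_end(xl, lol, hil)
      D <- oracle_conc_max_start(xr, lor, hir)
      if (A <= D + 1e-7) return(TRUE)
    }
    FALSE
  }
  a <- 0; b <- n / 2
  for (it in 1:50) {
    mid <- (a + b) / 2
    if (feasible(mid)) b <- mid else a <- mid
  }
  max(b / n, 0.5 / n)
}

# ---- event-by-event gating oracle ------------------------------------------
gate_oracle <- function(events, chl_thr, fsc_thr) {
  ns <- nc <- nd <- 0L
  for (i in seq_len(nrow(events))) {
    if (events$chl_fluor[i] > chl_thr) ns <- ns + 1L
    else if (events$fsc[i] > fsc_thr) nc <- nc + 1L
    else nd <- nd + 1L
  }
  list(n_symbiont = ns, n_coral = nc, n_debris = nd, load = ns / (ns + nc))
}

# ---- one-at-a-time exceedance oracle ---------------------------------------
exceed_oracle <- function(temps, threshold) {
  n <- 0L
  for (t in temps) if (t > threshold) n <- n + 1L
  n
}

# ---- Spearman S via explicit rank vectors ----------------------------------
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  S <- 0
  for (i in seq_along(x)) S <- S + (rx[i] - ry[i])^2
  list(S = S, rho = suppressWarnings(stats::cor(rx, ry, method = "pearson")))
}

# ---- OLS via normal equations ----------------------------------------------
ols_oracle <- function(y, X) {
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  res <- y - Xd %*% beta
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = drop(beta), r_squared = r2)
}

# ---- one-way ANOVA by hand decomposition -----------------------------------
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  grand <- mean(all_v)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1
  dfw <- length(all_v) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# ---- minimal GeoJSON (RFC 7946) structure validator ------------------------
validate_geojson <- function(gj) {
  ok <- is.list(gj) && identical(gj$type, "FeatureCollection") && is.list(gj$features)
  if (!ok) return(FALSE)
  for (f in gj$features) {
    if (!identical(f$type, "Feature")) return(FALSE)
    g <- f$geometry
    if (!identical(g$type, "Point")) return(FALSE)
    if (!is.numeric(g$coordinates) || length(g$coordinates) != 2) return(FALSE)
    if (abs(g$coordinates[1]) > 180 || abs(g$coordinates[2]) > 90) return(FALSE)
    if (!is.list(f$properties)) return(FALSE)
  }
  TRUE
}
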