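# Conditional Granger causality via vector autoregression.

# Stacked lag design for a VAR(q): response (T-q) x N, design with
# intercept (T-q) x (1 + N q).
var_design <- function(z, q) {
  N <- nrow(z)
  T <- ncol(z)
  Y <- t(z[, (q + 1):T, drop = FALSE])
  X <- matrix(0, T - q, N * q)
  for (l in seq_len(q)) {
    X[, ((l - 1) * N + 1):(l * N)] <- t(z[, (q + 1 - l):(T - l),
                                          drop = FALSE])
  }
  list(Y = Y, X = cbind(1, X))
}

# AIC-selected VAR order (multivariate Gaussian AIC; ties toward the
# smaller order).
var_select_order <- function(z, max_order) {
  N <- nrow(z)
  best <- 1L
  best_aic <- Inf
  for (q in seq_len(max_order)) {
    d <- var_design(z, q)
    Teff <- nrow(d$Y)
    B <- qr.solve(d$X, d$Y)
    E <- d$Y - d$X %*% B
    Sig <- crossprod(E) / Teff
    ld <- determinant(Sig, logarithm = TRUE)$modulus[1]
    aic <- Teff * ld + 2 * q * N * N
    if (aic < best_aic - 1e-9) {
      best_aic <- aic
      best <- q
    }
  }
  best
}

#' Conditional Granger causality
#'
#' Fits a vector autoregression of order selected by AIC (up to
#' `max_order`, ties broken toward the smaller order) by ordinary least
#' squares, then for each ordered pair computes the conditional
#' G-causality from source `j` to sink `i`:
#' `F[i, j] = log(RSS_reduced / RSS_full)` where the reduced model for
#' node `i` omits all lags of node `j` while keeping every other node's
#' lags (the conditioning).  Under the null of zero causality the
#' sample-size-scaled estimator `T_eff * F` is asymptotically
#' chi-squared with degrees of freedom equal to the selected order;
#' p-values are its upper tail, uncorrected for multiple comparisons.
#' The diagonal is undefined: `F = 0`, `p = 1`.
#'
#' @param z a [dcov_ts()]; `T` should be much larger than
#'   `N * max_order`.
#' @param max_order maximum VAR order considered (default 10).
#' @param cond_limit reject regressions whose design condition number
#'   exceeds this bound.
#' @return list with `F` (a directed [dcov_fc()], method `"cgranger"`),
#'   `p_values` (N x N matrix), and `order` (selected VAR order).
#' @export
conditional_granger <- function(z, max_order = 10, cond_limit = 1e10) {
  stopifnot(inherits(z, "dcov_ts"))
  N <- nrow(z)
  if (ncol(z) < 3 * N * max_order) {
    stop("time series too short for N = ", N, ", max_order = ", max_order)
  }
  zm <- ts_values(z)
  zm <- zm - rowMeans(zm)
  q <- var_select_order(zm, max_order)
  d <- var_design(zm, q)
  Teff <- nrow(d$Y)
  qrX <- qr(d$X)
  Rd <- abs(diag(qr.R(qrX)))
  if (min(Rd) == 0 || max(Rd) / min(Rd) > cond_limit) {
    stop("ill-conditioned VAR regression (condition estimate ",
         signif(max(Rd) / max(min(Rd), .Machine$double.xmin), 3), ")")
  }
  rss_full <- colSums((d$Y - d$X %*% qr.coef(qrX, d$Y))^2)
  Fm <- matrix(0, N, N)
  P <- matrix(1, N, N)
  for (j in seq_len(N)) {
    drop_cols <- 1 + (0:(q - 1)) * N + j
    Xr <- d$X[, -drop_cols, drop = FALSE]
    rss_red <- colSums((d$Y - Xr %*% qr.solve(Xr, d$Y))^2)
    for (i in seq_len(N)) {
      if (i == j) next
      Fm[i, j] <- max(log(rss_red[i] / rss_full[i]), 0)
      P[i, j] <- pchisq(Teff * Fm[i, j], df = q, lower.tail = FALSE)
    }
  }
  labels <- ts_labels(z)
  dimnames(P) <- list(labels, labels)
  list(F = dcov_fc(Fm, "cgranger", labels = labels,
                   diagnostics = list(order = q, df = q, T_eff = Teff)),
       p_values = P, order = q)
}
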