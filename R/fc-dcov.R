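# Differential-covariance estimators: raw, partialled, sparse-latent.

# Derivative and signal aligned on the same (trimmed) support.
dcov_parts <- function(z) {
  dz <- numerical_derivative(z, 1)
  T <- ncol(z)
  zt <- ts_values(z)[, 2:(T - 1), drop = FALSE]
  list(dz = ts_values(dz), z = zt)
}

#' Differential covariance (raw)
#'
#' `dcov_c[i, j] = cov(dz_i, z_j)`: sample covariance (means removed,
#' divisor `T - 1`) between the numerical derivative of the sink trace
#' `i` and the source trace `j`, both restricted to the derivative's
#' trimmed support.  Directed; row = sink, column = source.  For data
#' from a stationary linear system the matrix is approximately
#' antisymmetric (see [antisymmetry_index()]).
#'
#' @param z a [dcov_ts()] with at least 5 samples.
#' @return a directed [dcov_fc()] with method `"dcov_c"`.
#' @export
differential_covariance <- function(z) {
  stopifnot(inherits(z, "dcov_ts"))
  if (ncol(z) < 5) stop("need at least 5 samples")
  parts <- dcov_parts(z)
  dc <- cov(t(parts$dz), t(parts$z))
  dcov_fc(dc, "dcov_c", labels = ts_labels(z))
}

#' Partial differential covariance
#'
#' Removes confounder and chain effects from [differential_covariance()]
#' by partialling on all other nodes: for each ordered pair `(i, j)`
#' with conditioning set `K` (all nodes except `i` and `j`),
#' `dcov_p[i, j] = dcov_c[i, j] - Cov[j, K] Cov[K, K]^-1 dcov_c[i, K]^T`.
#' With `N = 2` the conditioning set is empty and the result equals the
#' raw differential covariance.  A ridge jitter of
#' `1e-8 * mean(diag(Cov))` is added to `Cov[K, K]` before solving (the
#' system is solved, never explicitly inverted) to guard against
#' collinear traces.
#'
#' @param z a [dcov_ts()] with `N >= 2` nodes.
#' @return a directed [dcov_fc()] with method `"dcov_p"`.
#' @export
partial_differential_covariance <- function(z) {
  stopifnot(inherits(z, "dcov_ts"))
  n <- nrow(z)
  if (n < 2) stop("need at least 2 nodes")
  parts <- dcov_parts(z)
  dc <- cov(t(parts$dz), t(parts$z))
  if (n == 2) return(dcov_fc(dc, "dcov_p", labels = ts_labels(z)))
  C <- cov(t(parts$z))
  jitter <- 1e-8 * mean(diag(C))
  dp <- dc
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      K <- setdiff(seq_len(n), c(i, j))
      CKK <- C[K, K, drop = FALSE]
      diag(CKK) <- diag(CKK) + jitter
      dp[i, j] <- dc[i, j] -
        drop(C[j, K, drop = FALSE] %*% solve(CKK, dc[i, K]))
    }
  }
  dcov_fc(dp, "dcov_p", labels = ts_labels(z))
}

#' Sparse + low-rank split of a connectivity matrix
#'
#' Decomposes a (partial differential covariance) matrix into a sparse
#' part `ds` — direct coupling between observed nodes — and a low-rank
#' part `L` — residual effects of unobserved common inputs — by solving
#'
#' `min ||ds||_1 + alpha ||L||_*  subject to  ds + L = dp`
#'
#' with an inexact augmented-Lagrange-multiplier method (singular-value
#' shrinkage for `L`, soft-thresholding for `ds`).  The nuclear norm
#' `||L||_*` generalizes the trace penalty to non-symmetric input (they
#' coincide for positive semidefinite `L`).  The default penalty ratio
#' `alpha = sqrt(N)` places the split at the exact-recovery calibration
#' of robust-PCA theory for this parametrization; `1/sqrt(N)` and `1/N`
#' can be supplied instead.
#'
#' @param dp a [dcov_fc()] (typically method `"dcov_p"`) or square
#'   numeric matrix.
#' @param alpha positive penalty ratio; default `sqrt(N)`.
#' @param tol convergence tolerance on the constraint residual
#'   `||ds + L - dp||_F`, relative to `max(1, ||dp||_F)`.
#' @param max_iter iteration cap; if reached, the best iterate is
#'   returned with `converged = FALSE` and a warning.
#' @return list with components `ds` (a `dcov_fc`, method `"dcov_s"`),
#'   `L` (a `dcov_fc`, method `"latent"`), `iterations`, `converged`
#'   and `residual`.
#' @export
sparse_latent_split <- function(dp, alpha = NULL, tol = 1e-7,
                                max_iter = 500) {
  labels <- if (inherits(dp, "dcov_fc")) rownames(dp) else NULL
  D <- if (inherits(dp, "dcov_fc")) fc_values(dp) else as.matrix(dp)
  if (any(!is.finite(D))) stop("input must be finite")
  n <- nrow(D)
  if (is.null(alpha)) alpha <- sqrt(n)
  if (alpha <= 0) stop("alpha must be positive")
  lam <- 1 / alpha  # weight of the L1 term relative to the nuclear term
  normD <- frob(D)
  if (normD == 0) {
    Z <- matrix(0, n, n)
    return(list(ds = dcov_fc(Z, "dcov_s", labels = labels),
                L = dcov_fc(Z, "latent", labels = labels),
                iterations = 0L, converged = TRUE, residual = 0))
  }
  spec <- svd(D, nu = 0, nv = 0)$d[1]
  Y <- D / max(spec, max(abs(D)) / lam)
  S <- matrix(0, n, n)
  mu <- 1.25 / spec
  rho <- 1.5
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    sv <- svd(D - S + Y / mu)
    dshr <- pmax(sv$d - 1 / mu, 0)
    L <- sv$u %*% (dshr * t(sv$v))
    S <- soft_threshold(D - L + Y / mu, lam / mu)
    R <- D - S - L
    resid <- frob(R)
    Y <- Y + mu * R
    mu <- mu * rho
    if (resid < tol * max(1, normD)) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  if (!converged) {
    warning("sparse-latent split did not converge in ", max_iter,
            " iterations (residual ", signif(resid, 3), ")")
  }
  diag_info <- list(iterations = it, converged = converged,
                    residual = resid, alpha = alpha)
  list(ds = dcov_fc(S, "dcov_s", labels = labels, diagnostics = diag_info),
       L = dcov_fc(L, "latent", labels = labels),
       iterations = it, converged = converged, residual = resid)
}
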