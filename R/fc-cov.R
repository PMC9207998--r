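# Connectivity-matrix container and covariance-family estimators.

fc_methods_known <- c("cov", "pcov", "l1reg", "l2reg", "cgranger",
                      "dcov_c", "dcov_p", "dcov_s", "latent")
fc_directed_methods <- c("cgranger", "dcov_c", "dcov_p", "dcov_s", "latent")

#' Connectivity matrix container
#'
#' An N x N numeric matrix with a method tag and a directionality flag.
#' Directed methods use the convention row = sink, column = source:
#' entry `(i, j)` quantifies the influence of node `j` on node `i`.
#'
#' @param values N x N numeric matrix.
#' @param method estimator tag, one of `"cov"`, `"pcov"`, `"l1reg"`,
#'   `"l2reg"`, `"cgranger"`, `"dcov_c"`, `"dcov_p"`, `"dcov_s"`,
#'   `"latent"`.
#' @param labels node names.
#' @param diagnostics optional list of solver diagnostics.
#' @return a `dcov_fc` object.
#' @export
dcov_fc <- function(values, method, labels = NULL, diagnostics = NULL) {
  method <- match.arg(method, fc_methods_known)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("connectivity matrix must be square")
  if (any(!is.finite(values))) stop("connectivity matrix has non-finite entries")
  labels <- check_labels(labels %||% rownames(values), nrow(values))
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dcov_fc", "matrix", "array"),
            method = method, directed = method %in% fc_directed_methods,
            convention = "row = sink, column = source",
            diagnostics = diagnostics)
}

#' @export
print.dcov_fc <- function(x, ...) {
  cat(sprintf("<dcov_fc> %d x %d, method = %s, %s\n", nrow(x), ncol(x),
              fc_method(x),
              if (fc_directed(x)) "directed (row = sink, column = source)"
              else "undirected"))
  invisible(x)
}

fc_method <- function(fc) attr(fc, "method")
fc_directed <- function(fc) attr(fc, "directed")

fc_values <- function(fc) {
  m <- unclass(fc)
  for (a in c("method", "directed", "convention", "diagnostics")) {
    attr(m, a) <- NULL
  }
  m
}

#' Relative antisymmetry of a connectivity matrix
#'
#' `||M + M^T||_F / ||M||_F`; near zero for an antisymmetric matrix.
#' Differential covariance of a stationary linear system is
#' approximately antisymmetric, so this index is reported as a
#' diagnostic rather than asserted.
#'
#' @param fc a [dcov_fc()].
#' @return a scalar in `[0, 2]`.
#' @export
antisymmetry_index <- function(fc) {
  m <- fc_values(fc)
  frob(m + t(m)) / frob(m)
}

#' Sample covariance connectivity
#'
#' Unbiased sample covariance (divisor `T - 1`) between node traces.
#'
#' @param z a [dcov_ts()].
#' @return a symmetric [dcov_fc()] with method `"cov"`.
#' @export
sample_covariance <- function(z) {
  stopifnot(inherits(z, "dcov_ts"))
  dcov_fc(cov(t(ts_values(z))), "cov", labels = ts_labels(z))
}

#' Partial covariance (precision matrix) connectivity
#'
#' Inverse of the sample covariance matrix.  When the covariance is
#' rank-deficient the Moore-Penrose pseudo-inverse is used and a warning
#' is emitted.
#'
#' @param z a [dcov_ts()].
#' @param tol relative eigenvalue tolerance for rank detection.
#' @return a symmetric [dcov_fc()] with method `"pcov"`.
#' @export
partial_covariance <- function(z, tol = 1e-10) {
  stopifnot(inherits(z, "dcov_ts"))
  C <- cov(t(ts_values(z)))
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  if (!all(keep)) {
    warning("covariance is rank-deficient (rank ", sum(keep), " < ",
            nrow(C), "); using Moore-Penrose pseudo-inverse")
  }
  P <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  P <- (P + t(P)) / 2
  dcov_fc(P, "pcov", labels = ts_labels(z))
}

#' Regularized partial covariance connectivity
#'
#' `kind = "L2"` computes the ridge precision
#' `(Cov + penalty * mean(diag(Cov)) * I)^-1` (default `penalty = 0.1`).
#' `kind = "L1"` computes a sparse precision estimate by nodewise lasso
#' regression (each node regressed on all others with an L1 penalty,
#' coefficients assembled into a symmetrised precision matrix); default
#' `penalty = 10` on the log-likelihood penalty scale, mapped internally
#' to the per-observation lasso scale.  At `penalty = 0` both kinds
#' reduce to [partial_covariance()].
#'
#' @param z a [dcov_ts()].
#' @param kind `"L1"` or `"L2"`.
#' @param penalty nonnegative penalty; defaults are method-specific
#'   (`10` for L1, `0.1` for L2) when `NULL`.
#' @return a symmetric [dcov_fc()] with method `"l1reg"` or `"l2reg"`.
#' @export
regularized_partial_covariance <- function(z, kind = c("L1", "L2"),
                                           penalty = NULL) {
  stopifnot(inherits(z, "dcov_ts"))
  kind <- match.arg(kind)
  if (is.null(penalty)) penalty <- if (kind == "L1") 10 else 0.1
  if (penalty < 0) stop("penalty must be >= 0")
  X <- t(ts_values(z))
  n <- ncol(X)
  if (kind == "L2") {
    C <- cov(X)
    P <- solve(C + diag(penalty * mean(diag(C)), n))
    return(dcov_fc((P + t(P)) / 2, "l2reg", labels = ts_labels(z)))
  }
  if (penalty == 0) {
    P <- fc_values(partial_covariance(z))
    return(dcov_fc(P, "l1reg", labels = ts_labels(z)))
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Teff <- nrow(Xc)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    fit <- glmnet::glmnet(Xc[, -i, drop = FALSE], Xc[, i],
                          lambda = penalty / Teff, standardize = FALSE,
                          intercept = FALSE)
    beta <- as.numeric(fit$beta)
    resid <- Xc[, i] - Xc[, -i, drop = FALSE] %*% beta
    s2 <- sum(resid^2) / (Teff - 1)
    P[i, i] <- 1 / s2
    P[i, -i] <- -beta / s2
  }
  P <- (P + t(P)) / 2
  dcov_fc(P, "l1reg", labels = ts_labels(z))
}
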