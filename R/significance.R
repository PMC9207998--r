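# Autoregressive-bootstrap edge significance and binarization.

#' Estimate a connectivity matrix by name
#'
#' Dispatcher used by the bootstrap and the pipeline so that empirical
#' and surrogate data go through the identical estimator.
#'
#' @param z a [dcov_ts()].
#' @param method one of `"cov"`, `"pcov"`, `"l1reg"`, `"l2reg"`,
#'   `"cgranger"`, `"dcov_c"`, `"dcov_p"`, `"dcov_s"`.
#' @param ... passed to the underlying estimator (e.g. `penalty`,
#'   `alpha`, `max_order`).
#' @return a [dcov_fc()].
#' @export
estimate_fc <- function(z, method, ...) {
  method <- match.arg(method, setdiff(fc_methods_known, "latent"))
  switch(method,
    cov = sample_covariance(z),
    pcov = partial_covariance(z),
    l1reg = regularized_partial_covariance(z, kind = "L1", ...),
    l2reg = regularized_partial_covariance(z, kind = "L2", ...),
    cgranger = conditional_granger(z, ...)$F,
    dcov_c = differential_covariance(z),
    dcov_p = partial_differential_covariance(z),
    dcov_s = sparse_latent_split(partial_differential_covariance(z), ...)$ds)
}

# ---- AR model fitting -------------------------------------------------

#' Fit node-wise autoregressive models with an incremental BIC rule
#'
#' Each node trace gets its own AR(q) model fitted by conditional least
#' squares on a common support (the first `max_order` samples are
#' conditioned on for every candidate order, making BIC values
#' comparable).  Starting from order 0 (white noise), a higher order is
#' accepted only if it lowers BIC by more than `bic_margin` (default 2);
#' the search stops at the first rejection.  A fit whose companion
#' matrix is not stable is rejected and the search falls back to the
#' previous (stationary) order.
#'
#' @param ts a [dcov_ts()] with `T > 3 * max_order`.
#' @param max_order largest order considered.
#' @param bic_margin required BIC improvement for accepting an order.
#' @return list of `ar_model` objects (fields `order`, `coefficients`,
#'   `noise_sd`, `node_label`, `mean`), one per node.
#' @export
fit_ar <- function(ts, max_order = 10, bic_margin = 2) {
  stopifnot(inherits(ts, "dcov_ts"))
  T <- ncol(ts)
  if (T <= 3 * max_order) stop("need T > 3 * max_order samples")
  lapply(seq_len(nrow(ts)), function(i) {
    fit_ar_node(ts_values(ts)[i, ], max_order, bic_margin,
                ts_labels(ts)[i])
  })
}

ar_stationary <- function(coefficients) {
  q <- length(coefficients)
  if (q == 0) return(TRUE)
  comp <- matrix(0, q, q)
  comp[1, ] <- coefficients
  if (q > 1) comp[cbind(2:q, 1:(q - 1))] <- 1
  max(Mod(eigen(comp, only.values = TRUE)$values)) < 1 - 1e-8
}

fit_ar_node <- function(x, max_order, bic_margin, label) {
  mu <- mean(x)
  x <- x - mu
  T <- length(x)
  y0 <- x[(max_order + 1):T]
  Teff <- length(y0)
  best <- list(order = 0L, coefficients = numeric(0),
               noise_sd = sqrt(sum(y0^2) / Teff), node_label = label,
               mean = mu)
  best_bic <- Teff * log(sum(y0^2) / Teff)
  X <- NULL
  for (q in seq_len(max_order)) {
    X <- cbind(X, x[(max_order + 1 - q):(T - q)])
    b <- qr.solve(X, y0)
    rss <- sum((y0 - X %*% b)^2)
    bic <- Teff * log(rss / Teff) + q * log(Teff)
    if (bic < best_bic - bic_margin) {
      if (!ar_stationary(b)) break  # keep previous stationary order
      best <- list(order = q, coefficients = as.numeric(b),
                   noise_sd = sqrt(rss / Teff), node_label = label,
                   mean = mu)
      best_bic <- bic
    } else {
      break
    }
  }
  structure(best, class = "ar_model")
}

#' @export
print.ar_model <- function(x, ...) {
  cat(sprintf("<ar_model> %s: AR(%d), noise sd %.4g\n", x$node_label,
              x$order, x$noise_sd))
  invisible(x)
}

# ---- Null surrogates --------------------------------------------------

# One surrogate draw of all nodes (independently), T samples each.
draw_null_matrix <- function(models, T, burn_in) {
  t(vapply(models, function(m) {
    if (m$order == 0) {
      m$mean + rnorm(T, sd = m$noise_sd)
    } else {
      m$mean + as.numeric(arima.sim(list(ar = m$coefficients), n = T,
                                    sd = m$noise_sd, n.start = burn_in))
    }
  }, numeric(T)))
}

#' Generate AR-bootstrap null time series
#'
#' Draws `n_surrogates` null datasets; every node is simulated
#' independently from its own fitted AR model (preserving each node's
#' power spectrum while destroying all cross-node dependence), with
#' `burn_in` initial samples discarded.
#'
#' @param models list of `ar_model` objects from [fit_ar()].
#' @param T samples per surrogate.
#' @param n_surrogates number of surrogate datasets (the reference
#'   procedure uses 1000).
#' @param seed integer seed; the surrogate set is a pure function of
#'   `(models, T, n_surrogates, seed)`.
#' @param dt,burn_in sampling interval attached to the surrogates and
#'   burn-in length.
#' @return list of [dcov_ts()] objects.
#' @export
generate_null <- function(models, T, n_surrogates = 1000, seed = 1,
                          dt = 1, burn_in = 500) {
  labels <- vapply(models, `[[`, character(1), "node_label")
  with_seed(seed, {
    lapply(seq_len(n_surrogates), function(s) {
      dcov_ts(draw_null_matrix(models, T, burn_in), dt = dt,
              kind = "reconstructed", labels = labels)
    })
  })
}

# ---- Edge p-values ----------------------------------------------------

new_edge_significance <- function(empirical, null_mean, null_sd, p_values,
                                  n_surrogates) {
  structure(list(empirical = empirical, null_mean = null_mean,
                 null_sd = null_sd, p_values = p_values,
                 n_surrogates = n_surrogates,
                 method = fc_method(empirical),
                 directed = fc_directed(empirical)),
            class = "edge_significance")
}

#' @export
print.edge_significance <- function(x, ...) {
  cat(sprintf(
    "<edge_significance> %d x %d edges, method = %s, %d surrogates\n",
    nrow(x$p_values), ncol(x$p_values), x$method, x$n_surrogates))
  invisible(x)
}

#' Gaussian edge p-values against a surrogate null ensemble
#'
#' Fits a Gaussian to each edge's null distribution (per-edge mean and
#' sd over the surrogate connectivity matrices) and computes two-sided
#' p-values `2 * pnorm(-|x - mu| / sigma)` for the empirical values.
#' No multiple-comparison correction is applied.  Edges with zero null
#' variance get `p = 0` if the empirical value differs from the null
#' mean and `p = 1` otherwise, with a warning.
#'
#' @param empirical a [dcov_fc()].
#' @param null_fcs list of [dcov_fc()] with the same method tag (at
#'   least 50).
#' @param p_mode `"gaussian"` (default) fits a Gaussian per edge;
#'   `"empirical"` uses the two-sided surrogate quantile
#'   `(1 + #(|v - mu| >= |x - mu|)) / (n + 1)`, which is
#'   distribution-free but cannot resolve p below `1/(n + 1)`.
#' @return an `edge_significance` object with fields `empirical`,
#'   `null_mean`, `null_sd`, `p_values`, `n_surrogates`, `method`,
#'   `directed`.
#' @export
edge_pvalues <- function(empirical, null_fcs,
                         p_mode = c("gaussian", "empirical")) {
  stopifnot(inherits(empirical, "dcov_fc"))
  p_mode <- match.arg(p_mode)
  if (length(null_fcs) < 50) stop("need at least 50 null matrices")
  same <- vapply(null_fcs, function(f) fc_method(f) == fc_method(empirical),
                 logical(1))
  if (!all(same)) stop("null matrices must share the empirical method tag")
  arr <- vapply(null_fcs, fc_values,
                matrix(0, nrow(empirical), ncol(empirical)))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), sd)
  emp <- fc_values(empirical)
  if (p_mode == "empirical") {
    ns <- length(null_fcs)
    exceed <- apply(sweep(abs(sweep(arr, c(1, 2), mu)), c(1, 2),
                          abs(emp - mu), ">="), c(1, 2), sum)
    p <- (1 + exceed) / (ns + 1)
  } else {
    p <- matrix(1, nrow(emp), ncol(emp))
    pos <- sdv > 0
    p[pos] <- 2 * pnorm(-abs(emp[pos] - mu[pos]) / sdv[pos])
    if (any(!pos)) {
      degenerate <- !pos & (emp != mu)
      p[degenerate] <- 0
      warning(sum(!pos), " edge(s) had zero null variance")
    }
  }
  dimnames(p) <- dimnames(emp)
  new_edge_significance(empirical, mu, sdv, p, length(null_fcs))
}

#' Full AR-bootstrap significance pipeline
#'
#' Fits per-node AR models to `z`, generates independent surrogate
#' datasets, re-estimates the connectivity on each (streaming, one
#' surrogate at a time) and returns Gaussian edge p-values.  The whole
#' procedure is deterministic given `(z, method, n_surrogates, seed)`.
#'
#' @param z a [dcov_ts()] — the same matrix the estimator consumes.
#' @param method connectivity estimator tag (see [estimate_fc()]).
#' @param n_surrogates surrogate count (default 1000).
#' @param seed integer seed.
#' @param max_order AR order cap for [fit_ar()].
#' @param burn_in surrogate burn-in samples.
#' @param p_mode `"gaussian"` or `"empirical"` (see [edge_pvalues()]).
#' @param ... passed to [estimate_fc()].
#' @return an `edge_significance` object.
#' @export
ar_bootstrap_significance <- function(z, method, n_surrogates = 1000,
                                      seed = 1, max_order = 10,
                                      burn_in = 500,
                                      p_mode = c("gaussian", "empirical"),
                                      ...) {
  stopifnot(inherits(z, "dcov_ts"))
  p_mode <- match.arg(p_mode)
  empirical <- estimate_fc(z, method, ...)
  models <- fit_ar(z, max_order = max_order)
  labels <- ts_labels(z)
  T <- ncol(z)
  n <- nrow(z)
  emp <- fc_values(empirical)
  sum1 <- matrix(0, n, n)
  sum2 <- matrix(0, n, n)
  keep <- if (p_mode == "empirical") {
    array(0, c(n, n, n_surrogates))
  }
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      zs <- dcov_ts(draw_null_matrix(models, T, burn_in), dt = ts_dt(z),
                    kind = ts_kind(z), labels = labels)
      v <- fc_values(estimate_fc(zs, method, ...))
      sum1 <- sum1 + v
      sum2 <- sum2 + v^2
      if (!is.null(keep)) keep[, , s] <- v
    }
  })
  mu <- sum1 / n_surrogates
  varv <- pmax(sum2 / n_surrogates - mu^2, 0) *
    n_surrogates / (n_surrogates - 1)
  sdv <- sqrt(varv)
  if (p_mode == "empirical") {
    exceed <- apply(sweep(abs(sweep(keep, c(1, 2), mu)), c(1, 2),
                          abs(emp - mu), ">="), c(1, 2), sum)
    p <- (1 + exceed) / (n_surrogates + 1)
  } else {
    p <- matrix(1, n, n)
    pos <- sdv > 0
    p[pos] <- 2 * pnorm(-abs(emp[pos] - mu[pos]) / sdv[pos])
    if (any(!pos)) {
      degenerate <- !pos & (emp != mu)
      p[degenerate] <- 0
      warning(sum(!pos), " edge(s) had zero null variance")
    }
  }
  dimnames(p) <- dimnames(emp)
  new_edge_significance(empirical, mu, sdv, p, n_surrogates)
}

# ---- Binarization -----------------------------------------------------

#' Binary network container
#'
#' Logical adjacency matrix with a directedness flag.  Two position
#' conventions exist: `"source"` (the graph-theory convention,
#' `a[i, j] = TRUE` means an edge from `i` to `j`; default for directly
#' constructed networks) and `"sink"` (the connectivity convention of
#' this package, rows are sinks; produced by [binarize()]).  Topology
#' and structure-matching code normalises internally, so the two are
#' interchangeable for symmetric networks.
#'
#' @param adjacency logical (or 0/1) square matrix.
#' @param directed logical; if `FALSE`, `adjacency` must be symmetric.
#' @param threshold significance level that produced the network, if
#'   any.
#' @param convention `"source"` or `"sink"` (see above).
#' @return a `binary_network` object.
#' @export
binary_network <- function(adjacency, directed = TRUE, threshold = NA_real_,
                           convention = c("source", "sink")) {
  convention <- match.arg(convention)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  mode(adjacency) <- "logical"
  if (anyNA(adjacency)) stop("adjacency must not contain NA")
  diag(adjacency) <- FALSE
  if (!directed && !isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("undirected adjacency must be symmetric")
  }
  labels <- check_labels(rownames(adjacency), nrow(adjacency))
  dimnames(adjacency) <- list(labels, labels)
  structure(list(adjacency = adjacency, directed = directed,
                 threshold = threshold, convention = convention),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges, %s%s\n",
              nrow(x$adjacency), sum(x$adjacency),
              if (x$directed) "directed" else "undirected",
              if (is.na(x$threshold)) "" else
                sprintf(", threshold %g", x$threshold)))
  invisible(x)
}

# Adjacency in the requested convention (transpose only matters for
# directed networks).
adjacency_as <- function(net, convention = c("source", "sink")) {
  convention <- match.arg(convention)
  a <- net$adjacency
  if (net$directed && net$convention != convention) t(a) else a
}

#' Binarize an edge-significance result
#'
#' Edges with `p < threshold` are kept; the diagonal is always FALSE.
#' The adjacency stays in the connectivity convention (row = sink), and
#' undirected methods yield a symmetrised adjacency (an undirected edge
#' is significant if either ordered pair is).
#'
#' @param sig an `edge_significance` object.
#' @param threshold significance level in (0, 1].
#' @return a `binary_network`.
#' @export
binarize <- function(sig, threshold = 0.05) {
  stopifnot(inherits(sig, "edge_significance"))
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  adj <- sig$p_values < threshold
  diag(adj) <- FALSE
  if (!sig$directed) adj <- adj | t(adj)
  binary_network(adj, directed = sig$directed, threshold = threshold,
                 convention = "sink")
}

#' Keep the k most significant edges of two results
#'
#' Sparsity-matched comparison: both networks retain exactly the `k`
#' most significant off-diagonal positions (smallest p; ties broken by
#' larger `|empirical|`, then row-major position), so that methods are
#' compared at identical sparsity regardless of how many edges each
#' deems significant.  The returned masks have position (directed)
#' semantics even for undirected estimators, because they are meant to
#' select exactly `k` structural-connectivity entries downstream.
#'
#' @param sig_a,sig_b `edge_significance` objects over the same nodes.
#' @param k number of edges to keep, `0 <= k <= N (N - 1)`.
#' @return list of two `binary_network` objects with exactly `k` edges
#'   each.
#' @export
match_sparsity <- function(sig_a, sig_b, k) {
  top_k <- function(sig) {
    p <- sig$p_values
    n <- nrow(p)
    if (k > n * (n - 1)) stop("k exceeds the number of off-diagonal edges")
    idx <- which(off_diag(p))
    ord <- order(p[idx], -abs(fc_values(sig$empirical))[idx], idx)
    adj <- matrix(FALSE, n, n, dimnames = dimnames(p))
    adj[idx[ord[seq_len(k)]]] <- TRUE
    binary_network(adj, directed = TRUE, threshold = NA_real_,
                   convention = "sink")
  }
  list(top_k(sig_a), top_k(sig_b))
}
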