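#' Generate a sparse stable ground-truth network
#'
#' Draws a directed weight matrix `W` for the linear stochastic dynamics
#' `dV/dt = W V + noise`.  Entry `(i, j)` is the influence of node `j`
#' (source) on node `i` (sink).  Diagonal entries are set to
#' `-self_decay` (leak) and exactly `round(density * N * (N - 1))`
#' off-diagonal entries receive nonzero weights, drawn uniformly from
#' `[0.5, 1.5]` with random sign.  If the resulting system is not stable
#' (spectral abscissa >= 0) the off-diagonal weights are rescaled by 0.9
#' repeatedly; after `max_attempts` failures an error is raised.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param density fraction of nonzero off-diagonal entries in (0, 1].
#' @param self_decay positive self-decay rate placed on the diagonal.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @param max_attempts bound on stabilisation rescalings.
#' @return an object of class `ground_truth_network`: a list with
#'   `weights`, `labels`, `density`, `seed`.
#' @export
generate_network <- function(n_nodes, density, self_decay = 1, seed = 1,
                             max_attempts = 100) {
  if (n_nodes < 2) stop("n_nodes must be >= 2")
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  if (self_decay <= 0) stop("self_decay must be positive")
  n_edges <- round(density * n_nodes * (n_nodes - 1))
  W <- with_seed(seed, {
    W <- diag(-self_decay, n_nodes)
    if (n_edges > 0) {
      off <- which(off_diag(W))
      pos <- sample(off, n_edges)
      w0 <- runif(n_edges, 0.5, 1.5) * sample(c(-1, 1), n_edges, replace = TRUE)
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        W[pos] <- w0 * 0.9^(attempt - 1)
        if (max(Re(eigen(W, only.values = TRUE)$values)) < -0.01) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not stabilise network at density ", density,
             " after ", max_attempts, " rescaling attempts")
      }
    }
    W
  })
  labels <- default_labels(n_nodes)
  dimnames(W) <- list(labels, labels)
  structure(list(weights = W, labels = labels, density = density,
                 seed = seed),
            class = "ground_truth_network")
}

#' @export
print.ground_truth_network <- function(x, ...) {
  cat(sprintf("<ground_truth_network> %d nodes, %d directed edges, seed %d\n",
              length(x$labels), sum(x$weights[off_diag(x$weights)] != 0),
              x$seed))
  invisible(x)
}

#' Simulate linear stochastic neural dynamics
#'
#' Integrates `dV/dt = W V + sigma dW_t` by Euler-Maruyama at step `dt`
#' and discards the first 10% of samples as burn-in, returning `T`
#' stationary samples.  Aborts if any trajectory exceeds `bound` (a
#' divergence guard; the generated networks are stable by construction).
#'
#' @param net a [generate_network()] result.
#' @param T number of retained samples.
#' @param dt integration step in seconds; must satisfy the Euler
#'   stability condition for `net$weights`.
#' @param noise_sd standard deviation of the driving white noise.
#' @param seed integer seed.
#' @param bound divergence bound on `|V|`.
#' @return a [dcov_ts()] of kind `"neural"`.
#' @export
simulate_neural <- function(net, T, dt = 0.01, noise_sd = 1, seed = 1,
                            bound = 1e6) {
  stopifnot(inherits(net, "ground_truth_network"))
  W <- net$weights
  n <- nrow(W)
  A <- diag(n) + dt * W
  if (max(abs(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("Euler step unstable: reduce dt")
  }
  burn <- ceiling(0.1 * T)
  total <- T + burn
  V <- with_seed(seed, {
    E <- matrix(rnorm(n * total, sd = noise_sd * sqrt(dt)), n, total)
    V <- matrix(0, n, total)
    x <- numeric(n)
    for (t in seq_len(total)) {
      x <- A %*% x + E[, t]
      V[, t] <- x
    }
    V
  })
  if (any(abs(V) > bound)) stop("simulation diverged: |V| exceeded ", bound)
  dcov_ts(V[, (burn + 1):total, drop = FALSE], dt = dt, kind = "neural",
          labels = net$labels)
}
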