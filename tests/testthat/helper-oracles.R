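# Shared fixtures and independent brute-force oracles for the suite.
# Oracles deliberately use different algorithms than the implementation.

make_ts <- function(m, dt = 1, kind = "neural") {
  dcov_ts(as.matrix(m), dt = dt, kind = kind)
}

random_adjacency <- function(n, p = 0.3, directed = TRUE) {
  a <- matrix(runif(n * n) < p, n, n)
  diag(a) <- FALSE
  if (!directed) a <- a | t(a)
  a
}

# --- Floyd-Warshall all-pairs distances (oracle for BFS paths) --------
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# --- Triple-enumeration triangles + clustering (oracle) ---------------
# adj in source convention (a[i, j] = edge i -> j).
enum_triangles <- function(adj, directed) {
  n <- nrow(adj)
  a <- adj * 1
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        acc <- acc + if (directed) {
          (a[i, j] + a[j, i]) * (a[i, h] + a[h, i]) * (a[j, h] + a[h, j])
        } else {
          a[i, j] * a[i, h] * a[j, h]
        }
      }
    }
    t_i[i] <- acc / 2
  }
  t_i
}

enum_clustering <- function(adj, directed) {
  n <- nrow(adj)
  a <- adj * 1
  t_i <- enum_triangles(adj, directed)
  denom <- numeric(n)
  for (i in seq_len(n)) {
    if (directed) {
      ktot <- sum(a[i, ]) + sum(a[, i])
      denom[i] <- ktot * (ktot - 1) - 2 * sum(a[i, ] * a[, i])
    } else {
      k <- sum(a[i, ])
      denom[i] <- k * (k - 1)
    }
  }
  num <- if (directed) t_i else 2 * t_i
  frac <- ifelse(denom > 0, num / denom, 0)
  keep <- denom > 0
  list(clustering = mean(frac),
       transitivity = if (any(keep)) sum(num[keep]) / sum(denom[keep]) else 0)
}

# --- Edge-count modularity oracle -------------------------------------
enum_modularity <- function(adj, partition) {
  a <- which(adj, arr.ind = TRUE)
  if (nrow(a) == 0) return(0)
  mods <- sort(unique(partition))
  e <- matrix(0, length(mods), length(mods))
  for (r in seq_len(nrow(a))) {
    u <- match(partition[a[r, 1]], mods)
    v <- match(partition[a[r, 2]], mods)
    e[u, v] <- e[u, v] + 1
  }
  e <- e / nrow(a)
  sum(diag(e) - rowSums(e)^2)
}

# --- Per-pair residual-regression oracle for partial dCov -------------
# Regress z_j and dz_i on z_K (least squares with intercept) and take
# the sample covariance of the residuals.
dp_regression_oracle <- function(z_ts) {
  z <- unclass(z_ts)
  T <- ncol(z)
  dt <- attr(z_ts, "dt")
  dz <- (z[, 3:T, drop = FALSE] - z[, 1:(T - 2), drop = FALSE]) / (2 * dt)
  zt <- z[, 2:(T - 1), drop = FALSE]
  n <- nrow(z)
  dp <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K <- setdiff(seq_len(n), c(i, j))
      if (length(K) == 0 || i == j) {
        dp[i, j] <- cov(dz[i, ], zt[j, ])
        next
      }
      X <- cbind(1, t(zt[K, , drop = FALSE]))
      rj <- qr.resid(qr(X), zt[j, ])
      ri <- qr.resid(qr(X), dz[i, ])
      dp[i, j] <- cov(ri, rj)
    }
  }
  dp
}

# Band-limited neural input: OU smoothed with a Gaussian kernel, as a
# differentiable stand-in for population activity.
smooth_neural <- function(n, T, dt, seed, kernel_sd = 0.2) {
  set.seed(seed)
  half <- ceiling(3 * kernel_sd / dt)
  ker <- dnorm(seq(-half, half) * dt, sd = kernel_sd)
  ker <- ker / sum(ker)
  V <- matrix(0, n, T)
  for (i in seq_len(n)) {
    x <- numeric(T + 2 * half)
    for (t in 2:length(x)) {
      x[t] <- x[t - 1] - dt * x[t - 1] + sqrt(dt) * rnorm(1)
    }
    sm <- as.numeric(stats::filter(x, ker, sides = 2))
    V[i, ] <- sm[(half + 1):(half + T)]
  }
  stopifnot(!anyNA(V))
  dcov_ts(V, dt = dt, kind = "neural")
}

# Central differences matching the package's first-derivative stencil.
cd1 <- function(x, dt) (x[3:length(x)] - x[1:(length(x) - 2)]) / (2 * dt)

frob <- function(m) sqrt(sum(m^2))

# Strip all non-dim attributes from a matrix-like object.
bare <- function(x) {
  m <- unclass(x)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}
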