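# AR fitting, null surrogates, edge p-values, binarization.

test_that("BIC rule selects parsimonious AR orders", {
  # white noise: order 0 almost always
  ord0 <- vapply(1:60, function(s) {
    set.seed(s)
    fit_ar(make_ts(matrix(rnorm(2000), 1)))[[1]]$order
  }, numeric(1))
  expect_gte(mean(ord0 <= 1), 0.9)
  expect_gte(mean(ord0 == 0), 0.8)

  # AR(2) with coefficients (0.5, -0.3): order 2 and accurate coefficients
  rec <- vapply(1:30, function(s) {
    set.seed(s)
    x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), n = 10000))
    m <- fit_ar(make_ts(matrix(x, 1)))[[1]]
    c(m$order,
      if (m$order == 2) max(abs(m$coefficients - c(0.5, -0.3))) else NA)
  }, numeric(2))
  expect_gte(mean(rec[1, ] == 2), 0.8)
  expect_lt(max(rec[2, ], na.rm = TRUE), 0.05)
})

test_that("a fitted AR recursion reproduces its own noiseless extension", {
  set.seed(4)
  x <- as.numeric(arima.sim(list(ar = c(0.6, -0.2)), n = 5000))
  m <- fit_ar(make_ts(matrix(x, 1)))[[1]]
  q <- m$order
  expect_gte(q, 2)
  # run the recursion noiselessly from arbitrary initial values, then
  # check one-step predictions reproduce the series exactly
  y <- c(rnorm(q), numeric(50))
  for (t in (q + 1):length(y)) {
    y[t] <- sum(m$coefficients * y[t - seq_len(q)])
  }
  pred <- vapply((q + 1):length(y), function(t) {
    sum(m$coefficients * y[t - seq_len(q)])
  }, numeric(1))
  expect_equal(pred, y[(q + 1):length(y)], tolerance = 1e-12)
})

test_that("fit_ar validates input length", {
  expect_error(fit_ar(make_ts(matrix(rnorm(25), 1)), max_order = 10),
               "max_order")
})

test_that("null surrogates are independent, reproducible and spectrum-preserving", {
  models <- list(
    structure(list(order = 2L, coefficients = c(0.5, -0.3), noise_sd = 1,
                   node_label = "a", mean = 0), class = "ar_model"),
    structure(list(order = 0L, coefficients = numeric(0), noise_sd = 2,
                   node_label = "b", mean = 5), class = "ar_model"))

  s1 <- generate_null(models, T = 2000, n_surrogates = 3, seed = 7)
  s2 <- generate_null(models, T = 2000, n_surrogates = 3, seed = 7)
  expect_identical(s1, s2)
  expect_length(s1, 3)

  # lag-0 cross-correlation vanishes at the 1/sqrt(T) rate
  cc <- vapply(generate_null(models, T = 5000, n_surrogates = 20, seed = 8),
               function(z) cor(unclass(z)[1, ], unclass(z)[2, ]),
               numeric(1))
  expect_lt(mean(abs(cc)), 3 / sqrt(5000))

  # surrogate spectrum matches the AR(2) model spectrum (shape)
  surs <- generate_null(models, T = 4096, n_surrogates = 100, seed = 9)
  spec_avg <- NULL
  for (z in surs) {
    sp <- spec.pgram(unclass(z)[1, ], plot = FALSE, taper = 0)
    spec_avg <- if (is.null(spec_avg)) sp$spec else spec_avg + sp$spec
  }
  spec_avg <- spec_avg / length(surs)
  freq <- spec.pgram(unclass(surs[[1]])[1, ], plot = FALSE,
                     taper = 0)$freq
  theo <- 1 / Mod(1 - 0.5 * exp(-2i * pi * freq) +
                    0.3 * exp(-4i * pi * freq))^2
  rel <- sqrt(mean((spec_avg / mean(spec_avg) -
                      theo / mean(theo))^2)) /
    sqrt(mean((theo / mean(theo))^2))
  expect_lt(rel, 0.15)

  # mean level preserved for the order-0 node
  expect_equal(mean(unclass(surs[[1]])[2, ]), 5, tolerance = 0.3)
})

test_that("Gaussian edge p-values follow the closed form", {
  n <- 3
  set.seed(11)
  base <- matrix(rnorm(n * n), n, n)
  nulls <- lapply(1:60, function(s) {
    dcov_fc(base + matrix(rnorm(n * n, sd = 0.5), n, n), "dcov_p")
  })
  arr <- sapply(nulls, function(f) as.numeric(unclass(f)))
  mu <- matrix(rowMeans(arr), n, n)
  sdv <- matrix(apply(arr, 1, sd), n, n)

  # empirical equal to the null mean -> p = 1
  sig1 <- edge_pvalues(dcov_fc(mu, "dcov_p"), nulls)
  expect_true(all(sig1$p_values == 1))

  # empirical at mu + 1.959964 sd -> p = 0.05
  sig2 <- edge_pvalues(dcov_fc(mu + 1.959964 * sdv, "dcov_p"), nulls)
  expect_equal(as.numeric(sig2$p_values), rep(0.05, n * n),
               tolerance = 1e-6)

  # zero null variance -> degenerate p with warning
  const_nulls <- lapply(1:60, function(s) dcov_fc(matrix(1, 2, 2), "cov"))
  expect_warning(
    sig3 <- edge_pvalues(dcov_fc(matrix(c(1, 2, 1, 1), 2, 2), "cov"),
                         const_nulls),
    "zero null variance")
  expect_equal(as.numeric(sig3$p_values), c(1, 0, 1, 1))

  # method tag and count guards
  expect_error(edge_pvalues(dcov_fc(mu, "cov"), nulls), "method tag")
  expect_error(edge_pvalues(dcov_fc(mu, "dcov_p"), nulls[1:10]),
               "at least 50")

  # empirical-quantile mode: an extreme empirical value hits the floor
  # 1/(n+1); a value at the null mean is maximal
  sig_e <- edge_pvalues(dcov_fc(mu + 100 * sdv, "dcov_p"), nulls,
                        p_mode = "empirical")
  expect_true(all(sig_e$p_values == 1 / 61))
  sig_c <- edge_pvalues(dcov_fc(mu, "dcov_p"), nulls,
                        p_mode = "empirical")
  expect_true(all(sig_c$p_values > 0.9))
})

test_that("binarization thresholds are nested and countable", {
  set.seed(12)
  n <- 5
  p <- matrix(runif(n * n, 0.1, 1), n, n)
  p[cbind(1:3, c(2, 3, 4))] <- c(0.001, 0.004, 0.008)
  sig <- structure(list(
    empirical = dcov_fc(matrix(rnorm(n * n), n, n), "dcov_p"),
    null_mean = matrix(0, n, n), null_sd = matrix(1, n, n),
    p_values = p, n_surrogates = 100, method = "dcov_p",
    directed = TRUE), class = "edge_significance")

  all_edges <- binarize(sig, 1)
  expect_equal(sum(all_edges$adjacency), n * (n - 1))  # full off-diagonal

  expect_equal(sum(binarize(sig, 0.01)$adjacency), 3)  # exact count

  e1 <- binarize(sig, 0.01)$adjacency
  e5 <- binarize(sig, 0.05)$adjacency
  expect_true(all(!e1 | e5))                           # nesting

  expect_error(binarize(sig, 0), "threshold")
})

test_that("match_sparsity keeps exactly k edges for both methods", {
  set.seed(13)
  n <- 4
  mk <- function(seed) {
    set.seed(seed)
    structure(list(
      empirical = dcov_fc(matrix(rnorm(n * n), n, n), "dcov_p"),
      null_mean = matrix(0, n, n), null_sd = matrix(1, n, n),
      p_values = matrix(runif(n * n), n, n), n_surrogates = 100,
      method = "dcov_p", directed = TRUE), class = "edge_significance")
  }
  a <- mk(1)
  b <- mk(2)
  for (k in c(0, 3, n * (n - 1))) {
    nets <- match_sparsity(a, b, k)
    expect_equal(sum(nets[[1]]$adjacency), k)
    expect_equal(sum(nets[[2]]$adjacency), k)
  }
  expect_error(match_sparsity(a, b, n * n), "exceeds")
})

test_that("the AR bootstrap pipeline is deterministic end to end", {
  set.seed(14)
  net <- generate_network(4, 0.25, seed = 14)
  z <- simulate_neural(net, T = 800, dt = 0.05, seed = 15)
  s1 <- ar_bootstrap_significance(z, "dcov_c", n_surrogates = 60, seed = 3)
  s2 <- ar_bootstrap_significance(z, "dcov_c", n_surrogates = 60, seed = 3)
  expect_identical(s1$p_values, s2$p_values)
  expect_identical(s1$null_mean, s2$null_mean)
  expect_true(all(s1$p_values >= 0 & s1$p_values <= 1))
})
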