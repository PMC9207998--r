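#' Central-difference numerical derivative
#'
#' Differentiates each node trace with central differences of the given
#' order, scaled by the sampling interval.  The output is trimmed
#' symmetrically by `order` samples at each end so that higher orders
#' always return a strictly interior support; labels are preserved and
#' the result has kind `"derivative"` (`dt` unchanged).
#'
#' Stencils: order 1 `( -1, 0, 1 ) / 2h`; order 2 `( 1, -2, 1 ) / h^2`;
#' order 3 `( -1, 2, 0, -2, 1 ) / 2h^3`; order 4
#' `( 1, -4, 6, -4, 1 ) / h^4`.  Orders 1 and 2 are exact on quadratics,
#' orders 3 and 4 on quartics, with `O(h^2)` truncation error otherwise.
#'
#' @param ts a [dcov_ts()].
#' @param order derivative order, 1 to 4.
#' @return a [dcov_ts()] of kind `"derivative"` with `T - 2 * order`
#'   samples.
#' @export
numerical_derivative <- function(ts, order = 1) {
  stopifnot(inherits(ts, "dcov_ts"))
  if (!order %in% 1:4) stop("order must be in 1..4")
  T <- ncol(ts)
  if (T <= 2 * order) stop("need more than ", 2 * order, " samples for ",
                           "order ", order)
  h <- ts_dt(ts)
  z <- ts_values(ts)
  sl <- function(k) z[, (3 + k):(T - 2 + k), drop = FALSE]  # offset on +-2 support
  d <- switch(order,
    (z[, 3:T, drop = FALSE] - z[, 1:(T - 2), drop = FALSE]) / (2 * h),
    (z[, 3:T, drop = FALSE] - 2 * z[, 2:(T - 1), drop = FALSE] +
       z[, 1:(T - 2), drop = FALSE]) / h^2,
    (sl(2) - 2 * sl(1) + 2 * sl(-1) - sl(-2)) / (2 * h^3),
    (sl(2) - 4 * sl(1) + 6 * sl(0) - 4 * sl(-1) + sl(-2)) / h^4)
  extra <- order - switch(order, 1L, 1L, 2L, 2L)  # trim to `order` per side
  if (extra > 0) {
    d <- d[, (1 + extra):(ncol(d) - extra), drop = FALSE]
  }
  dcov_ts(d, dt = h, kind = "derivative", labels = ts_labels(ts))
}

#' Backward reconstruction of neural activity from BOLD
#'
#' Inverts the linearized Balloon-Windkessel model: the surrogate neural
#' signal is the linear combination
#' `z = p4 y'''' + p3 y''' + p2 y'' + p1 y' + p0 y`
#' of the BOLD trace and its first four derivatives, with weights from
#' [balloon_coefficients()].  For data generated by the linearized
#' forward model, `z` equals `q1 V' + q0 V`, a mixture of the neural
#' signal and its first derivative.  All derivative orders are aligned
#' on the common trimmed support (4 samples dropped at each end).
#'
#' An optional Savitzky-Golay pre-filter (off by default) can be applied
#' before differentiation for noisy recordings; it requires the
#' `signal` package.
#'
#' @param y a [dcov_ts()] of kind `"bold"` with more than 8 samples.
#' @param params a [balloon_params()] set.
#' @param sg_filter apply a Savitzky-Golay pre-filter first.
#' @param sg_window,sg_order filter length (odd) and polynomial order.
#' @return a [dcov_ts()] of kind `"reconstructed"` with `T - 8` samples.
#' @export
backward_reconstruct <- function(y, params = balloon_params(),
                                 sg_filter = FALSE, sg_window = 9,
                                 sg_order = 3) {
  stopifnot(inherits(y, "dcov_ts"))
  if (ts_kind(y) != "bold") stop("input kind must be 'bold'")
  if (ncol(y) <= 8) stop("need more than 8 samples for 4th-order derivatives")
  if (sg_filter) {
    if (!requireNamespace("signal", quietly = TRUE)) {
      stop("the Savitzky-Golay pre-filter requires the 'signal' package")
    }
    sm <- t(apply(ts_values(y), 1, signal::sgolayfilt, p = sg_order,
                  n = sg_window))
    y <- dcov_ts(sm, dt = ts_dt(y), kind = "bold", labels = ts_labels(y))
  }
  p <- balloon_coefficients(params)$p
  T <- ncol(y)
  # supports after trimming by `order` per side; align all on trim 4
  align <- function(d, trim) {
    m <- ts_values(d)
    keep <- (1 + 4 - trim):(ncol(m) - (4 - trim))
    m[, keep, drop = FALSE]
  }
  z <- p["p0"] * ts_values(y)[, 5:(T - 4), drop = FALSE] +
    p["p1"] * align(numerical_derivative(y, 1), 1) +
    p["p2"] * align(numerical_derivative(y, 2), 2) +
    p["p3"] * align(numerical_derivative(y, 3), 3) +
    p["p4"] * ts_values(numerical_derivative(y, 4))
  dcov_ts(z, dt = ts_dt(y), kind = "reconstructed", labels = ts_labels(y))
}
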