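#' Balloon-Windkessel haemodynamic parameters
#'
#' Biophysical parameter set of the four-state Balloon-Windkessel model
#' (vasodilatory signal, inflow, venous volume, deoxyhaemoglobin) and
#' its BOLD readout.  Defaults are the canonical values of the model;
#' all are overridable.  `TE` (echo time) and `B` (field strength) are
#' acquisition properties and should always be set to match the dataset
#' (e.g. human 3 T: `TE = 0.033`, `B = 3`; mouse 9.4 T: `TE = 0.012`,
#' `B = 9.4`).  The frequency offset `theta0` scales linearly with field
#' strength, `theta0 = 40.3 * B / 1.5` s^-1, unless given explicitly.
#'
#' @param tau haemodynamic transit time (s).
#' @param epsilon ratio of intra- to extravascular signal
#'   (dimensionless); enters the BOLD readout coefficients.
#' @param alpha Grubb's vessel stiffness exponent, in (0, 1).
#' @param kappa vasodilatory signal decay rate (1/s).
#' @param gamma flow-dependent elimination rate (1/s).
#' @param rho resting oxygen extraction fraction (dimensionless).
#' @param eta neuronal efficacy: gain from neural activity to the
#'   vasodilatory signal (dimensionless).
#' @param V0 resting venous blood volume fraction.
#' @param TE echo time (s).
#' @param r0 intravascular relaxation slope (1/s).
#' @param B static field strength (Tesla).
#' @param theta0 frequency offset at the outer surface of magnetised
#'   vessels (1/s); default scales with `B`.
#' @return an object of class `balloon_params` (named list).
#' @export
balloon_params <- function(tau = 0.98, epsilon = 0.5, alpha = 0.32,
                           kappa = 0.65, gamma = 0.41, rho = 0.34,
                           eta = 0.02, V0 = 0.02, TE = 0.033, r0 = 25,
                           B = 3, theta0 = 40.3 * B / 1.5) {
  p <- list(tau = tau, epsilon = epsilon, alpha = alpha, kappa = kappa,
            gamma = gamma, rho = rho, eta = eta, V0 = V0, TE = TE,
            r0 = r0, B = B, theta0 = theta0)
  bad <- names(p)[!vapply(p, function(v) is.numeric(v) && length(v) == 1 &&
                            is.finite(v) && v > 0, logical(1))]
  if (length(bad)) stop("balloon parameters must be positive scalars: ",
                        paste(bad, collapse = ", "))
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (rho >= 1) stop("rho must lie in (0, 1)")
  structure(p, class = "balloon_params")
}

#' @export
print.balloon_params <- function(x, ...) {
  cat("<balloon_params>\n")
  cat(paste(sprintf("  %s = %g", names(x), unlist(x)), collapse = "\n"), "\n")
  invisible(x)
}

#' Reconstruction coefficients of the linearized Balloon model
#'
#' Computes the BOLD readout coefficients `k1, k2, k3`, the backward
#' reconstruction weights `p0..p4` applied to the BOLD signal and its
#' derivatives, and the neural-side weights `q0, q1` such that for the
#' linearized forward model
#' `z = p4 y'''' + p3 y''' + p2 y'' + p1 y' + p0 y = q1 V' + q0 V`.
#'
#' The `p` weights are the coefficients of the characteristic polynomial
#' `tau (s^2 + kappa s + gamma) (s + 1/(tau alpha)) (s + 1/tau)` of the
#' linearized haemodynamic cascade, so `p4 = tau` exactly.  The `q`
#' weights follow from linearizing the deoxyhaemoglobin dynamics around
#' the resting point, with oxygen-extraction slope
#' `c_f = 1 + (1 - rho) log(1 - rho) / rho`.
#'
#' @param params a [balloon_params()] set.
#' @return an object of class `balloon_coefficients`: list with numeric
#'   vectors `p` (`p0..p4`), `q` (`q0, q1`) and `k` (`k1, k2, k3`).
#' @export
balloon_coefficients <- function(params) {
  stopifnot(inherits(params, "balloon_params"))
  with(params, {
    k1 <- 4.3 * theta0 * rho * TE
    k2 <- epsilon * r0 * rho * TE
    k3 <- 1 - epsilon
    cf <- 1 + (1 - rho) * log(1 - rho) / rho
    p <- c(p0 = gamma / (tau * alpha),
           p1 = (1 + 1 / alpha) * gamma + kappa / (tau * alpha),
           p2 = 1 / (tau * alpha) + tau * gamma + (1 + 1 / alpha) * kappa,
           p3 = 1 + 1 / alpha + tau * kappa,
           p4 = tau)
    q <- c(q0 = (V0 * eta / tau) *
             (k2 - k3 - (k1 + k2) * (1 + (cf - 1) / alpha)),
           q1 = V0 * eta * (k2 - k3 - (k1 + k2) * cf))
    structure(list(p = p, q = q, k = c(k1 = k1, k2 = k2, k3 = k3), cf = cf),
              class = "balloon_coefficients")
  })
}

# Time derivative of the haemodynamic state.  x is a 4 x n matrix of
# states (s, f, v, q) per node (nonlinear: f, v, q around 1; linearized:
# deviations around 0); u is the neural drive per node.
balloon_deriv <- function(x, u, params, cf, linear) {
  s <- x[1, ]; f <- x[2, ]; v <- x[3, ]; q <- x[4, ]
  with(params, {
    if (linear) {
      rbind(eta * u - kappa * s - gamma * f,
            s,
            (f - v / alpha) / tau,
            (cf * f - (1 / alpha - 1) * v - q) / tau)
    } else {
      Ef <- 1 - (1 - rho)^(1 / f)
      rbind(eta * u - kappa * s - gamma * (f - 1),
            s,
            (f - v^(1 / alpha)) / tau,
            (f * Ef / rho - v^(1 / alpha - 1) * q) / tau)
    }
  })
}

#' Forward Balloon-Windkessel haemodynamic model
#'
#' Maps neural activity to BOLD deviation traces by integrating the
#' four-state Balloon-Windkessel system per node with fixed-step RK4.
#' The haemodynamic state starts at its resting fixed point, so zero
#' input maps to zero BOLD deviation.  Each node is driven independently
#' by its own trace (zero-order hold within a sample); the integrator
#' sub-steps internally so the RK4 step never exceeds 0.01 s.
#'
#' With `linearize = TRUE` the model is replaced by its linearization
#' around the resting point, the regime inverted exactly by
#' [backward_reconstruct()].
#'
#' @param V a [dcov_ts()] of kind `"neural"`.
#' @param params a [balloon_params()] set.
#' @param linearize integrate the linearized system instead of the full
#'   nonlinear one.
#' @return a [dcov_ts()] of kind `"bold"` with the same dimensions,
#'   labels and `dt`.  BOLD readout:
#'   `y = V0 (k1 (1 - q) + k2 (1 - q/v) + k3 (1 - v))`.
#' @export
balloon_forward <- function(V, params = balloon_params(),
                            linearize = FALSE) {
  stopifnot(inherits(V, "dcov_ts"))
  if (ts_kind(V) != "neural") stop("input kind must be 'neural'")
  stopifnot(inherits(params, "balloon_params"))
  co <- balloon_coefficients(params)
  k <- co$k
  dt <- ts_dt(V)
  n <- nrow(V)
  nt <- ncol(V)
  nsub <- max(1L, ceiling(dt / 0.01))
  h <- dt / nsub
  x <- if (linearize) matrix(0, 4, n) else rbind(rep(0, n), 1, 1, 1)
  y <- matrix(0, n, nt)
  Vm <- ts_values(V)
  for (t in seq_len(nt)) {
    u <- Vm[, t]
    for (s in seq_len(nsub)) {
      a <- balloon_deriv(x, u, params, co$cf, linearize)
      b <- balloon_deriv(x + h / 2 * a, u, params, co$cf, linearize)
      d <- balloon_deriv(x + h / 2 * b, u, params, co$cf, linearize)
      e <- balloon_deriv(x + h * d, u, params, co$cf, linearize)
      x <- x + h / 6 * (a + 2 * b + 2 * d + e)
    }
    if (any(!is.finite(x))) stop("haemodynamic state became non-finite at ",
                                 "sample ", t)
    y[, t] <- if (linearize) {
      params$V0 * (-(k[1] + k[2]) * x[4, ] + (k[2] - k[3]) * x[3, ])
    } else {
      params$V0 * (k[1] * (1 - x[4, ]) + k[2] * (1 - x[4, ] / x[3, ]) +
                     k[3] * (1 - x[3, ]))
    }
  }
  dcov_ts(y, dt = dt, kind = "bold", labels = ts_labels(V))
}
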