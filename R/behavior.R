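# Surrogate behaviour tables and efficiency-behaviour correlation.

#' Surrogate behaviour table coupled to network efficiency
#'
#' Builds a subjects-by-measures table in which exactly one measure
#' (`"coupled_measure"`) is generated as
#' `coupling * efficiency + confound loadings + noise`, the confound
#' columns are included as observed measures, and all remaining
#' measures are pure noise.  A configurable fraction of entries in the
#' non-confound measures is set missing at random, emulating incomplete
#' behavioural batteries.
#'
#' @param efficiencies per-subject network efficiency values.
#' @param coupling linear coupling of the target measure to efficiency
#'   (may be negative).
#' @param confounds subjects x C numeric matrix of confound values
#'   (e.g. age, weight, height, blood pressures, brain volume); may be
#'   NULL for no confounds.
#' @param noise_sd sd of the additive noise on every generated measure.
#' @param seed integer seed.
#' @param n_noise number of pure-noise measures.
#' @param confound_loading weights of the confounds in the coupled
#'   measure (recycled).
#' @param missing_frac fraction of entries set missing in non-confound
#'   measures.
#' @return a `behavior_table`: list with `subjects`, `measures`
#'   (matrix with NAs), `measure_names`, `confound_names`.
#' @export
surrogate_behavior <- function(efficiencies, coupling, confounds = NULL,
                               noise_sd = 1, seed = 1, n_noise = 20,
                               confound_loading = 1, missing_frac = 0) {
  n <- length(efficiencies)
  if (n < 2) stop("need at least 2 subjects")
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n)
  }
  ncf <- if (is.null(confounds)) 0L else ncol(confounds)
  confound_names <- if (ncf) sprintf("confound%02d", seq_len(ncf)) else
    character(0)
  with_seed(seed, {
    target <- coupling * efficiencies + noise_sd * rnorm(n)
    if (ncf) {
      load <- rep_len(confound_loading, ncf)
      target <- target + drop(confounds %*% load)
    }
    noise <- matrix(rnorm(n * n_noise, sd = noise_sd), n, n_noise)
    measures <- cbind(target, if (ncf) confounds, noise)
    measure_names <- c("coupled_measure", confound_names,
                       sprintf("noise%03d", seq_len(n_noise)))
    colnames(measures) <- measure_names
    if (missing_frac > 0) {
      maskable <- setdiff(seq_along(measure_names),
                          match(confound_names, measure_names))
      for (jm in maskable) {
        miss <- runif(n) < missing_frac
        measures[miss, jm] <- NA_real_
      }
    }
    structure(list(subjects = sprintf("subj%04d", seq_len(n)),
                   measures = measures, measure_names = measure_names,
                   confound_names = confound_names),
              class = "behavior_table")
  })
}

#' @export
print.behavior_table <- function(x, ...) {
  cat(sprintf("<behavior_table> %d subjects x %d measures (%d confounds, %d missing entries)\n",
              length(x$subjects), length(x$measure_names),
              length(x$confound_names), sum(is.na(x$measures))))
  invisible(x)
}

#' Regress confounds out of a per-subject statistic
#'
#' Least-squares residuals of `values` on an intercept plus the
#' confound columns.  Collinear confound columns are dropped with a
#' warning (pivoted QR).
#'
#' @param values per-subject numeric vector (e.g. global efficiency).
#' @param confounds subjects x C matrix; NULL for intercept only.
#' @return numeric residual vector.
#' @export
regress_confounds <- function(values, confounds = NULL) {
  n <- length(values)
  X <- cbind(intercept = rep(1, n),
             if (!is.null(confounds)) as.matrix(confounds))
  if (ncol(X) >= n) stop("more confounds than subjects")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("dropping collinear confound column(s): ",
            paste(dropped, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, values))
}

#' Rank behavioural measures by correlation with residual efficiency
#'
#' Excludes measures with more than `max_missing` missing entries and
#' the confound columns themselves, then correlates each remaining
#' measure with the residual statistic, controlling for the table's
#' confound columns on the measure side as well (the measure is
#' residualized on an intercept plus the confounds over its
#' pairwise-complete subjects).  This makes the ranking invariant to
#' how strongly the confounds load on a measure; when a measure is
#' confound-free it reduces to the plain Pearson correlation with the
#' residual statistic.  Results are sorted by ascending (uncorrected)
#' two-sided p-value.  Constant measures are skipped with a warning.
#'
#' @param residuals per-subject residual statistic (see
#'   [regress_confounds()]).
#' @param bm a `behavior_table`.
#' @param max_missing missing-entry cutoff per measure (default 200).
#' @return a tibble with columns `measure`, `r`, `p`, `n`, sorted by
#'   `p`.
#' @export
rank_correlations <- function(residuals, bm, max_missing = 200) {
  stopifnot(inherits(bm, "behavior_table"))
  if (length(residuals) != nrow(bm$measures)) {
    stop("residuals length must equal the number of subjects")
  }
  conf <- if (length(bm$confound_names)) {
    bm$measures[, bm$confound_names, drop = FALSE]
  } else {
    NULL
  }
  candidates <- setdiff(bm$measure_names, bm$confound_names)
  rows <- lapply(candidates, function(name) {
    x <- bm$measures[, name]
    if (sum(is.na(x)) > max_missing) return(NULL)
    ok <- !is.na(x) & !is.na(residuals)
    if (!is.null(conf)) ok <- ok & !apply(is.na(conf), 1, any)
    if (sum(ok) < 4 || sd(x[ok]) == 0) {
      warning("skipping constant or near-empty measure: ", name)
      return(NULL)
    }
    xr <- if (is.null(conf)) {
      x[ok]
    } else {
      regress_confounds(x[ok], conf[ok, , drop = FALSE])
    }
    ct <- cor.test(residuals[ok], xr)
    tibble::tibble(measure = name, r = unname(ct$estimate),
                   p = ct$p.value, n = sum(ok))
  })
  out <- do.call(rbind, rows)
  out[order(out$p), ]
}
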