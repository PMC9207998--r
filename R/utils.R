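# Internal helpers shared across modules.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so no function leaks global random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Rank-based ROC-AUC of `score` against logical `truth` (Wilcoxon form).
rank_auc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

frob <- function(m) sqrt(sum(m^2))

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

off_diag <- function(m) row(m) != col(m)

`%||%` <- function(a, b) if (is.null(a)) b else a

default_labels <- function(n) sprintf("node%02d", seq_len(n))

check_labels <- function(labels, n) {
  if (is.null(labels)) labels <- default_labels(n)
  labels <- as.character(labels)
  if (length(labels) != n) stop("need ", n, " labels, got ", length(labels))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  labels
}
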