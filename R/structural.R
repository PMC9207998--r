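# Structural connectivity surrogates and FC-SC comparison (SCS / ASCS).

#' Surrogate structural connectivity from a ground-truth network
#'
#' Derives a structural-connectivity (SC) matrix from the generating
#' weights, emulating the two conventions of the reference datasets:
#'
#' * `"mouse"` (tracing-style, ordinal): absolute off-diagonal weights
#'   are rank-quantized into 7 equal-mass bins on a 1 (weakest) to 7
#'   (strongest) scale; ties share a bin, so absent connections all map
#'   to 1.  The diagonal is set to 7 (intraregional connectivity is
#'   taken to be maximal).  Directed.
#' * `"dmri"` (diffusion-imaging-style, continuous): symmetrized
#'   magnitude `|W| + |W^T|` with zero diagonal.  Undirected.
#'
#' @param net a [generate_network()] result.
#' @param convention `"mouse"` or `"dmri"`.
#' @return a `surrogate_sc` object: list with `weights`, `labels`,
#'   `symmetric`, `convention`.
#' @export
surrogate_sc <- function(net, convention = c("mouse", "dmri")) {
  stopifnot(inherits(net, "ground_truth_network"))
  convention <- match.arg(convention)
  W <- net$weights
  n <- nrow(W)
  if (convention == "mouse") {
    S <- matrix(7, n, n)
    idx <- which(off_diag(W))
    v <- abs(W[idx])
    m <- length(idx)
    bins <- ceiling(7 * rank(v, ties.method = "min") / m)
    S[idx] <- pmax(bins, 1)
    symmetric <- FALSE
  } else {
    S <- abs(W) + abs(t(W))
    diag(S) <- 0
    symmetric <- TRUE
  }
  dimnames(S) <- list(net$labels, net$labels)
  structure(list(weights = S, labels = net$labels, symmetric = symmetric,
                 convention = convention),
            class = "surrogate_sc")
}

#' @export
print.surrogate_sc <- function(x, ...) {
  cat(sprintf("<surrogate_sc> %d nodes, %s convention (%s)\n",
              length(x$labels), x$convention,
              if (x$symmetric) "symmetric" else "directed"))
  invisible(x)
}

#' Write / read a labelled square matrix as TSV
#'
#' Header row plus a first column of labels; used for networks and SC.
#'
#' @param m labelled square matrix.
#' @param path file path.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` a labelled matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Load a structural-connectivity matrix aligned to FC nodes
#'
#' Reads a labelled square SC matrix and aligns it to the FC node
#' order.  When a node maps to several atlas regions (via
#' `region_map`), its SC row and column are the mean over the mapped
#' regions' rows and columns — the averaging rule used when one
#' component covers multiple anatomical locations.
#'
#' @param path TSV file of a labelled square matrix (see
#'   [read_matrix_tsv()]).
#' @param labels FC node names, in order.
#' @param region_map optional named list: `labels`-named entries giving
#'   the atlas region(s) each node maps to; by default each label maps
#'   to the identically named region.
#' @return a `surrogate_sc` object (convention `"file"`).
#' @export
load_structural <- function(path, labels, region_map = NULL) {
  raw <- read_matrix_tsv(path)
  if (is.null(region_map)) {
    region_map <- stats::setNames(as.list(labels), labels)
  }
  missing_nodes <- setdiff(labels, names(region_map))
  if (length(missing_nodes)) {
    stop("no region mapping for node(s): ",
         paste(missing_nodes, collapse = ", "))
  }
  all_regions <- unique(unlist(region_map[labels]))
  unknown <- setdiff(all_regions, rownames(raw))
  if (length(unknown)) {
    stop("region(s) absent from SC file: ", paste(unknown, collapse = ", "))
  }
  n <- length(labels)
  rows <- t(vapply(labels, function(l) {
    colMeans(raw[region_map[[l]], , drop = FALSE])
  }, numeric(ncol(raw))))                      # labels x regions
  S <- vapply(labels, function(l) {
    rowMeans(rows[, region_map[[l]], drop = FALSE])
  }, numeric(n))                               # S[i, j]: row i, column j
  dimnames(S) <- list(labels, labels)
  structure(list(weights = S, labels = labels,
                 symmetric = isTRUE(all.equal(S, t(S))),
                 convention = "file"),
            class = "surrogate_sc")
}

#' Structural connectivity strength of significant edges
#'
#' For each subject's binary network, the SC entries at the TRUE
#' off-diagonal positions (row = sink, column = source, matching the
#' connectivity convention) are pooled into one SCS set across
#' subjects; ASCS is its mean.  Undirected networks contribute both
#' `(i, j)` and `(j, i)` once each, since their masks are symmetric.
#' The diagonal is always excluded: FC diagonals are self-terms, not
#' connections.
#'
#' @param binaries a `binary_network` or list of them (one per
#'   subject).
#' @param sc a `surrogate_sc` with matching labels.
#' @param method,threshold optional tags carried into the result.
#' @return an `scs_result`: list with `values`, `ascs`, `method`,
#'   `threshold`, `n_edges`, `n_subjects`, `empty`.
#' @export
scs_values <- function(binaries, sc, method = NA_character_,
                       threshold = NA_real_) {
  stopifnot(inherits(sc, "surrogate_sc"))
  if (inherits(binaries, "binary_network")) binaries <- list(binaries)
  values <- unlist(lapply(binaries, function(net) {
    stopifnot(inherits(net, "binary_network"))
    if (!identical(rownames(net$adjacency), sc$labels)) {
      stop("binary network labels do not match SC labels")
    }
    mask <- adjacency_as(net, "sink")
    diag(mask) <- FALSE
    sc$weights[mask]
  }))
  empty <- length(values) == 0
  if (empty) warning("no significant edges: ASCS undefined")
  structure(list(values = as.numeric(values),
                 ascs = if (empty) NA_real_ else mean(values),
                 method = method, threshold = threshold,
                 n_edges = length(values), n_subjects = length(binaries),
                 empty = empty),
            class = "scs_result")
}

#' @export
print.scs_result <- function(x, ...) {
  cat(sprintf("<scs_result> %s @ p<%g: %d pooled edges, ASCS = %.4g\n",
              x$method, x$threshold, x$n_edges, x$ascs))
  invisible(x)
}

#' ASCS across binarization thresholds
#'
#' Binarizes each subject's edge-significance result at every threshold
#' (given in descending order), pools the selected SC strengths across
#' subjects and returns one [scs_values()] result per threshold.
#' Decreasing thresholds select fewer edges, tracing out how strongly
#' the surviving connections are structurally supported.
#'
#' @param sigs an `edge_significance` or list of them (one per
#'   subject), all from the same method.
#' @param sc a `surrogate_sc`.
#' @param thresholds descending significance levels.
#' @return an `ascs_curve` object: list of `scs_result`, one per
#'   threshold.
#' @export
ascs_curve <- function(sigs, sc,
                       thresholds = c(0.05, 0.01, 0.005, 0.001)) {
  if (inherits(sigs, "edge_significance")) sigs <- list(sigs)
  if (is.unsorted(rev(thresholds))) {
    stop("thresholds must be in descending order")
  }
  method <- sigs[[1]]$method
  out <- lapply(thresholds, function(th) {
    nets <- lapply(sigs, binarize, threshold = th)
    suppressWarnings(scs_values(nets, sc, method = method, threshold = th))
  })
  structure(out, class = "ascs_curve")
}

#' @export
print.ascs_curve <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}
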