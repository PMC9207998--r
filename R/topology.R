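# Binary graph topology measures for directed and undirected networks.
#
# All formulas operate on the graph-theory adjacency convention
# a[i, j] = 1  <=>  edge i -> j (row = source); binary_network objects
# carrying the connectivity convention (row = sink) are transposed on
# entry.  For undirected networks the directed formulas reduce to the
# undirected ones, which is asserted in the test suite.

as_net <- function(net) {
  if (inherits(net, "binary_network")) return(net)
  m <- as.matrix(net)
  mode(m) <- "logical"
  binary_network(m, directed = !isTRUE(all.equal(m, t(m))))
}

topo_adj <- function(net) {
  net <- as_net(net)
  a <- adjacency_as(net, "source")
  storage.mode(a) <- "double"
  a
}

#' Node degrees
#'
#' Out-degree is the row sum, in-degree the column sum of the (source
#' convention) adjacency; for undirected networks the two coincide.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @return list with numeric vectors `out` and `in_`.
#' @export
degrees <- function(net) {
  a <- topo_adj(net)
  list(out = rowSums(a), in_ = colSums(a))
}

#' Shortest path lengths (unweighted, direction-respecting)
#'
#' Breadth-first search from every source.  `d[i, i] = 0`; unreachable
#' pairs get `Inf`.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @return N x N matrix of path lengths.
#' @export
shortest_paths <- function(net) {
  a <- topo_adj(net) > 0
  n <- nrow(a)
  d <- matrix(Inf, n, n, dimnames = dimnames(a))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- which(colSums(a[frontier, , drop = FALSE]) > 0 &
                     is.infinite(dist))
      dist[nxt] <- depth
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Global efficiency
#'
#' Mean inverse shortest path length,
#' `E = 1/N sum_i 1/(N-1) sum_{j != i} 1/d_ij`, with `1/Inf = 0`.
#' Equals 1 exactly for a complete graph and 0 for an empty one.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @return scalar in `[0, 1]`.
#' @export
global_efficiency <- function(net) {
  d <- shortest_paths(net)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 nodes")
  inv <- 1 / d
  diag(inv) <- 0
  mean(rowSums(inv) / (n - 1))
}

#' Per-node triangle counts
#'
#' Undirected: `t_i = 1/2 sum_{j,h} a_ij a_ih a_jh`.  Directed:
#' `t_i = 1/2 sum_{j,h} (a_ij + a_ji)(a_ih + a_hi)(a_jh + a_hj)`, which
#' counts each configuration of edges closing a triangle around `i`
#' regardless of orientation (and is 8 times the undirected count on a
#' symmetric graph).
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @return numeric vector of per-node triangle counts.
#' @export
triangles <- function(net) {
  net <- as_net(net)
  a <- topo_adj(net)
  u <- if (net$directed) a + t(a) else a
  diag(u %*% u %*% u) / 2
}

# Directed clustering denominator per node:
# (k_out + k_in)(k_out + k_in - 1) - 2 * #reciprocal edges at i.
clustering_denominator <- function(net) {
  net <- as_net(net)
  a <- topo_adj(net)
  if (net$directed) {
    ktot <- rowSums(a) + colSums(a)
    recip <- rowSums(a * t(a))
    ktot * (ktot - 1) - 2 * recip
  } else {
    k <- rowSums(a)
    k * (k - 1)
  }
}

#' Clustering coefficient and transitivity
#'
#' Clustering averages each node's triangle density
#' `t_i / denom_i` (undirected `denom_i = k_i (k_i - 1) / ...` with the
#' factor 2 folded into `t_i`; directed
#' `denom_i = (k_out + k_in)(k_out + k_in - 1) - 2 sum_j a_ij a_ji`);
#' nodes with zero denominator contribute 0.  Transitivity is the ratio
#' of the summed numerators to the summed denominators, so hubs weigh
#' more than in clustering.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @return list with scalars `clustering` and `transitivity`.
#' @export
clustering_transitivity <- function(net) {
  net <- as_net(net)
  t_i <- triangles(net)
  denom <- clustering_denominator(net)
  num <- if (net$directed) t_i else 2 * t_i
  frac <- ifelse(denom > 0, num / denom, 0)
  trans_idx <- denom > 0
  list(clustering = mean(frac),
       transitivity = if (any(trans_idx)) {
         sum(num[trans_idx]) / sum(denom[trans_idx])
       } else 0)
}

#' Local efficiency
#'
#' Average over nodes of the efficiency computed within each node's
#' neighbourhood: paths between neighbours `j, h` of `i` are measured
#' in the subgraph induced by `i`'s neighbours (both in- and
#' out-neighbours for directed graphs), inverse lengths in both
#' directions are summed and normalised by the directed clustering
#' denominator.  Zero-denominator nodes contribute 0.  For symmetric
#' adjacency this reduces to averaging the global efficiency of each
#' induced neighbour subgraph.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @return scalar.
#' @export
local_efficiency <- function(net) {
  net <- as_net(net)
  a <- topo_adj(net)
  n <- nrow(a)
  u <- if (net$directed) a + t(a) else a
  denom <- clustering_denominator(net)
  eff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(u[i, ] > 0)
    if (length(nb) < 2 || denom[i] <= 0) next
    sub <- binary_network(a[nb, nb, drop = FALSE] > 0,
                          directed = net$directed)
    inv <- 1 / shortest_paths(sub)
    diag(inv) <- 0
    w <- u[i, nb]
    eff[i] <- if (net$directed) {
      drop(t(w) %*% (inv + t(inv)) %*% w) / denom[i]
    } else {
      drop(t(w) %*% inv %*% w) / denom[i]
    }
  }
  if (net$directed) mean(eff) / 2 else mean(eff)
}

#' Modularity of a partition
#'
#' With `e_uv` the proportion of all edges linking module `u` to module
#' `v` and `a_u = sum_v e_uv`, computes the Newman modularity
#' `Q = sum_u (e_uu - a_u^2)`.  Undirected graphs are handled as
#' symmetric directed graphs (each undirected edge counted in both
#' directions), which reproduces the standard undirected value.  The
#' historically printed variant `sum_u (e_uu - a_u)^2`, which squares
#' the whole bracket, is available via `printed_form = TRUE` for
#' auditability but is not the standard definition.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @param partition integer or factor vector assigning every node to a
#'   module.
#' @param printed_form use the bracket-squared variant.
#' @return scalar Q.
#' @export
modularity_q <- function(net, partition, printed_form = FALSE) {
  a <- topo_adj(net)
  n <- nrow(a)
  if (length(partition) != n) stop("partition must cover all nodes")
  partition <- as.integer(factor(partition))
  e <- module_link_matrix(a, partition)
  au <- rowSums(e)
  if (printed_form) sum((diag(e) - au)^2) else sum(diag(e) - au^2)
}

# e[u, v]: proportion of all directed edges from module u to module v.
module_link_matrix <- function(a, partition) {
  k <- max(partition)
  M <- matrix(0, nrow(a), k)
  M[cbind(seq_len(nrow(a)), partition)] <- 1
  e <- t(M) %*% a %*% M
  tot <- sum(e)
  if (tot == 0) matrix(0, k, k) else e / tot
}

#' Greedy modularity-maximising partition
#'
#' Agglomerative search: every node starts in its own module and the
#' merge that most increases [modularity_q()] is applied until no merge
#' improves it.  If the local optimum is worse than the single-module
#' partition (Q = 0) the latter is returned, so the result is never
#' worse than trivial.  Deterministic given `seed` (the seed only
#' breaks ties in the merge order).
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @param seed integer seed.
#' @return integer vector of module ids (1-based, consecutive).
#' @export
find_partition <- function(net, seed = 1) {
  a <- topo_adj(net)
  n <- nrow(a)
  if (sum(a) == 0) return(rep(1L, n))
  part <- seq_len(n)
  order_jitter <- with_seed(seed, runif(n * n, 0, 1e-12))
  repeat {
    e <- module_link_matrix(a, part)
    au <- rowSums(e)
    mods <- sort(unique(part))
    k <- length(mods)
    if (k == 1) break
    best_gain <- 0
    best_pair <- NULL
    for (u in seq_len(k - 1)) {
      for (v in (u + 1):k) {
        gain <- e[u, v] + e[v, u] - 2 * au[u] * au[v] +
          order_jitter[(u - 1) * k + v]
        if (gain > best_gain + 1e-14) {
          best_gain <- gain
          best_pair <- c(u, v)
        }
      }
    }
    if (is.null(best_pair)) break
    part[part == mods[best_pair[2]]] <- mods[best_pair[1]]
    part <- as.integer(factor(part))
  }
  q <- modularity_q(net, part)
  if (q < 0) part <- rep(1L, n)
  as.integer(factor(part))
}

#' Full topology report
#'
#' Computes every topological measure for a binary network: degrees,
#' shortest-path matrix, triangles, global and local efficiency,
#' clustering, transitivity, and modularity of a greedily optimised
#' partition.
#'
#' @param net a `binary_network` (or adjacency matrix).
#' @param seed seed for [find_partition()].
#' @return a `topology_report` list.
#' @export
topology_report <- function(net, seed = 1) {
  net <- as_net(net)
  deg <- degrees(net)
  ct <- clustering_transitivity(net)
  part <- find_partition(net, seed = seed)
  structure(list(
    directed = net$directed,
    out_degree = deg$out,
    in_degree = deg$in_,
    distances = shortest_paths(net),
    triangles = triangles(net),
    global_efficiency = global_efficiency(net),
    local_efficiency = local_efficiency(net),
    clustering = ct$clustering,
    transitivity = ct$transitivity,
    partition = part,
    modularity = modularity_q(net, part)),
    class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<topology_report> %s, %d nodes\n",
    "  E = %.4f  E_loc = %.4f  C = %.4f  T = %.4f  Q = %.4f ",
    "(%d modules)\n"),
    if (x$directed) "directed" else "undirected", length(x$out_degree),
    x$global_efficiency, x$local_efficiency, x$clustering,
    x$transitivity, x$modularity, length(unique(x$partition))))
  invisible(x)
}
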