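#' Cluster summary container
#'
#' Summarises a partition of the `N` agents into groups: the number of
#' clusters, the multiset of cluster sizes, the number of isolates
#' (size-1 clusters) and the largest size. `tidy()` gives one row per
#' cluster, `glance()` the one-row summary.
#'
#' @param sizes Integer vector of cluster sizes (sums to `N`).
#' @param membership Optional integer vector mapping each agent to its
#'   cluster id.
#' @param kind Label for the partition rule used.
#' @return An object of class `cluster_summary`.
#' @export
cluster_summary <- function(sizes, membership = NULL, kind = "clusters") {
  sizes <- sort(as.integer(sizes), decreasing = TRUE)
  structure(list(n_clusters = length(sizes), sizes = sizes,
                 n_isolates = sum(sizes == 1L), largest = max(sizes),
                 membership = membership, kind = kind),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %s: %d cluster(s) over %d agents; largest %d, isolates %d\n",
              x$kind, x$n_clusters, sum(x$sizes), x$largest, x$n_isolates))
  invisible(x)
}

#' @export
tidy.cluster_summary <- function(x, ...) {
  tibble::tibble(cluster = seq_along(x$sizes), size = x$sizes)
}

#' @export
glance.cluster_summary <- function(x, ...) {
  tibble::tibble(n_clusters = x$n_clusters, largest = x$largest,
                 n_isolates = x$n_isolates, mean_size = mean(x$sizes),
                 n_agents = sum(x$sizes))
}

#' Count opinion-based groups (non-spatial clusters)
#'
#' Clusters are the equivalence classes of identical length-`F` culture
#' vectors over all agents, regardless of lattice position — the spatial
#' constraint of the classic cultural-region definition is deliberately
#' dropped. Singletons (isolates) count as clusters of size 1.
#'
#' @param state An `axelrod_state` (or a plain integer matrix).
#' @return A [cluster_summary()]; `membership` maps agents to clusters.
#' @examples
#' st <- axelrod_state(matrix(c(0, 0, 1, 0, 0, 1, 1, 0), 4, 2), q = 2)
#' count_clusters(st)$n_clusters
#' @export
count_clusters <- function(state) {
  tr <- if (inherits(state, "axelrod_state")) state$traits else state
  key <- apply(tr, 1, paste, collapse = ",")
  fid <- match(key, unique(key))
  cluster_summary(tabulate(fid), membership = fid, kind = "opinion groups")
}

# pairwise shared-feature counts, dense N x N integer matrix
shared_matrix <- function(tr) {
  N <- nrow(tr)
  S <- matrix(0L, N, N)
  for (k in seq_len(ncol(tr))) {
    v <- tr[, k]
    S <- S + outer(v, v, `==`)
  }
  S
}

#' Components under relaxed agreement
#'
#' Connected components of the graph on agents with an edge wherever two
#' agents agree on at least `F - m` features; `m = 0` reduces exactly to
#' [count_clusters()], `m = 1` joins groups differing on at most one
#' feature, and so on. Agreement is chained: a component may contain pairs
#' that disagree on more than `m` features.
#'
#' @param state An `axelrod_state`.
#' @param m Maximum per-edge disagreement, integer with `0 <= m < F`.
#' @return A [cluster_summary()].
#' @export
relaxed_components <- function(state, m) {
  tr <- if (inherits(state, "axelrod_state")) state$traits else state
  F <- ncol(tr)
  if (length(m) != 1 || is.na(m) || m != round(m) || m < 0 || m >= F)
    stop("`m` must be an integer with 0 <= m < F", call. = FALSE)
  if (m == 0) {
    cl <- count_clusters(state)
    cl$kind <- "relaxed components (m = 0)"
    return(cl)
  }
  S <- shared_matrix(tr)
  adj <- S >= F - m
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  cluster_summary(comp$csize, membership = comp$membership,
                  kind = sprintf("relaxed components (m = %d)", m))
}

#' Spatially connected cultural regions
#'
#' The classic Axelrod statistic, for comparison with the non-spatial
#' cluster count: connected components of the lattice restricted to edges
#' whose endpoints have identical culture vectors. A culture occupying two
#' physically separated patches forms two regions but one opinion-based
#' group, so the region count is never below [count_clusters()].
#'
#' @param state An `axelrod_state`.
#' @param topology A [lattice_topology()].
#' @return A [cluster_summary()].
#' @export
spatial_regions <- function(state, topology) {
  tr <- state$traits
  e <- topology$edges
  same <- vapply(seq_len(nrow(e)),
                 function(r) all(tr[e[r, 1], ] == tr[e[r, 2], ]),
                 logical(1))
  g <- igraph::make_empty_graph(n = nrow(tr), directed = FALSE)
  if (any(same)) g <- igraph::add_edges(g, t(e[same, , drop = FALSE]))
  comp <- igraph::components(g)
  cluster_summary(comp$csize, membership = comp$membership,
                  kind = "spatial regions")
}
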