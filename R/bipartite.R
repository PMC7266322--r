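#' Bipartite agent-attitude representation of a culture state
#'
#' Two-mode graph with agent nodes on one side and attitude nodes —
#' (feature, trait) combinations — on the other; an edge records that the
#' agent holds that trait on that feature. Every agent therefore has degree
#' exactly `F` and the graph has `N * F` edges. Attitude nodes are named
#' `"f<k>:t<t>"` (`k` 1-based feature index, `t` 0-based trait value) and
#' agents `"a<i>"`.
#'
#' @param state An `axelrod_state`.
#' @param all_nodes If `FALSE` (default) only attitude nodes held by at
#'   least one agent appear; `TRUE` includes all `F * q` combinations
#'   (useful for fixed layouts).
#' @return An object of class `axelrod_bipartite`: an igraph graph with
#'   logical vertex attribute `type` (`FALSE` agents, `TRUE` attitudes) and
#'   attributes `feature`, `trait` on attitude nodes.
#' @examples
#' st <- axelrod_state(matrix(0L, 4, 3), q = 5)   # consensus
#' g <- build_bipartite(st)
#' igraph::ecount(g)  # N * F = 12
#' @export
build_bipartite <- function(state, all_nodes = FALSE) {
  tr <- state$traits
  N <- nrow(tr); F <- ncol(tr); q <- state$q
  agent_names <- paste0("a", seq_len(N))
  att_name <- function(k, t) paste0("f", k, ":t", t)

  long <- tidyr::expand_grid(feature = seq_len(F), agent = seq_len(N)) |>
    dplyr::mutate(trait = tr[cbind(.data$agent, .data$feature)])
  held <- dplyr::distinct(long, .data$feature, .data$trait) |>
    dplyr::arrange(.data$feature, .data$trait)
  atts <- if (all_nodes)
    tidyr::expand_grid(feature = seq_len(F), trait = 0:(q - 1))
  else held

  verts <- tibble::tibble(
    name = c(agent_names, att_name(atts$feature, atts$trait)),
    type = rep(c(FALSE, TRUE), c(N, nrow(atts))),
    feature = c(rep(NA_integer_, N), atts$feature),
    trait = c(rep(NA_integer_, N), atts$trait)
  )
  edges <- tibble::tibble(
    from = agent_names[long$agent],
    to = att_name(long$feature, long$trait)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = verts)
  class(g) <- c("axelrod_bipartite", class(g))
  g
}

#' Tidy a bipartite graph into an edge table
#'
#' @param x An `axelrod_bipartite`.
#' @param ... Unused.
#' @return A tibble with `agent`, `feature`, `trait` per holding.
#' @export
tidy.axelrod_bipartite <- function(x, ...) {
  e <- igraph::as_edgelist(x)
  att <- ifelse(grepl("^f", e[, 1]), e[, 1], e[, 2])
  ag <- ifelse(grepl("^a", e[, 1]) & !grepl(":", e[, 1]), e[, 1], e[, 2])
  m <- regmatches(att, regexec("^f([0-9]+):t([0-9]+)$", att))
  tibble::tibble(
    agent = as.integer(sub("^a", "", ag)),
    feature = as.integer(vapply(m, `[`, "", 2)),
    trait = as.integer(vapply(m, `[`, "", 3))
  ) |> dplyr::arrange(.data$agent, .data$feature)
}

new_projection <- function(graph, type) {
  structure(list(graph = graph, type = type,
                 nodes = tibble::as_tibble(igraph::as_data_frame(graph, "vertices")),
                 edges = tibble::as_tibble(igraph::as_data_frame(graph, "edges"))),
            class = "weighted_projection")
}

#' @export
print.weighted_projection <- function(x, ...) {
  cat(sprintf("<weighted_projection> %s space: %d nodes, %d weighted edges\n",
              x$type, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.weighted_projection <- function(x, ...) x$edges

#' One-mode projection onto attitude space
#'
#' Co-occurrence graph over (feature, trait) attitude nodes: the weight of
#' an edge is the number of agents holding both endpoint attitudes. Since
#' each agent holds exactly one trait per feature, no edge ever joins two
#' attitudes of the same feature.
#'
#' @param bipartite An [build_bipartite()] graph.
#' @return A `weighted_projection` (`type = "attitude"`), with the igraph
#'   graph in `$graph` and a tidy edge table in `$edges`.
#' @export
attitude_projection <- function(bipartite) {
  proj <- igraph::bipartite_projection(bipartite, multiplicity = TRUE)
  new_projection(proj$proj2, "attitude")
}

#' One-mode projection onto agent space
#'
#' Graph over agents with an edge wherever two agents hold at least
#' `min_weight` attitudes in common; the weight is the shared-feature
#' count (`weight = F` iff identical culture vectors). All `N` agent nodes
#' are kept, so agents sharing no attitude with anyone appear as isolated
#' vertices.
#'
#' @param bipartite An [build_bipartite()] graph.
#' @param min_weight Minimum shared-feature count for an edge (default 1).
#' @return A `weighted_projection` (`type = "agent"`).
#' @export
agent_projection <- function(bipartite, min_weight = 1) {
  proj <- igraph::bipartite_projection(bipartite, multiplicity = TRUE)
  g <- proj$proj1
  drop <- igraph::E(g)[igraph::E(g)$weight < min_weight]
  g <- igraph::delete_edges(g, drop)
  p <- new_projection(g, "agent")
  p$min_weight <- min_weight
  p
}

#' Bin projection edges by weight
#'
#' Splits the observed edge weights into `n_bins` classes from weakest to
#' strongest (terciles by default, the split used to style projection
#' figures). Boundaries are the empirical quantiles of the weight
#' distribution; an edge lying exactly on a boundary goes to the lower bin,
#' and if every weight is equal all edges land in the lowest bin.
#'
#' @param projection A `weighted_projection` (or igraph graph with a
#'   `weight` edge attribute).
#' @param n_bins Number of classes (default 3).
#' @return The projection with `bin` (integer, 1 = weakest) and, for
#'   `n_bins = 3`, `bin_label` in bottom/middle/top added to `$edges` and
#'   the graph; quantile boundaries in `$bin_boundaries`.
#' @export
bin_edge_weights <- function(projection, n_bins = 3) {
  g <- if (inherits(projection, "weighted_projection")) projection$graph
  else projection
  w <- igraph::E(g)$weight
  if (length(w) == 0) {
    bins <- integer(0)
    bounds <- numeric(0)
  } else {
    bounds <- stats::quantile(w, probs = seq(0, 1, length.out = n_bins + 1),
                              names = FALSE, type = 7)
    # bin = smallest b with w <= bounds[b + 1]: boundary ties fall low
    upper <- bounds[-1]
    bins <- vapply(w, function(x) which(x <= upper)[1], integer(1))
  }
  g <- igraph::set_edge_attr(g, "bin", value = bins)
  if (n_bins == 3)
    g <- igraph::set_edge_attr(
      g, "bin_label", value = c("bottom", "middle", "top")[bins])
  if (inherits(projection, "weighted_projection")) {
    out <- new_projection(g, projection$type)
    out$min_weight <- projection$min_weight
    out$bin_boundaries <- bounds
    out
  } else {
    attr(g, "bin_boundaries") <- bounds
    g
  }
}

#' Export / import graphs
#'
#' Writes a bipartite graph or projection either as GraphML (all node and
#' edge attributes preserved; lossless round trip) or as a
#' whitespace-delimited weighted edge list (`from to weight`). Exports
#' always contain every node, including isolates (GraphML only for the
#' edge-list format, which cannot carry them).
#'
#' @param graph An `axelrod_bipartite`, `weighted_projection`, or igraph.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  g <- if (inherits(graph, "weighted_projection")) graph$graph else graph
  if (!igraph::is_igraph(g)) stop("not a graph object", call. = FALSE)
  if (format == "graphml") {
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    e <- igraph::as_data_frame(g, "edges")
    if (is.null(e$weight)) e$weight <- 1
    utils::write.table(e[c("from", "to", "weight")], path,
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
import_graph <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    e <- utils::read.table(path, header = FALSE,
                           col.names = c("from", "to", "weight"),
                           colClasses = c("character", "character", "numeric"))
    g <- igraph::graph_from_data_frame(e[1:2], directed = FALSE)
    igraph::E(g)$weight <- e$weight
    g
  }
}
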