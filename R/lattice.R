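#' Non-periodic square-lattice topology
#'
#' Builds the neighbour structure of an `L x L` grid without periodic
#' boundary conditions. Sites are numbered 1..N in row-major order
#' (site `i` sits at row `(i - 1) %/% L + 1`, column `(i - 1) %% L + 1`).
#' With the von Neumann neighbourhood corners have degree 2, other border
#' sites degree 3 and interior sites degree 4.
#'
#' @param L Lattice side, integer `>= 2`.
#' @param neighborhood `"von_neumann"` (4 orthogonal neighbours, default) or
#'   `"moore"` (8 neighbours including diagonals).
#' @return An object of class `lattice_topology`: a list with `L`, `N`,
#'   `neighborhood`, `nbrs` (list of integer neighbour vectors), and
#'   `edges` (two-column matrix of undirected edges, `i < j`).
#' @examples
#' top <- lattice_topology(3)
#' lengths(top$nbrs)  # degrees: corners 2, edges 3, centre 4
#' @export
lattice_topology <- function(L, neighborhood = c("von_neumann", "moore")) {
  neighborhood <- match.arg(neighborhood)
  L <- as.integer(L)
  if (length(L) != 1 || is.na(L) || L < 2) stop("`L` must be an integer >= 2")
  N <- L * L
  row <- (seq_len(N) - 1L) %/% L + 1L
  col <- (seq_len(N) - 1L) %% L + 1L
  offsets <- if (neighborhood == "von_neumann")
    cbind(dr = c(-1L, 1L, 0L, 0L), dc = c(0L, 0L, -1L, 1L))
  else
    cbind(dr = rep(c(-1L, 0L, 1L), each = 3)[-5L],
          dc = rep(c(-1L, 0L, 1L), times = 3)[-5L])

  nbrs <- lapply(seq_len(N), function(i) {
    r <- row[i] + offsets[, "dr"]
    c <- col[i] + offsets[, "dc"]
    ok <- r >= 1L & r <= L & c >= 1L & c <= L
    sort((r[ok] - 1L) * L + c[ok])
  })
  edges <- do.call(rbind, lapply(seq_len(N), function(i) {
    j <- nbrs[[i]][nbrs[[i]] > i]
    if (length(j)) cbind(i = rep(i, length(j)), j = j)
  }))
  structure(list(L = L, N = N, neighborhood = neighborhood,
                 nbrs = nbrs, edges = edges),
            class = "lattice_topology")
}

#' @export
print.lattice_topology <- function(x, ...) {
  cat(sprintf("<lattice_topology> %d x %d, %s, %d undirected edges\n",
              x$L, x$L, x$neighborhood, nrow(x$edges)))
  invisible(x)
}

# flat 0-based representation for the C++ engine
topology_flat <- function(topology) {
  deg <- lengths(topology$nbrs)
  list(flat = as.integer(unlist(topology$nbrs) - 1L),
       start = as.integer(c(0L, cumsum(deg))),
       edges0 = topology$edges - 1L)
}

#' Convert a lattice topology to an igraph graph
#'
#' @param topology A [lattice_topology()].
#' @return An undirected igraph graph on `N` vertices.
#' @export
lattice_graph <- function(topology) {
  igraph::graph_from_edgelist(topology$edges, directed = FALSE)
}
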