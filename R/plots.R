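#' Lattice view of a culture state
#'
#' Draws the `L x L` grid with one point per agent (coloured by full
#' culture vector) and each lattice edge styled by how much its endpoints
#' agree, generalising the classic four classes to any `F`:
#' all `F` features shared — no line; more than half — dotted; up to half —
#' dashed; none — thick solid (a frozen boundary).
#'
#' @param state An `axelrod_state`.
#' @param topology A [lattice_topology()]; defaults to the von Neumann grid
#'   implied by the state.
#' @param point_size Agent marker size.
#' @return A ggplot object.
#' @export
plot_lattice <- function(state, topology = NULL, point_size = 3) {
  if (is.na(state$L)) stop("state has no lattice embedding", call. = FALSE)
  if (is.null(topology)) topology <- lattice_topology(state$L)
  tr <- state$traits
  L <- state$L
  pos <- tibble::tibble(agent = seq_len(nrow(tr)),
                        x = (seq_len(nrow(tr)) - 1L) %% L + 1L,
                        y = L - (seq_len(nrow(tr)) - 1L) %/% L)
  culture <- apply(tr, 1, paste, collapse = "")
  e <- tibble::as_tibble(topology$edges)
  e$shared <- vapply(seq_len(nrow(e)),
                     function(r) shared_feature_count(tr[e$i[r], ], tr[e$j[r], ]),
                     integer(1))
  e$class <- edge_agreement_class(e$shared, state$F)
  e <- dplyr::left_join(e, pos, by = c(i = "agent")) |>
    dplyr::left_join(pos, by = c(j = "agent"), suffix = c("", "_j")) |>
    dplyr::filter(.data$class != "all shared")

  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_j, yend = .data$y_j,
                   linetype = .data$class, linewidth = .data$class),
      colour = "grey30") +
    ggplot2::geom_point(
      data = pos, ggplot2::aes(.data$x, .data$y, colour = culture),
      size = point_size, show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(linetype = "agreement", linewidth = "agreement")
  if (nrow(e) > 0)
    p <- p +
      ggplot2::scale_linetype_manual(
        values = c("most shared" = "dotted", "some shared" = "dashed",
                   "none shared" = "solid"), drop = FALSE) +
      ggplot2::scale_linewidth_manual(
        values = c("most shared" = 0.4, "some shared" = 0.4,
                   "none shared" = 1.4), drop = FALSE)
  p
}

# shared-feature class per edge, parameterised by F:
# F shared -> "all shared"; (F/2, F) -> "most shared"; (0, F/2] -> "some
# shared"; 0 -> "none shared"
edge_agreement_class <- function(shared, F) {
  cls <- ifelse(shared == F, "all shared",
         ifelse(shared > F / 2, "most shared",
         ifelse(shared > 0, "some shared", "none shared")))
  factor(cls, levels = c("all shared", "most shared", "some shared",
                         "none shared"))
}

#' Bipartite view of a culture state
#'
#' Agents in one column, attitude (feature, trait) nodes in the other,
#' attitude nodes coloured by feature; an edge per holding. Deterministic
#' given the state.
#'
#' @param state An `axelrod_state`.
#' @param all_nodes Include unheld attitude nodes (fixed layout).
#' @return A ggplot object.
#' @export
plot_bipartite <- function(state, all_nodes = FALSE) {
  g <- build_bipartite(state, all_nodes = all_nodes)
  v <- tibble::as_tibble(igraph::as_data_frame(g, "vertices"))
  agents <- v[!v$type, ]
  atts <- v[v$type, ]
  agents$x <- 0; agents$y <- seq_len(nrow(agents))
  atts <- dplyr::arrange(atts, .data$feature, .data$trait)
  atts$x <- 1
  atts$y <- seq(1, max(nrow(agents), 2), length.out = max(nrow(atts), 2))[seq_len(nrow(atts))]
  pos <- dplyr::bind_rows(agents, atts)
  e <- tibble::as_tibble(igraph::as_data_frame(g, "edges")) |>
    dplyr::left_join(pos[c("name", "x", "y")], by = c(from = "name")) |>
    dplyr::left_join(pos[c("name", "x", "y")], by = c(to = "name"),
                     suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = e, ggplot2::aes(x = .data$x, y = .data$y,
                             xend = .data$x_to, yend = .data$y_to),
      colour = "grey70", linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_point(data = agents, ggplot2::aes(.data$x, .data$y),
                        size = 1.5, colour = "grey20") +
    ggplot2::geom_point(
      data = atts,
      ggplot2::aes(.data$x, .data$y, colour = factor(.data$feature)),
      size = 3) +
    ggplot2::labs(colour = "feature") +
    ggplot2::theme_void()
}

#' Plot a one-mode projection
#'
#' Edges coloured by weight class — by default the white/blue/red
#' strongest-to-weakest scheme on a dark background. Attitude projections
#' use the tercile bins of [bin_edge_weights()]; agent projections may
#' instead be classed by agreement level (all `F` shared, `F - 1`, fewer).
#' Layout is a seeded Fruchterman-Reingold embedding, so repeated calls
#' with the same seed give identical figures.
#'
#' @param projection A `weighted_projection`.
#' @param class_by `"bin"` (weight terciles) or `"agreement"` (agent
#'   projections only).
#' @param F Total feature count, required for `class_by = "agreement"`.
#' @param giant_component_only Drop all but the largest component before
#'   plotting (display only; exported graphs keep every node).
#' @param layout_seed Seed for the layout.
#' @param colours Vector of edge colours, strongest class first.
#' @return A ggplot object.
#' @export
plot_projection <- function(projection,
                            class_by = c("bin", "agreement"),
                            F = NULL,
                            giant_component_only = FALSE,
                            layout_seed = 42,
                            colours = c("white", "#4f8fdd", "#d64541")) {
  class_by <- match.arg(class_by)
  g <- projection$graph
  if (class_by == "bin" && is.null(igraph::E(g)$bin))
    g <- bin_edge_weights(projection)$graph
  if (giant_component_only) {
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, which(comp$membership ==
                                             which.max(comp$csize)))
  }
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  v <- tibble::as_tibble(igraph::as_data_frame(g, "vertices"))
  v$x <- xy[, 1]; v$y <- xy[, 2]
  e <- tibble::as_tibble(igraph::as_data_frame(g, "edges"))
  if (nrow(e) > 0) {
    if (class_by == "agreement") {
      if (is.null(F)) stop("supply `F` for agreement classes", call. = FALSE)
      e$class <- agreement_class(e$weight, F)
    } else {
      e$class <- factor(c("bottom", "middle", "top")[e$bin],
                        levels = c("top", "middle", "bottom"))
    }
    e <- dplyr::left_join(e, v[c("name", "x", "y")], by = c(from = "name")) |>
      dplyr::left_join(v[c("name", "x", "y")], by = c(to = "name"),
                       suffix = c("", "_to"))
  }
  pal <- colours[seq_len(nlevels(if (nrow(e)) e$class else factor(0)))]
  p <- ggplot2::ggplot()
  if (nrow(e) > 0)
    p <- p + ggplot2::geom_segment(
      data = e, ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_to,
                             yend = .data$y_to, colour = .data$class),
      linewidth = 0.4)
  p +
    ggplot2::geom_point(data = v, ggplot2::aes(.data$x, .data$y),
                        colour = "grey80", size = 1.5) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE,
                                 na.value = "grey50") +
    ggplot2::theme_void() +
    ggplot2::theme(panel.background = ggplot2::element_rect(fill = "grey10"),
                   legend.position = "bottom") +
    ggplot2::labs(colour = if (class_by == "bin") "weight tercile"
                  else "shared features")
}

# agreement classes for agent-projection display: all F, F-1, fewer
agreement_class <- function(weight, F) {
  cls <- ifelse(weight == F, sprintf("all %d", F),
         ifelse(weight == F - 1, sprintf("%d shared", F - 1), "fewer"))
  factor(cls, levels = c(sprintf("all %d", F), sprintf("%d shared", F - 1),
                         "fewer"))
}

#' Plot ensemble summaries
#'
#' `kind = "means"` draws mean cluster count against `F`, one line per
#' agreement threshold `a`; `kind = "density"` draws the discrete
#' cluster-count densities per `a` for a fixed `F`.
#'
#' @param result An `axelrod_ensemble` (or runs tibble).
#' @param kind `"means"` or `"density"`.
#' @param F Feature count selecting the density cell(s).
#' @return A ggplot object.
#' @export
plot_ensemble <- function(result, kind = c("means", "density"), F = NULL) {
  kind <- match.arg(kind)
  df <- tibble::as_tibble(result)
  if (kind == "means") {
    tab <- mean_clusters_table(df)
    ggplot2::ggplot(tab, ggplot2::aes(.data$F, .data$mean_clusters,
                                      colour = factor(.data$a))) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_clusters - .data$se,
                                          ymax = .data$mean_clusters + .data$se),
                             width = 0.15) +
      ggplot2::labs(x = "features F", y = "mean number of clusters",
                    colour = "a") +
      ggplot2::theme_minimal()
  } else {
    if (!is.null(F)) df <- df[df$F %in% F, ]
    dens <- dplyr::group_by(df, .data$a) |>
      dplyr::group_modify(~ cluster_density(.x)) |>
      dplyr::ungroup()
    ggplot2::ggplot(dens, ggplot2::aes(.data$n_clusters, .data$density,
                                       colour = factor(.data$a))) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(x = "number of clusters", y = "probability density",
                    colour = "a") +
      ggplot2::theme_minimal()
  }
}

#' @rdname plot_lattice
#' @param object,... `autoplot` dispatch arguments.
#' @export
autoplot.axelrod_state <- function(object, ...) plot_lattice(object, ...)

#' @rdname plot_ensemble
#' @param object,... `autoplot` dispatch arguments.
#' @export
autoplot.axelrod_ensemble <- function(object, ...) plot_ensemble(object, ...)

#' Save a plot deterministically
#'
#' Writes a ggplot to PNG or SVG through the base grDevices devices (no
#' extra graphics backends), so repeated invocations on the same inputs
#' produce identical vector output.
#'
#' @param plot A ggplot object.
#' @param path Output path ending in `.png` or `.svg`.
#' @param width,height Size in inches.
#' @return `path`, invisibly.
#' @export
save_plot <- function(plot, path, width = 7, height = 6) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path, width = width, height = height, units = "in",
                   res = 150)
  } else if (ext == "svg") {
    grDevices::svg(path, width = width, height = height)
  } else {
    stop("output format must be png or svg", call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  print(plot)
  invisible(path)
}
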