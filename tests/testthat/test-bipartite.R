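test_that("the bipartite graph records exactly one holding per agent and feature", {
  # consensus: N = 100, F = 3 -> 3 attitude nodes of degree 100, 300 edges
  st <- axelrod_state(matrix(2L, 100, 3), q = 5)
  g <- build_bipartite(st)
  expect_equal(igraph::ecount(g), 300)
  type <- igraph::V(g)$type
  expect_equal(sum(type), 3)
  expect_true(all(igraph::degree(g, igraph::V(g)[type]) == 100))
  # random states: totality and tally oracle
  for (s in 1:5) {
    st <- random_state(36, 4, 3, seed = s)
    g <- build_bipartite(st)
    expect_equal(igraph::ecount(g), 36 * 4)
    type <- igraph::V(g)$type
    expect_true(all(igraph::degree(g, igraph::V(g)[!type]) == 4))
    expect_equal(sum(igraph::degree(g, igraph::V(g)[type])), 36 * 4)
    # attitude degree = independent column-value tally
    v <- igraph::as_data_frame(g, "vertices")
    att <- v[v$type, ]
    for (r in seq_len(nrow(att))) {
      expect_equal(
        unname(igraph::degree(g, att$name[r])),
        sum(st$traits[, att$feature[r]] == att$trait[r]))
    }
    # two-mode property: every edge joins an agent to an attitude
    e <- igraph::as_edgelist(g)
    is_att <- function(x) grepl(":", x)
    expect_true(all(xor(is_att(e[, 1]), is_att(e[, 2]))))
  }
  # all_nodes includes every (feature, trait) combination
  g_all <- build_bipartite(random_state(9, 2, 4, seed = 1), all_nodes = TRUE)
  expect_equal(sum(igraph::V(g_all)$type), 2 * 4)
})

test_that("attitude projection counts co-holding agents and never links within a feature", {
  # consensus: clique on F attitudes, every weight N
  st <- axelrod_state(matrix(0L, 25, 3), q = 5)
  p <- attitude_projection(build_bipartite(st))
  expect_equal(nrow(p$edges), 3)
  expect_true(all(p$edges$weight == 25))
  # two agents (0,0) and (1,1): two disjoint weight-1 edges
  st2 <- axelrod_state(rbind(c(0L, 0L), c(1L, 1L)), q = 2)
  p2 <- attitude_projection(build_bipartite(st2))
  expect_equal(nrow(p2$edges), 2)
  expect_true(all(p2$edges$weight == 1))
  # random states vs O(N F^2) counting oracle
  for (s in 1:5) {
    st <- random_state(25, 4, 3, seed = 10 + s)
    p <- attitude_projection(build_bipartite(st))
    v <- p$nodes
    feat_of <- stats::setNames(v$feature, v$name)
    expect_true(all(feat_of[p$edges$from] != feat_of[p$edges$to]))
    oracle <- oracle_attitude_weights(st$traits)
    expect_equal(nrow(p$edges), length(oracle))
    for (r in seq_len(nrow(p$edges))) {
      ends <- c(p$edges$from[r], p$edges$to[r])
      ends <- ends[order(feat_of[ends])]
      expect_equal(p$edges$weight[r], oracle[[paste(ends, collapse = "--")]])
    }
  }
})

test_that("agent projection weights equal pairwise shared-feature counts", {
  st <- axelrod_state(matrix(3L, 16, 4), q = 5)
  p <- agent_projection(build_bipartite(st))
  expect_equal(nrow(p$edges), choose(16, 2))   # complete graph
  expect_true(all(p$edges$weight == 4))
  # zero shared features: no edge
  st2 <- axelrod_state(rbind(c(0L, 1L, 2L), c(3L, 4L, 0L)), q = 5)
  expect_equal(nrow(agent_projection(build_bipartite(st2))$edges), 0)
  for (s in 1:5) {
    st <- random_state(25, 3, 3, seed = 20 + s)
    p <- agent_projection(build_bipartite(st))
    key <- function(x) as.integer(sub("a", "", x))
    W <- matrix(0L, 25, 25)
    W[cbind(key(p$edges$from), key(p$edges$to))] <- p$edges$weight
    W <- pmax(W, t(W))
    for (i in 1:24) for (j in (i + 1):25)
      expect_equal(W[i, j],
                   oracle_shared(st$traits[i, ], st$traits[j, ]))
    # min_weight = F components match the identical-culture classes
    pF <- agent_projection(build_bipartite(st), min_weight = 3)
    comp <- igraph::components(pF$graph)
    expect_equal(comp$no, count_clusters(st)$n_clusters)
    expect_equal(sort(as.integer(comp$csize), decreasing = TRUE),
                 count_clusters(st)$sizes)
  }
})

test_that("weight bins split edges into terciles with ties falling low", {
  mk <- function(w) {
    g <- igraph::make_ring(length(w) + 1, circular = FALSE)
    igraph::E(g)$weight <- w
    bin_edge_weights(new_proj <- structure(
      list(graph = g, type = "agent",
           nodes = tibble::tibble(), edges = tibble::tibble()),
      class = "weighted_projection"))
  }
  expect_equal(igraph::E(mk(c(5, 5, 5, 5))$graph)$bin, rep(1L, 4))
  expect_equal(igraph::E(mk(c(1, 2, 3))$graph)$bin, 1:3)
  set.seed(41)
  for (r in 1:20) {
    w <- sample.int(20, sample(3:30, 1), replace = TRUE)
    b <- mk(w)
    bins <- igraph::E(b$graph)$bin
    bounds <- b$bin_boundaries
    expect_true(all(bins %in% 1:3))
    # monotone in weight
    expect_true(all(diff(bins[order(w)]) >= 0))
    # each edge obeys its bin's boundaries, ties assigned low
    for (i in seq_along(w)) {
      expect_lte(w[i], bounds[bins[i] + 1])
      if (bins[i] > 1) expect_gt(w[i], bounds[bins[i]])
    }
  }
  # empty edge set: empty labelling, no error
  st2 <- axelrod_state(rbind(c(0L, 1L), c(2L, 3L)), q = 4)
  p0 <- bin_edge_weights(agent_projection(build_bipartite(st2)))
  expect_equal(nrow(p0$edges), 0)
})

test_that("graphs round-trip losslessly through GraphML and edge lists", {
  st <- random_state(16, 3, 4, seed = 77)
  g <- build_bipartite(st)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, f, "graphml")
  g2 <- import_graph(f, "graphml")
  expect_equal(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))
  el <- function(x) {
    e <- igraph::as_edgelist(x)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_equal(el(g2), el(g))
  # consensus graph file carries N + F nodes
  gc <- build_bipartite(axelrod_state(matrix(0L, 9, 2), q = 3))
  fc <- withr::local_tempfile(fileext = ".graphml")
  export_graph(gc, fc, "graphml")
  expect_equal(igraph::vcount(import_graph(fc, "graphml")), 9 + 2)
  # projection weights survive the edge-list round trip
  p <- attitude_projection(build_bipartite(st))
  fe <- withr::local_tempfile(fileext = ".txt")
  export_graph(p, fe, "edgelist")
  p2 <- import_graph(fe, "edgelist")
  e_in <- igraph::as_data_frame(p2, "edges")
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_equal(e_in$weight[order(key(e_in))],
               p$edges$weight[order(key(p$edges))])
  expect_error(export_graph(p, fe, "gexf"), "arg")
})
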