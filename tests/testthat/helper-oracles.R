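# Brute-force oracles, kept deliberately independent of the package's
# implementation paths (plain loops, no igraph, no C++).

random_state <- function(N, F, q, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  axelrod_state(matrix(sample.int(q, N * F, replace = TRUE) - 1L, N, F), q = q)
}

# a state part-way to absorption, for mid-run property tests
midrun_state <- function(L, F, q, a = NULL, mode = "standard", seed = 1,
                         steps = 50 * L * L) {
  cfg <- axelrod_config(L = L, F = F, q = q, a = a, mode = mode,
                        max_steps = steps, check_every = steps)
  suppressWarnings(run_to_absorption(cfg, seed = seed))$final_state
}

oracle_shared <- function(u, v) {
  s <- 0L
  for (k in seq_along(u)) if (u[k] == v[k]) s <- s + 1L
  s
}

# exhaustive event enumeration: could ANY (i, j, feature) event change the
# state? mirrors the dynamics definition with raw loops
oracle_can_change <- function(traits, nbrs, mode, a, selection_rule = "within_threshold") {
  N <- nrow(traits); F <- ncol(traits)
  for (i in seq_len(N)) {
    for (j in nbrs[[i]]) {
      d <- abs(traits[i, ] - traits[j, ])
      p <- if (mode == "standard") sum(d == 0) / F else sum(d <= a) / F
      if (p <= 0) next
      candidates <- if (mode == "threshold" && selection_rule == "within_threshold")
        which(d > 0 & d <= a) else which(d > 0)
      for (k in candidates) {
        permitted <- if (mode == "threshold" && selection_rule == "literal_two_stage")
          d[k] <= a else TRUE
        if (permitted && traits[i, k] != traits[j, k]) return(TRUE)
      }
    }
  }
  FALSE
}

oracle_distinct_rows <- function(traits) {
  keys <- apply(traits, 1, paste, collapse = "|")
  tab <- table(keys)
  list(n = length(tab), sizes = sort(as.integer(tab), decreasing = TRUE))
}

# number of agents co-holding both (feature, trait) attitudes, O(N F^2)
oracle_attitude_weights <- function(traits) {
  N <- nrow(traits); F <- ncol(traits)
  out <- list()
  for (i in seq_len(N)) {
    for (k1 in seq_len(F - 1)) {
      for (k2 in (k1 + 1):F) {
        key <- paste0("f", k1, ":t", traits[i, k1], "--",
                      "f", k2, ":t", traits[i, k2])
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# union-find over all agent pairs with shared features >= F - m
oracle_relaxed_components <- function(traits, m) {
  N <- nrow(traits); F <- ncol(traits)
  parent <- seq_len(N)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      if (oracle_shared(traits[i, ], traits[j, ]) >= F - m) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(N), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}
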