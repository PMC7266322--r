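#' Number of features two agents hold in common
#'
#' @param vec_i,vec_j Length-`F` trait vectors.
#' @return Integer in `[0, F]`.
#' @examples
#' shared_feature_count(c(0, 1, 2), c(0, 1, 4))  # 2
#' @export
shared_feature_count <- function(vec_i, vec_j) {
  if (length(vec_i) != length(vec_j))
    stop("trait vectors must have the same length", call. = FALSE)
  sum(vec_i == vec_j)
}

#' Features eligible for copying in one interaction
#'
#' In standard mode these are the differing features. In threshold mode with
#' the default `within_threshold` rule they are the differing features whose
#' trait distance is within the agreement threshold; under
#' `literal_two_stage` the candidate is drawn among all differing features
#' and the threshold is checked afterwards (in [attempt_interaction()]).
#'
#' @param vec_i,vec_j Length-`F` trait vectors.
#' @param config An [axelrod_config()].
#' @return Integer vector of feature indices (1-based), possibly empty.
#' @export
eligible_features <- function(vec_i, vec_j, config) {
  assert_config(config)
  if (length(vec_i) != length(vec_j))
    stop("trait vectors must have the same length", call. = FALSE)
  d <- abs(vec_i - vec_j)
  if (config$mode == "threshold" && config$selection_rule == "within_threshold")
    which(d > 0 & d <= config$a)
  else
    which(d > 0)
}

#' Probability that a chosen pair interacts
#'
#' Standard mode: the number of common features over `F` (Axelrod's
#' homophily rule). Threshold mode: the number of features whose trait
#' distance is at most `a` over `F` — distance-0 features count, so the
#' threshold-mode probability is never below the standard one.
#'
#' @inheritParams eligible_features
#' @return A probability in `[0, 1]`.
#' @examples
#' cfg <- axelrod_config(L = 2, F = 3, q = 5, mode = "standard")
#' interaction_probability(c(0, 1, 2), c(0, 1, 4), cfg)  # 2/3
#' @export
interaction_probability <- function(vec_i, vec_j, config) {
  assert_config(config)
  if (length(vec_i) != length(vec_j))
    stop("trait vectors must have the same length", call. = FALSE)
  F <- length(vec_i)
  if (config$mode == "standard")
    shared_feature_count(vec_i, vec_j) / F
  else
    sum(abs(vec_i - vec_j) <= config$a) / F
}

#' Could any future event between two agents change a trait?
#'
#' Standard mode: true iff `0 < shared features < F`. Threshold mode: true
#' iff some feature differs by at most `a` (such a feature also makes the
#' interaction probability positive).
#'
#' @inheritParams eligible_features
#' @return Logical.
#' @export
is_pair_active <- function(vec_i, vec_j, config) {
  assert_config(config)
  if (config$mode == "standard") {
    s <- shared_feature_count(vec_i, vec_j)
    s > 0 && s < length(vec_i)
  } else {
    d <- abs(vec_i - vec_j)
    any(d > 0 & d <= config$a)
  }
}

# one unif draw -> index in 1..n; mirrors the C++ engine's draw_index
draw_index1 <- function(n) {
  k <- as.integer(stats::runif(1) * n)
  if (k >= n) k <- n - 1L
  k + 1L
}

#' Perform one elementary event
#'
#' One time step of the dynamics: agent `i` is drawn uniformly, then one of
#' its lattice neighbours `j`; with probability
#' [interaction_probability()] the pair interacts and `i` copies `j`'s trait
#' on one candidate feature (drawn uniformly from [eligible_features()]).
#' Under `literal_two_stage` the copy additionally requires the candidate's
#' trait distance to be within the threshold; otherwise the event is a null
#' interaction. `step_count` always advances by exactly 1 and at most one
#' matrix entry changes.
#'
#' RNG-consumption protocol (shared with the compiled engine, so both
#' produce identical trajectories from the same seed): one uniform each for
#' `i`, `j` and the interaction Bernoulli, plus one for the candidate
#' feature only when the pair interacts and the eligible set is nonempty.
#'
#' @param state An `axelrod_state`.
#' @param topology A [lattice_topology()].
#' @param config An [axelrod_config()].
#' @return A list: `state` (updated), `i`, `j`, `interacted` (logical),
#'   `copied_feature` (index or `NA`).
#' @export
attempt_interaction <- function(state, topology, config) {
  assert_config(config)
  tr <- state$traits
  N <- nrow(tr)
  i <- draw_index1(N)
  nb <- topology$nbrs[[i]]
  j <- nb[draw_index1(length(nb))]
  p <- interaction_probability(tr[i, ], tr[j, ], config)
  interacted <- stats::runif(1) < p
  copied <- NA_integer_
  if (interacted) {
    elig <- eligible_features(tr[i, ], tr[j, ], config)
    if (length(elig) > 0) {
      k <- elig[draw_index1(length(elig))]
      ok <- TRUE
      if (config$mode == "threshold" &&
          config$selection_rule == "literal_two_stage")
        ok <- abs(tr[i, k] - tr[j, k]) <= config$a
      if (ok) {
        tr[i, k] <- tr[j, k]
        copied <- k
      }
    }
  }
  state$traits <- tr
  state$step_count <- state$step_count + 1
  list(state = state, i = i, j = j, interacted = interacted,
       copied_feature = copied)
}

#' Is a state absorbing?
#'
#' True iff no permitted event can change any trait: every lattice edge is
#' inactive under [is_pair_active()] (exhaustive scan of the edge list).
#'
#' @inheritParams attempt_interaction
#' @return Logical.
#' @export
is_absorbing <- function(state, topology, config) {
  assert_config(config)
  tr <- state$traits
  e <- topology$edges
  for (r in seq_len(nrow(e))) {
    if (is_pair_active(tr[e[r, 1], ], tr[e[r, 2], ], config)) return(FALSE)
  }
  TRUE
}

#' Run the dynamics to the absorbing state
#'
#' Repeats elementary events until no event can change the state (checked
#' every `check_every` events) or `max_steps` is reached. Fully reproducible
#' from `config$seed` (or the `seed` argument): the same seed yields a
#' bit-identical result.
#'
#' @param config An [axelrod_config()].
#' @param seed Overrides `config$seed` if given.
#' @param init Optional `axelrod_state` to start from; by default the state
#'   is seeded uniformly at random via [init_random()] (after `set.seed`),
#'   the model's standard random initial condition.
#' @param topology Optional precomputed [lattice_topology()] (saves rebuild
#'   in ensembles).
#' @return An object of class `axelrod_run`: list with `final_state`,
#'   `initial_state`, `steps`, `copies`, `absorbed`, `config`, `seed`.
#'   If `max_steps` is hit first, `absorbed` is `FALSE` and a warning is
#'   raised; the result is still returned.
#' @examples
#' cfg <- axelrod_config(L = 3, F = 1, q = 2, a = 1, mode = "threshold")
#' run <- run_to_absorption(cfg, seed = 1)
#' run$absorbed                       # TRUE: a = q - 1 forces consensus
#' count_clusters(run$final_state)$n_clusters
#' @export
run_to_absorption <- function(config, seed = NULL, init = NULL,
                              topology = NULL) {
  assert_config(config)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  if (is.null(topology)) topology <- lattice_topology(config$L, config$neighborhood)
  if (is.null(init)) init <- init_random(config)
  stopifnot(nrow(init$traits) == config$N, ncol(init$traits) == config$F)

  flat <- topology_flat(topology)
  mode <- if (config$mode == "standard") 0L else 1L
  rule <- if (config$selection_rule == "within_threshold") 0L else 1L
  a <- if (is.na(config$a)) 0L else config$a
  res <- cpp_run_engine(init$traits, flat$flat, flat$start, flat$edges0,
                        config$q, a, mode, rule,
                        config$max_steps, config$check_every)
  if (!res$absorbed)
    warning("max_steps = ", format(config$max_steps),
            " reached before absorption", call. = FALSE)
  final <- axelrod_state(res$traits, q = config$q, L = config$L,
                         step_count = init$step_count + res$steps)
  structure(list(final_state = final, initial_state = init,
                 steps = res$steps, copies = res$copies,
                 absorbed = res$absorbed, config = config, seed = seed),
            class = "axelrod_run")
}

#' @export
print.axelrod_run <- function(x, ...) {
  cat(sprintf("<axelrod_run> %s%s: %s after %g events (%g copies)\n",
              x$config$mode,
              if (x$config$mode == "threshold")
                sprintf(" (a = %d)", x$config$a) else "",
              if (x$absorbed) "absorbed" else "NOT absorbed (max_steps)",
              x$steps, x$copies))
  invisible(x)
}

#' Tidy / summarise a finished run
#'
#' `tidy()` returns the final state in long form (one row per agent and
#' feature); `glance()` returns a one-row summary with the run's headline
#' numbers, including the non-spatial opinion-based-group count.
#'
#' @param x An `axelrod_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.axelrod_run <- function(x, ...) tidy(x$final_state)

#' @rdname tidy.axelrod_run
#' @export
glance.axelrod_run <- function(x, ...) {
  cl <- count_clusters(x$final_state)
  tibble::tibble(
    L = x$config$L, N = x$config$N, F = x$config$F, q = x$config$q,
    a = x$config$a, mode = x$config$mode,
    seed = if (is.null(x$seed)) NA_integer_ else x$seed,
    steps = x$steps, copies = x$copies, absorbed = x$absorbed,
    n_clusters = cl$n_clusters, largest_cluster = cl$largest,
    mean_cluster_size = mean(cl$sizes), n_isolates = cl$n_isolates
  )
}
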