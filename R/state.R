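#' Culture state of the agent population
#'
#' An `axelrod_state` holds the entire dynamical state: an `N x F` integer
#' matrix of traits (entry `(i, k)` is agent `i`'s trait on feature `k`,
#' in `0..q-1`), the trait range `q`, the lattice side `L`, and the number
#' of elementary events elapsed (`step_count`).
#'
#' @param traits Integer matrix, `N x F`, entries in `0..q-1`.
#' @param q Traits per feature.
#' @param L Lattice side with `L^2 = nrow(traits)`.
#' @param step_count Elementary events elapsed (default 0).
#' @return An object of class `axelrod_state`.
#' @export
axelrod_state <- function(traits, q, L = NULL, step_count = 0) {
  traits <- as.matrix(traits)
  storage.mode(traits) <- "integer"
  dimnames(traits) <- NULL
  N <- nrow(traits)
  if (is.null(L)) {
    # non-square populations (e.g. survey matrices) carry no lattice embedding
    L <- as.integer(round(sqrt(N)))
    if (L * L != N) L <- NA_integer_
  } else {
    L <- as.integer(L)
    if (is.na(L) || L * L != N)
      stop("nrow(traits) must equal L^2 (got N = ", N, ", L = ", L, ")",
           call. = FALSE)
  }
  q <- as.integer(q)
  if (anyNA(traits) || any(traits < 0L) || any(traits >= q))
    stop("all traits must be integers in 0..q-1", call. = FALSE)
  structure(list(traits = traits, q = q, L = L, F = ncol(traits),
                 step_count = as.numeric(step_count)),
            class = "axelrod_state")
}

#' Random initial culture state
#'
#' Assigns every (agent, feature) cell a trait drawn i.i.d. uniformly from
#' `0..q-1`, the model's standard random seeding.
#'
#' @param config An [axelrod_config()].
#' @param seed Optional seed; `NULL` (default) uses the current RNG state,
#'   so a preceding `set.seed()` makes the draw reproducible.
#' @return An `axelrod_state` with `step_count = 0`.
#' @examples
#' cfg <- axelrod_config(L = 4, F = 3, q = 5, mode = "standard")
#' st <- init_random(cfg, seed = 1)
#' dim(st$traits)
#' @export
init_random <- function(config, seed = NULL) {
  assert_config(config)
  if (!is.null(seed)) set.seed(seed)
  traits <- matrix(sample.int(config$q, config$N * config$F, replace = TRUE) - 1L,
                   nrow = config$N, ncol = config$F)
  axelrod_state(traits, q = config$q, L = config$L)
}

#' @export
print.axelrod_state <- function(x, ...) {
  cat(sprintf("<axelrod_state> N = %d agents (%d x %d lattice), F = %d, q = %d, %g events\n",
              nrow(x$traits), x$L, x$L, x$F, x$q, x$step_count))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a culture state into long form
#'
#' @param x An `axelrod_state`.
#' @param ... Unused.
#' @return A tibble with one row per (agent, feature) holding: `agent`,
#'   `row`, `col` (lattice position), `feature`, `trait` (0-based).
#' @export
tidy.axelrod_state <- function(x, ...) {
  N <- nrow(x$traits)
  tibble::tibble(
    agent = rep(seq_len(N), times = x$F),
    row = rep((seq_len(N) - 1L) %/% x$L + 1L, times = x$F),
    col = rep((seq_len(N) - 1L) %% x$L + 1L, times = x$F),
    feature = rep(seq_len(x$F), each = N),
    trait = as.integer(x$traits)
  )
}

#' Write / read a culture state as CSV plus a JSON sidecar
#'
#' The CSV holds the `N x F` trait matrix (one row per agent in row-major
#' lattice order, columns `f1..fF`, 0-based integer traits). A `.json`
#' sidecar records `q`, `L`, `step_count` and, if supplied, the generating
#' configuration.
#'
#' @param state An `axelrod_state`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @param config Optional `axelrod_config` echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_state <- function(state, path, config = NULL) {
  stopifnot(inherits(state, "axelrod_state"))
  df <- as.data.frame(state$traits)
  names(df) <- paste0("f", seq_len(ncol(df)))
  readr::write_csv(tibble::as_tibble(df), path)
  side <- list(q = state$q, L = state$L, F = state$F,
               step_count = state$step_count)
  if (!is.null(config)) side$config <- config_as_list(config)
  jsonlite::write_json(side, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  axelrod_state(as.matrix(df), q = side$q, L = side$L,
                step_count = side$step_count)
}

#' Read a survey-style N x F categorical matrix from CSV
#'
#' Accepts user data shaped like Likert-type survey responses: `N`
#' respondents (rows) each answering `F` items (columns) with one of `q`
#' ordered options. Values may be 0-based (`0..q-1`) or 1-based (`1..q`);
#' 1-based input is shifted down to the package's 0-based storage.
#'
#' @param path CSV path, one column per item, integer entries.
#' @param q Number of response options per item.
#' @return An `axelrod_state`. If `N` is not a perfect square the state has
#'   no lattice embedding (`L` is `NA`); cluster and bipartite statistics
#'   still apply, lattice dynamics and plots do not.
#' @export
read_culture_csv <- function(path, q) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m) || anyNA(m) || any(m != round(m)))
    stop("culture CSV must be all integers", call. = FALSE)
  storage.mode(m) <- "integer"
  if (min(m) >= 1L && max(m) <= q) m <- m - 1L
  if (min(m) < 0L || max(m) >= q)
    stop("trait values outside 0..q-1 (or 1..q)", call. = FALSE)
  axelrod_state(m, q = q)
}
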