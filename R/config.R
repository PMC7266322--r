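#' Simulation configuration
#'
#' Bundles every parameter of a single run: the lattice side `L`
#' (so there are `N = L^2` agents), the number of cultural features `F`
#' (survey items), the number of traits per feature `q` (ordered response
#' options, stored 0-based as `0..q-1`), the interaction `mode`, and, in
#' threshold mode, the agreement threshold `a` — the largest trait distance
#' at which a feature still counts towards interaction and may be copied
#' (a discrete latitude of acceptance).
#'
#' @param L Lattice side; the model runs on a non-periodic `L x L` grid.
#' @param F Number of features, integer `>= 1`.
#' @param q Traits per feature, integer `>= 2`.
#' @param a Agreement threshold, integer in `[0, q - 1]`. Required in
#'   threshold mode; must be omitted (or `NULL`) in standard mode, where it
#'   plays no role and is reported as `NA`.
#' @param mode `"standard"` (Axelrod's homophily rule) or `"threshold"`
#'   (ordinal agreement-threshold rule).
#' @param selection_rule How the candidate feature is chosen in threshold
#'   mode: `"within_threshold"` draws uniformly among differing features
#'   within the threshold (no wasted draws); `"literal_two_stage"` draws
#'   among all differing features and then rejects the copy if the trait
#'   distance exceeds `a`. Absorbing states coincide; transient kinetics
#'   differ.
#' @param neighborhood `"von_neumann"` (4-neighbour, default) or `"moore"`
#'   (8-neighbour).
#' @param max_steps Cap on elementary events (one event = one draw of an
#'   agent and a neighbour, whether or not anything changes).
#' @param check_every Absorbing-state scan cadence in events; defaults to
#'   `N * F`.
#' @param seed RNG seed used by [run_to_absorption()]; `NULL` leaves the
#'   current RNG state untouched.
#'
#' @return An object of class `axelrod_config`.
#' @examples
#' axelrod_config(L = 10, F = 3, q = 5, mode = "standard", seed = 1)
#' axelrod_config(L = 10, F = 6, q = 3, a = 1, mode = "threshold")
#' @export
axelrod_config <- function(L, F, q, a = NULL,
                           mode = c("standard", "threshold"),
                           selection_rule = c("within_threshold",
                                              "literal_two_stage"),
                           neighborhood = c("von_neumann", "moore"),
                           max_steps = 1e7,
                           check_every = NULL,
                           seed = NULL) {
  mode <- match.arg(mode)
  selection_rule <- match.arg(selection_rule)
  neighborhood <- match.arg(neighborhood)

  check_count <- function(x, nm, min = NULL, max = NULL) {
    if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x))
      stop("`", nm, "` must be a single integer", call. = FALSE)
    x <- as.integer(x)
    if (!is.null(min) && x < min)
      stop("`", nm, "` must be >= ", min, call. = FALSE)
    if (!is.null(max) && x > max)
      stop("`", nm, "` must be <= ", max, call. = FALSE)
    x
  }
  L <- check_count(L, "L", min = 2)
  F <- check_count(F, "F", min = 1)
  q <- check_count(q, "q", min = 2)
  if (mode == "threshold") {
    if (is.null(a))
      stop("threshold mode requires an agreement threshold `a`", call. = FALSE)
    a <- check_count(a, "a", min = 0, max = q - 1L)
  } else {
    if (!is.null(a) && !is.na(a))
      warning("`a` is unused in standard mode and will be reported as NA",
              call. = FALSE)
    a <- NA_integer_
  }
  if (!is.null(seed)) seed <- check_count(seed, "seed")
  max_steps <- as.numeric(max_steps)
  if (length(max_steps) != 1 || is.na(max_steps) || max_steps < 0)
    stop("`max_steps` must be a single non-negative number", call. = FALSE)
  if (is.null(check_every)) check_every <- as.numeric(L)^2 * F
  check_every <- max(1, as.numeric(check_every))

  structure(
    list(L = L, N = L * L, F = F, q = q, a = a, mode = mode,
         selection_rule = selection_rule, neighborhood = neighborhood,
         max_steps = max_steps, check_every = check_every, seed = seed),
    class = "axelrod_config"
  )
}

#' @export
print.axelrod_config <- function(x, ...) {
  cat("<axelrod_config>\n")
  cat(sprintf("  lattice      %d x %d (N = %d, %s)\n",
              x$L, x$L, x$N, x$neighborhood))
  cat(sprintf("  features     F = %d, traits q = %d\n", x$F, x$q))
  if (x$mode == "threshold")
    cat(sprintf("  mode         threshold (a = %d, %s)\n",
                x$a, x$selection_rule))
  else
    cat("  mode         standard\n")
  cat(sprintf("  max_steps    %g (absorbing check every %g events)\n",
              x$max_steps, x$check_every))
  if (!is.null(x$seed)) cat(sprintf("  seed         %d\n", x$seed))
  invisible(x)
}

is_axelrod_config <- function(x) inherits(x, "axelrod_config")

# plain list for JSON output; the unused threshold in standard mode is
# reported as null
config_as_list <- function(config) {
  x <- unclass(config)
  if (is.na(x$a)) x["a"] <- list(NULL)
  x
}

assert_config <- function(config) {
  if (!is_axelrod_config(config))
    stop("`config` must be created by axelrod_config()", call. = FALSE)
  invisible(config)
}

#' Read a configuration from a YAML or JSON file
#'
#' Flat keys matching the arguments of [axelrod_config()]. Values in
#' `overrides` (e.g. parsed CLI flags) take precedence over file values.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` to use
#'   only `overrides`.
#' @param overrides Named list of argument overrides.
#' @return An `axelrod_config`.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  keep <- intersect(names(vals), names(formals(axelrod_config)))
  do.call(axelrod_config, vals[keep])
}
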