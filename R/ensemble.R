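#' Specify an ensemble of simulation campaigns
#'
#' A grid of model configurations (over `F`, the agreement threshold `a`,
#' and optionally `q` and `L`) with `n_runs` independent runs per cell —
#' the design behind mean-cluster-versus-features curves and cluster-count
#' densities. Per-run seeds are derived from `master_seed` by a single
#' recorded `sample.int()` draw over cells in lexicographic order, so any
#' row can be re-run on its own.
#'
#' @param F_grid,a_grid,q_grid,L_grid Parameter grids (vectors); the full
#'   cross-product forms the cells.
#' @param n_runs Runs per cell (1,000 for headline curves; smaller for
#'   quick profiles).
#' @param master_seed Integer master seed.
#' @param mode,selection_rule,neighborhood,max_steps Passed to
#'   [axelrod_config()] for every cell.
#' @return An object of class `ensemble_spec`; `$cells` is a tibble with
#'   one row per grid cell.
#' @examples
#' ensemble_spec(F_grid = c(2, 4), a_grid = 1, q_grid = 5, L_grid = 10,
#'               n_runs = 10, master_seed = 1)
#' @export
ensemble_spec <- function(F_grid, a_grid, q_grid = 5, L_grid = 10,
                          n_runs = 1000, master_seed = 1,
                          mode = "threshold",
                          selection_rule = "within_threshold",
                          neighborhood = "von_neumann",
                          max_steps = 1e7) {
  cells <- tidyr::expand_grid(L = sort(unique(as.integer(L_grid))),
                              q = sort(unique(as.integer(q_grid))),
                              F = sort(unique(as.integer(F_grid))),
                              a = sort(unique(as.integer(a_grid)))) |>
    dplyr::filter(.data$a <= .data$q - 1 | mode == "standard")
  if (nrow(cells) == 0) stop("empty parameter grid", call. = FALSE)
  if (n_runs < 1) stop("`n_runs` must be >= 1", call. = FALSE)
  # validate every cell up front
  purrr::pwalk(cells, function(L, q, F, a)
    axelrod_config(L = L, F = F, q = q,
                   a = if (mode == "threshold") a else NULL,
                   mode = mode, selection_rule = selection_rule,
                   neighborhood = neighborhood, max_steps = max_steps))
  structure(list(cells = cells, n_runs = as.integer(n_runs),
                 master_seed = as.integer(master_seed), mode = mode,
                 selection_rule = selection_rule,
                 neighborhood = neighborhood, max_steps = max_steps),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf("<ensemble_spec> %d cells x %d runs (%s mode, master seed %d)\n",
              nrow(x$cells), x$n_runs, x$mode, x$master_seed))
  invisible(x)
}

ensemble_seeds <- function(spec) {
  set.seed(spec$master_seed)
  matrix(sample.int(2147483645L, nrow(spec$cells) * spec$n_runs),
         nrow = nrow(spec$cells), byrow = TRUE)
}

#' Run an ensemble of simulations
#'
#' Executes [run_to_absorption()] for every (cell, run) pair. Deterministic
#' given `master_seed`: cells are seeded independently, so results do not
#' depend on execution order.
#'
#' @param spec An [ensemble_spec()].
#' @param progress Print a line per cell as it completes.
#' @return An `axelrod_ensemble`: a tibble with one row per run —
#'   `F, q, a, L, mode, seed, n_clusters, largest_cluster,
#'   mean_cluster_size, n_isolates, steps, absorbed` — carrying the spec as
#'   an attribute. Runs that hit `max_steps` are kept with
#'   `absorbed = FALSE` (and surface in [glance()]), never dropped.
#' @export
run_ensemble <- function(spec, progress = FALSE) {
  stopifnot(inherits(spec, "ensemble_spec"))
  seeds <- ensemble_seeds(spec)
  cells <- spec$cells
  rows <- purrr::map_dfr(seq_len(nrow(cells)), function(ci) {
    cell <- cells[ci, ]
    cfg <- axelrod_config(L = cell$L, F = cell$F, q = cell$q,
                          a = if (spec$mode == "threshold") cell$a else NULL,
                          mode = spec$mode,
                          selection_rule = spec$selection_rule,
                          neighborhood = spec$neighborhood,
                          max_steps = spec$max_steps)
    top <- lattice_topology(cfg$L, cfg$neighborhood)
    out <- purrr::map_dfr(seq_len(spec$n_runs), function(ri) {
      res <- suppressWarnings(
        run_to_absorption(cfg, seed = seeds[ci, ri], topology = top))
      cl <- count_clusters(res$final_state)
      tibble::tibble(F = cell$F, q = cell$q,
                     a = if (spec$mode == "threshold") cell$a else NA_integer_,
                     L = cell$L, mode = spec$mode, run = ri,
                     seed = seeds[ci, ri],
                     n_clusters = cl$n_clusters, largest_cluster = cl$largest,
                     mean_cluster_size = mean(cl$sizes),
                     n_isolates = cl$n_isolates,
                     steps = res$steps, absorbed = res$absorbed)
    })
    if (progress)
      message(sprintf("cell %d/%d (L=%d F=%d q=%d a=%s) done",
                      ci, nrow(cells), cell$L, cell$F, cell$q, cell$a))
    out
  })
  structure(rows, class = c("axelrod_ensemble", class(tibble::tibble()))) |>
    `attr<-`("spec", spec)
}

#' Per-cell mean cluster counts
#'
#' @param result An `axelrod_ensemble` (or its runs tibble).
#' @return A tibble per (L, q, F, a): `mean_clusters`, standard error `se`,
#'   `n_runs`, plus means of the size statistics.
#' @export
mean_clusters_table <- function(result) {
  dplyr::group_by(tibble::as_tibble(result),
                  .data$L, .data$q, .data$F, .data$a) |>
    dplyr::summarise(
      mean_clusters = mean(.data$n_clusters),
      se = stats::sd(.data$n_clusters) / sqrt(dplyr::n()),
      mean_largest = mean(.data$largest_cluster),
      mean_size = mean(.data$mean_cluster_size),
      n_runs = dplyr::n(),
      n_unabsorbed = sum(!.data$absorbed),
      .groups = "drop")
}

#' Discrete density of cluster counts in one cell
#'
#' Exact normalised frequencies of the observed cluster counts (the
#' quantity behind the density panels); no smoothing is applied to the
#' integer counts themselves.
#'
#' @param result An `axelrod_ensemble`.
#' @param F,q,a,L Cell coordinates; any left `NULL` must be unique in the
#'   result.
#' @return A tibble with `n_clusters` and `density` summing to 1.
#' @export
cluster_density <- function(result, F = NULL, q = NULL, a = NULL, L = NULL) {
  df <- tibble::as_tibble(result)
  for (nm in c("F", "q", "a", "L")) {
    val <- get(nm)
    if (!is.null(val)) df <- df[df[[nm]] %in% val, ]
    else if (length(unique(df[[nm]])) > 1)
      stop("cell underdetermined: supply `", nm, "`", call. = FALSE)
  }
  if (nrow(df) == 0) stop("no runs match the requested cell", call. = FALSE)
  dplyr::count(df, .data$n_clusters, name = "count") |>
    dplyr::mutate(density = .data$count / sum(.data$count)) |>
    dplyr::select("n_clusters", "count", "density")
}

#' @export
glance.axelrod_ensemble <- function(x, ...) {
  spec <- attr(x, "spec")
  tibble::tibble(n_cells = nrow(spec$cells), n_runs = spec$n_runs,
                 total_runs = nrow(x),
                 master_seed = spec$master_seed, mode = spec$mode,
                 n_unabsorbed = sum(!x$absorbed),
                 mean_steps = mean(x$steps))
}

#' Write / read ensemble results
#'
#' `write_results()` writes `runs.csv` (one row per run), `summary.csv`
#' (per-cell means) and `spec.json` (grid, seeds scheme, master seed,
#' package version) into `dir`; `read_results()` reads them back so the
#' in-memory tables are reproduced.
#'
#' @param result An `axelrod_ensemble`.
#' @param dir Output directory (created if missing).
#' @return `write_results()`: `dir`, invisibly. `read_results()`: a list
#'   with `runs`, `summary`, `spec`.
#' @export
write_results <- function(result, dir) {
  spec <- attr(result, "spec")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(result), file.path(dir, "runs.csv"))
  readr::write_csv(mean_clusters_table(result), file.path(dir, "summary.csv"))
  meta <- list(
    cells = spec$cells, n_runs = spec$n_runs,
    master_seed = spec$master_seed, mode = spec$mode,
    selection_rule = spec$selection_rule, neighborhood = spec$neighborhood,
    max_steps = spec$max_steps,
    seed_scheme = "set.seed(master_seed); sample.int(2147483645, n_cells * n_runs) filled row-wise over cells in lexicographic (L, q, F, a) order",
    package_version = as.character(utils::packageVersion("axelgroup")))
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @rdname write_results
#' @export
read_results <- function(dir) {
  runs <- readr::read_csv(file.path(dir, "runs.csv"), show_col_types = FALSE)
  summ <- readr::read_csv(file.path(dir, "summary.csv"), show_col_types = FALSE)
  spec <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  list(runs = runs, summary = summ, spec = spec)
}
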