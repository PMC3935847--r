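#' Experiment configuration
#'
#' Bundles everything that determines an experiment: the network model and
#' its parameters (or a fixed user-supplied graph), the cascade tolerance,
#' the attack strategies and removal-fraction grid, the number of
#' realizations, and a master seed. A configuration plus its master seed
#' fully determines every result table (per-realization seeds are drawn once
#' from the master seed).
#'
#' @param model `"er"` or `"sf"` (ignored when `graph` is supplied).
#' @param n nodes per realization.
#' @param mean_degree target average degree `<k> = m / n`.
#' @param gamma power-law exponent (scale-free model only).
#' @param alpha cascade tolerance parameter.
#' @param strategies subset of `c("RA", "IA")`.
#' @param f_grid removal fractions in `[0, 1]`.
#' @param n_realizations independent realizations to average over.
#' @param master_seed integer master seed.
#' @param graph optional fixed `digraph` used for every realization
#'   (realizations then differ only in attack randomness).
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(model = c("er", "sf"), n = 500L, mean_degree = 3,
                              gamma = 2.5, alpha = 0.3,
                              strategies = c("RA", "IA"),
                              f_grid = seq(0, 0.8, by = 0.05),
                              n_realizations = 50L, master_seed = 1L,
                              graph = NULL) {
  model <- match.arg(model)
  if (!all(strategies %in% c("RA", "IA"))) stop("strategies must be RA and/or IA")
  if (any(f_grid < 0 | f_grid > 1)) stop("f_grid must lie in [0, 1]")
  if (n_realizations < 1L) stop("need at least one realization")
  if (alpha < 0) stop("alpha must be >= 0")
  if (!is.null(graph)) stopifnot_digraph(graph)
  structure(
    list(model = model, n = as.integer(n), mean_degree = mean_degree,
         gamma = gamma, alpha = alpha, strategies = strategies,
         f_grid = f_grid, n_realizations = as.integer(n_realizations),
         master_seed = as.integer(master_seed), graph = graph),
    class = "experiment_config"
  )
}

# Per-realization and per-cell seed streams, all derived once from the
# master seed so the whole experiment is reproducible byte-for-byte.
derive_seeds <- function(config, n_cells_per_real) {
  total <- config$n_realizations * (1L + n_cells_per_real)
  seeds <- withr::with_seed(config$master_seed,
                            sample.int(.Machine$integer.max - 1L, total))
  list(
    graph = seeds[seq_len(config$n_realizations)],
    cell = matrix(seeds[-seq_len(config$n_realizations)],
                  nrow = config$n_realizations)
  )
}

config_graph <- function(config, seed) {
  if (!is.null(config$graph)) return(config$graph)
  switch(config$model,
    er = generate_er(config$n, config$mean_degree, seed),
    sf = generate_sf(config$n, config$mean_degree, config$gamma, seed)
  )
}

#' Single highest-load-edge trigger experiment
#'
#' For each realization: build the network, compute initial loads and
#' capacities, remove the single highest-load edge, run the cascade, and
#' record the driver-node count and SCC edge count at every stage. Traces of
#' different lengths are aligned by stage index, shorter ones padded with
#' their terminal value, and averaged across realizations.
#'
#' @param config an [experiment_config()] (its `strategies`/`f_grid` are not
#'   used here).
#' @return a list of class `trigger_result`: `realizations` (one row per
#'   realization: intact/final driver counts, `delta_nd`, `total_failed`,
#'   `n_stages`), `stage_summary` (per-stage mean and standard error of
#'   `n_drivers` and `scc_edges`), and the config.
#' @export
single_trigger_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) stop("expected an `experiment_config`")
  seeds <- derive_seeds(config, n_cells_per_real = 1L)
  nd_traces <- list(); scc_traces <- list()
  rows <- vector("list", config$n_realizations)
  for (i in seq_len(config$n_realizations)) {
    g <- config_graph(config, seeds$graph[i])
    if (g$m == 0L) stop("realization ", i, " has no edges; cannot attack")
    loads <- compute_loads(g)
    caps <- assign_capacities(loads, config$alpha)
    trig <- highest_load_edge(g, loads, seed = seeds$cell[i, 1L])
    intact_nd <- driver_report(g)$n_drivers
    tr <- run_cascade(g, caps, trig)
    nd_traces[[i]] <- tr$stages$n_drivers
    scc_traces[[i]] <- tr$stages$scc_edges
    rows[[i]] <- data.frame(
      realization = i, seed = seeds$graph[i],
      intact_nd = intact_nd,
      final_nd = tr$stages$n_drivers[nrow(tr$stages)],
      delta_nd = tr$stages$n_drivers[nrow(tr$stages)] - intact_nd,
      total_failed = tr$total_failed,
      n_stages = nrow(tr$stages) - 1L,
      intact_scc_edges = scc_edge_count(g)
    )
  }
  structure(
    list(realizations = do.call(rbind, rows),
         stage_summary = summarize_traces(nd_traces, scc_traces),
         config = config),
    class = "trigger_result"
  )
}

# Align stage-indexed traces (pad with terminal value) and average.
summarize_traces <- function(nd_traces, scc_traces) {
  len <- max(vapply(nd_traces, length, integer(1)))
  pad <- function(x) c(x, rep(x[length(x)], len - length(x)))
  nd <- do.call(rbind, lapply(nd_traces, pad))
  scc <- do.call(rbind, lapply(scc_traces, pad))
  se <- function(mat) apply(mat, 2L, stats::sd) / sqrt(nrow(mat))
  data.frame(
    stage = 0:(len - 1L),
    mean_n_drivers = colMeans(nd), se_n_drivers = se(nd),
    mean_scc_edges = colMeans(scc), se_scc_edges = se(scc)
  )
}

#' Census of failed edges by controllability category
#'
#' Over the union of attacked and overload-failed edges, the fraction that
#' were critical, ordinary, or redundant *on the intact pre-attack graph*
#' (classification on the shrinking residual graph would conflate cause and
#' effect). Undefined (all-`NA`, `defined = FALSE`) when no edge failed.
#'
#' @param categories per-edge labels from [classify_edges()] on the intact
#'   graph.
#' @param trace a `cascade_trace`.
#' @param attacked attacked edge indices (defaults to `trace$attacked`).
#' @return named list `critical`, `ordinary`, `redundant`, `defined`,
#'   `n_failed`.
#' @export
failed_edge_census <- function(categories, trace, attacked = trace$attacked) {
  if (!inherits(trace, "cascade_trace")) stop("expected a `cascade_trace`")
  failed <- union(attacked, unlist(trace$failed_edges))
  if (length(failed) == 0L) {
    return(list(critical = NA_real_, ordinary = NA_real_,
                redundant = NA_real_, defined = FALSE, n_failed = 0L))
  }
  lab <- categories[failed]
  list(critical = mean(lab == "critical"),
       ordinary = mean(lab == "ordinary"),
       redundant = mean(lab == "redundant"),
       defined = TRUE, n_failed = length(failed))
}

#' Removal-fraction sweep
#'
#' Full factorial over (strategy, removal fraction f, realization). Each cell
#' attacks `round(f * m)` edges (random, or in descending order of initial
#' load), runs the cascade to completion, and records the final driver-node
#' count, the number of overload-failed edges, and the failed-edge category
#' census against the intact-graph classification.
#'
#' @param config an [experiment_config()].
#' @param classify compute per-realization edge classification for the
#'   census (set `FALSE` to skip, e.g. for timing).
#' @return a list of class `sweep_result`: `cells` (one row per
#'   strategy/f/realization) and `summary` (realization-averaged, from
#'   [aggregate_realizations()]).
#' @export
fraction_sweep <- function(config, classify = TRUE) {
  if (!inherits(config, "experiment_config")) stop("expected an `experiment_config`")
  grid <- expand.grid(strategy = config$strategies, f = config$f_grid,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(config, n_cells_per_real = nrow(grid))
  rows <- list()
  for (i in seq_len(config$n_realizations)) {
    g <- config_graph(config, seeds$graph[i])
    if (g$m == 0L) stop("realization ", i, " has no edges")
    loads <- compute_loads(g)
    caps <- assign_capacities(loads, config$alpha)
    cats <- if (classify) classify_edges(g) else NULL
    intact_nd <- driver_report(g)$n_drivers
    for (j in seq_len(nrow(grid))) {
      f <- grid$f[j]; strat <- grid$strategy[j]
      seed_j <- seeds$cell[i, j]
      removed <- if (strat == "RA") {
        select_edges_random(g, f, seed_j)
      } else {
        select_edges_intentional(g, loads, f, seed_j)
      }
      tr <- run_cascade(g, caps, removed, instrument = FALSE)
      cen <- if (classify) {
        failed_edge_census(cats, tr)
      } else {
        list(critical = NA_real_, ordinary = NA_real_, redundant = NA_real_,
             defined = NA, n_failed = NA_integer_)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        realization = i, strategy = strat, f = f,
        intact_nd = intact_nd,
        n_drivers_final = tr$stages$n_drivers[nrow(tr$stages)],
        total_failed = tr$total_failed,
        n_attacked = length(removed),
        density_critical = cen$critical,
        density_ordinary = cen$ordinary,
        density_redundant = cen$redundant,
        census_defined = cen$defined
      )
    }
  }
  cells <- do.call(rbind, rows)
  structure(list(cells = cells, summary = aggregate_realizations(cells),
                 config = config),
            class = "sweep_result")
}

#' Average sweep cells over realizations
#'
#' Mean and standard error per (strategy, f) cell for the final driver
#' count, overload-failed edge count, and the failed-edge category
#' densities. Realizations whose census is undefined (no failed edge) are
#' excluded from the density averages; their count is reported.
#'
#' @param cells the per-realization cell table from [fraction_sweep()].
#' @return a data.frame with one row per (strategy, f).
#' @export
aggregate_realizations <- function(cells) {
  if (nrow(cells) == 0L) stop("no realization records to aggregate")
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  parts <- split(cells, list(cells$strategy, cells$f), drop = TRUE)
  out <- lapply(parts, function(d) {
    cen <- d[!is.na(d$census_defined) & d$census_defined, , drop = FALSE]
    data.frame(
      strategy = d$strategy[1L], f = d$f[1L],
      n_realizations = nrow(d),
      mean_nd_final = mean(d$n_drivers_final), se_nd_final = se(d$n_drivers_final),
      mean_total_failed = mean(d$total_failed), se_total_failed = se(d$total_failed),
      mean_density_critical = if (nrow(cen)) mean(cen$density_critical) else NA_real_,
      mean_density_ordinary = if (nrow(cen)) mean(cen$density_ordinary) else NA_real_,
      mean_density_redundant = if (nrow(cen)) mean(cen$density_redundant) else NA_real_,
      n_census_defined = nrow(cen)
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$strategy, out$f), , drop = FALSE]
  rownames(out) <- NULL
  out
}
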