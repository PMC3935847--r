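#' Shortest-path edge loads
#'
#' The load on a directed edge is the number of shortest directed paths
#' passing through it, summed over all ordered node pairs; every distinct
#' shortest path of equal length counts fully (raw count). Set
#' `fractional = TRUE` for the Brandes edge-betweenness variant, in which
#' each pair contributes 1 split across its equal-length shortest paths
#' (available for sensitivity analysis).
#'
#' @param g a `digraph`.
#' @param fractional use fractional (Brandes) instead of raw counting.
#' @return numeric vector of loads, one per edge row of `g`.
#' @export
compute_loads <- function(g, fractional = FALSE) {
  stopifnot_digraph(g)
  if (g$m == 0L) return(numeric(0))
  if (fractional) {
    return(as.numeric(igraph::edge_betweenness(as_igraph(g), directed = TRUE)))
  }
  edge_loads_cpp(g$n, g$edges)
}

#' Assign edge capacities from initial loads
#'
#' Each edge's capacity is proportional to its load on the intact network:
#' `C_e = (1 + alpha) * L_e(0)`, where `alpha >= 0` is the tolerance
#' parameter. Capacities are fixed at trigger time and never updated during
#' a cascade.
#'
#' @param loads numeric vector of initial (intact-graph) loads.
#' @param alpha non-negative tolerance parameter.
#' @return a list of class `capacity_map` with `capacity` and `alpha`.
#' @export
assign_capacities <- function(loads, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number")
  }
  structure(list(capacity = (1 + alpha) * loads, alpha = alpha),
            class = "capacity_map")
}

#' Run a load-capacity cascade
#'
#' Starting from the attacked graph, iterate: recompute all edge loads on the
#' residual graph; every surviving edge whose load strictly exceeds its
#' (fixed, intact-graph) capacity fails; all overloaded edges are removed
#' simultaneously; repeat until no edge is overloaded. An edge whose load
#' equals its capacity survives (capacity is the maximum load the edge can
#' handle). Terminates in at most `m` stages.
#'
#' Stage 0 records the state immediately after the attacked edges are
#' removed, before any overload failure. `total_failed` counts only edges
#' failed by overload, excluding the initially attacked ones.
#'
#' @param g the intact `digraph`.
#' @param capacities a `capacity_map` computed from the intact graph's loads.
#' @param removed_edges integer indices (edge rows of `g`) removed by the
#'   attack; may be empty.
#' @param instrument record `n_drivers` and `scc_edges` at every stage
#'   (set `FALSE` to record them only at the final stage).
#' @param fractional passed to [compute_loads()].
#' @return a list of class `cascade_trace`: `stages` (data.frame with
#'   `stage`, `failed_this_stage`, `cumulative_failed`, `n_drivers`,
#'   `scc_edges`), `failed_edges` (list of overload-failed edge indices per
#'   stage), `attacked`, `total_failed`, `terminated`.
#' @export
run_cascade <- function(g, capacities, removed_edges = integer(0),
                        instrument = TRUE, fractional = FALSE) {
  stopifnot_digraph(g)
  if (!inherits(capacities, "capacity_map")) stop("expected a `capacity_map`")
  cap <- capacities$capacity
  if (length(cap) != g$m) stop("capacity vector does not match edge count")
  removed_edges <- as.integer(removed_edges)
  if (length(removed_edges) > 0L &&
      (min(removed_edges) < 1L || max(removed_edges) > g$m)) {
    stop("removed_edges must index edge rows of `g`")
  }
  alive <- rep(TRUE, g$m)
  alive[removed_edges] <- FALSE

  stage_rows <- list()
  failed_per_stage <- list()
  measure <- function(stage, failed_idx, record_state) {
    res <- edge_subgraph(g, alive)
    nd <- if (record_state) driver_report(res)$n_drivers else NA_integer_
    scc <- if (record_state) scc_edge_count(res) else NA_integer_
    list(row = data.frame(
      stage = stage,
      failed_this_stage = length(failed_idx),
      cumulative_failed = sum(!alive) - length(removed_edges),
      n_drivers = nd,
      scc_edges = scc
    ), failed = failed_idx)
  }

  stage <- 0L
  st <- measure(stage, integer(0), instrument)
  stage_rows[[1L]] <- st$row
  failed_per_stage[[1L]] <- integer(0)

  repeat {
    live_idx <- which(alive)
    if (length(live_idx) == 0L) break
    res <- edge_subgraph(g, alive)
    loads <- compute_loads(res, fractional = fractional)
    over <- live_idx[loads > cap[live_idx]]
    if (length(over) == 0L) break
    alive[over] <- FALSE
    stage <- stage + 1L
    if (stage > g$m) stop("cascade failed to terminate within m stages")
    st <- measure(stage, over, instrument)
    stage_rows[[stage + 1L]] <- st$row
    failed_per_stage[[stage + 1L]] <- over
  }

  stages <- do.call(rbind, stage_rows)
  if (!instrument) {
    # final state is always reported
    res <- edge_subgraph(g, alive)
    stages$n_drivers[nrow(stages)] <- driver_report(res)$n_drivers
    stages$scc_edges[nrow(stages)] <- scc_edge_count(res)
  }
  structure(
    list(stages = stages,
         failed_edges = failed_per_stage,
         attacked = removed_edges,
         total_failed = sum(!alive) - length(removed_edges),
         terminated = TRUE),
    class = "cascade_trace"
  )
}

#' @export
print.cascade_trace <- function(x, ...) {
  cat(sprintf("cascade: %d stage(s), %d attacked, %d overload-failed\n",
              nrow(x$stages) - 1L, length(x$attacked), x$total_failed))
  print(x$stages)
  invisible(x)
}
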