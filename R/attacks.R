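# Edge-attack strategies. Both remove round(f * m) edges in one batch before
# the cascade starts (intentional ranking uses *initial* loads only, so there
# is no sequential re-ranking), rounding half away from zero with a minimum
# of one edge whenever f > 0.

attack_count <- function(m, f) {
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    stop("removal fraction f must lie in [0, 1]")
  }
  k <- floor(f * m + 0.5)
  if (f > 0 && k < 1L) k <- 1L
  as.integer(min(k, m))
}

#' Random edge attack (RA)
#'
#' Removes a uniform sample (without replacement) of `round(f * m)` edges.
#'
#' @param g a `digraph` with at least one edge.
#' @param f removal fraction in `[0, 1]`.
#' @param seed integer seed; same graph + f + seed gives the same set.
#' @return integer vector of removed edge indices (rows of `g$edges`).
#' @export
select_edges_random <- function(g, f, seed) {
  stopifnot_digraph(g)
  if (g$m < 1L) stop("graph has no edges to attack")
  k <- attack_count(g$m, f)
  if (k == 0L) return(integer(0))
  withr::with_seed(seed, sample.int(g$m, k))
}

#' Intentional edge attack (IA)
#'
#' Removes the `round(f * m)` edges of highest *initial* load, in descending
#' load order. Ties at the cutoff load are broken uniformly at random under
#' `seed`, so the result does not depend on the input edge order. With `f`
#' sized to a single edge this is the highest-load-edge trigger.
#'
#' @param g a `digraph` with at least one edge.
#' @param loads initial loads computed on the intact graph
#'   ([compute_loads()]).
#' @param f removal fraction in `[0, 1]`.
#' @param seed integer seed for cutoff tie-breaking.
#' @return integer vector of removed edge indices.
#' @export
select_edges_intentional <- function(g, loads, f, seed) {
  stopifnot_digraph(g)
  if (g$m < 1L) stop("graph has no edges to attack")
  if (length(loads) != g$m) stop("loads must have one entry per edge")
  k <- attack_count(g$m, f)
  if (k == 0L) return(integer(0))
  cutoff <- sort(loads, decreasing = TRUE)[k]
  sure <- which(loads > cutoff)
  ties <- which(loads == cutoff)
  need <- k - length(sure)
  picked <- if (need == length(ties)) {
    ties
  } else {
    withr::with_seed(seed, sample(ties, need))
  }
  c(sure, picked)
}

#' Highest-load edge trigger
#'
#' Convenience wrapper: the single edge of maximum initial load (ties broken
#' by seed), the trigger used in single-attack cascade experiments.
#'
#' @inheritParams select_edges_intentional
#' @return a single edge index.
#' @export
highest_load_edge <- function(g, loads, seed = 1L) {
  select_edges_intentional(g, loads, f = 1 / g$m, seed = seed)
}
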