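#' Maximum matching of a directed graph
#'
#' A matching in the directed-graph sense: a set of edges no two of which
#' share a source and no two of which share a target. It is computed as a
#' maximum bipartite matching on the out-copy/in-copy representation, where
#' the directed edge `(i, j)` becomes the bipartite edge `i+ -- j-`. A node
#' is *matched* when a matched edge points to it; the unmatched nodes are the
#' driver nodes of structural controllability.
#'
#' @param g a `digraph`.
#' @return a list of class `digraph_matching` with `size`, `matched_edges`
#'   (indices into the edge rows of `g`), and `matched_by` (for each node,
#'   the source of its inbound matched edge, or `NA`).
#' @export
maximum_matching <- function(g) {
  stopifnot_digraph(g)
  n <- g$n
  matched_by <- rep(NA_integer_, n)
  matched_edges <- integer(0)
  if (g$m > 0L) {
    mt <- bipartite_match_raw(g)
    # mt[v] = out-copy matched into in-copy v, NA if v unmatched
    for (e in seq_len(g$m)) {
      u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
      if (!is.na(mt[v]) && mt[v] == u) {
        matched_by[v] <- u
        matched_edges <- c(matched_edges, e)
      }
    }
  }
  structure(
    list(size = length(matched_edges),
         matched_edges = matched_edges,
         matched_by = matched_by),
    class = "digraph_matching"
  )
}

# Maximum bipartite matching on the out/in copy representation via igraph.
# Returns, for each in-copy (node as target), its matched out-copy or NA.
bipartite_match_raw <- function(g) {
  n <- g$n
  types <- c(rep(FALSE, n), rep(TRUE, n))
  be <- cbind(g$edges[, 1L], n + g$edges[, 2L])
  bg <- igraph::make_empty_graph(n = 2L * n, directed = FALSE)
  bg <- igraph::add_edges(bg, t(be))
  res <- igraph::max_bipartite_match(bg, types = types)
  mt <- res$matching[(n + 1L):(2L * n)]
  mt[mt > n] <- NA_integer_  # unmatched sentinel safety
  unname(mt)
}

#' Driver-node report
#'
#' The minimum number of independent input signals needed to fully control
#' the network equals the number of nodes left unmatched by a maximum
#' matching; those unmatched nodes are the driver nodes. When the matching is
#' perfect, one input is still required, attached by convention to the
#' lowest-id node (every node then lies on a matched cycle), so
#' `n_drivers = max(n - |matching|, 1)`.
#'
#' Driver *sets* are not unique across maximum matchings; the count is. This
#' function returns one deterministic representative set.
#'
#' @param g a `digraph`.
#' @param matching optionally, a precomputed [maximum_matching()] of `g`.
#' @return a list of class `controllability_report` with `n_drivers`,
#'   `driver_nodes`, `n_drivers_density`, and `matching`.
#' @export
driver_report <- function(g, matching = NULL) {
  stopifnot_digraph(g)
  if (is.null(matching)) matching <- maximum_matching(g)
  unmatched <- which(is.na(matching$matched_by))
  if (length(unmatched) == 0L) {
    drivers <- 1L
  } else {
    drivers <- unmatched
  }
  nd <- max(g$n - matching$size, 1L)
  structure(
    list(n_drivers = nd,
         driver_nodes = drivers,
         n_drivers_density = nd / g$n,
         matching = matching),
    class = "controllability_report"
  )
}

#' @export
print.controllability_report <- function(x, ...) {
  cat(sprintf("N_D = %d (density %.4f); drivers: %s\n",
              x$n_drivers, x$n_drivers_density,
              paste(utils::head(x$driver_nodes, 10L), collapse = ", ")))
  invisible(x)
}

#' Classify edges as critical, ordinary, or redundant
#'
#' With respect to structural controllability, an edge is *critical* if its
#' removal increases the number of driver nodes, *redundant* if it belongs to
#' no maximum matching, and *ordinary* otherwise (in some but not every
#' maximum matching).
#'
#' The classification is computed in linear time from one maximum matching
#' via the alternating-structure (flow-residual) digraph: orient each
#' unmatched bipartite edge `u+ -> v-`, each matched edge `v- -> u+`, connect
#' a source/sink pair to free copies, and take strongly connected components.
#' A matched edge is ordinary iff its two copies share a component (an
#' alternating cycle or even alternating path can reroute around it),
#' otherwise critical; an unmatched edge is ordinary iff its copies share a
#' component (it lies in some maximum matching), otherwise redundant.
#'
#' @param g a `digraph`.
#' @return a character vector of length `m` with values
#'   `"critical"`, `"ordinary"`, `"redundant"`, one per edge row.
#' @export
classify_edges <- function(g) {
  stopifnot_digraph(g)
  if (g$m == 0L) return(character(0))
  n <- g$n
  mm <- maximum_matching(g)
  matched_by <- mm$matched_by              # target -> matched source
  matched_src <- rep(FALSE, n)             # source has an outbound matched edge
  matched_src[matched_by[!is.na(matched_by)]] <- TRUE
  is_matched_edge <- logical(g$m)
  is_matched_edge[mm$matched_edges] <- TRUE

  # residual digraph nodes: 1..n out-copies, n+1..2n in-copies, 2n+1 = s, 2n+2 = t
  s_node <- 2L * n + 1L; t_node <- 2L * n + 2L
  u <- g$edges[, 1L]; v <- g$edges[, 2L]
  from <- ifelse(is_matched_edge, n + v, u)
  to <- ifelse(is_matched_edge, u, n + v)
  free_src <- which(!matched_src)
  free_tgt <- which(is.na(matched_by))
  used_src <- which(matched_src)
  used_tgt <- which(!is.na(matched_by))
  from <- c(from, rep(s_node, length(free_src)), used_src,
            n + free_tgt, rep(t_node, length(used_tgt)))
  to <- c(to, free_src, rep(s_node, length(used_src)),
          rep(t_node, length(free_tgt)), n + used_tgt)
  rg <- igraph::make_empty_graph(n = 2L * n + 2L, directed = TRUE)
  rg <- igraph::add_edges(rg, t(cbind(from, to)))
  memb <- igraph::components(rg, mode = "strong")$membership
  same <- memb[u] == memb[n + v]
  out <- ifelse(same, "ordinary", ifelse(is_matched_edge, "critical", "redundant"))
  # perfect matching: n_drivers is already at its floor of 1, so no removal
  # can increase it -- edges that are in every maximum matching are ordinary
  if (mm$size == n) out[out == "critical"] <- "ordinary"
  out
}

#' Exact controllability via eigenvalue multiplicity
#'
#' For a specific weighted adjacency matrix `A`, the minimum number of
#' independent inputs is `max_lambda (n - rank(lambda * I - A))`, the maximum
#' geometric multiplicity over distinct eigenvalues. This is the
#' exact-controllability counterpart to the matching-based (structural)
#' driver count: with generic random weights the two agree; with identical
#' weights the exact count may exceed the structural one on degenerate
#' spectra.
#'
#' Numerical conventions: eigenvalues are grouped as "equal" by an absolute
#' tolerance (`eig_tol`, default `1e-8`); the rank of `lambda*I - A` is the
#' number of singular values above `max(dim) * eps * largest`. Eigenvalue
#' groups of algebraic multiplicity 1 have geometric multiplicity 1 and are
#' skipped; `lambda = 0` is always evaluated explicitly because a defective
#' zero eigenvalue scatters numerically beyond any fixed grouping tolerance.
#'
#' @param g a `digraph` (dense linear algebra; guarded at `n <= 5000`).
#' @param weight_mode `"identical"` (all nonzero weights 1) or `"random"`
#'   (independent uniform draws on (0, 1]).
#' @param seed seed for random weights.
#' @param eig_tol grouping tolerance for distinct eigenvalues.
#' @return integer driver count, `>= 1`.
#' @export
exact_driver_count <- function(g, weight_mode = c("identical", "random"),
                               seed = 1L, eig_tol = 1e-8) {
  stopifnot_digraph(g)
  weight_mode <- match.arg(weight_mode)
  n <- g$n
  if (n > 5000L) stop("n too large for dense exact-controllability computation")
  A <- matrix(0, n, n)
  if (g$m > 0L) {
    w <- if (weight_mode == "identical") {
      rep(1, g$m)
    } else {
      withr::with_seed(seed, 1 - stats::runif(g$m))  # uniform on (0, 1]
    }
    A[cbind(g$edges[, 2L], g$edges[, 1L])] <- w  # A[i, j] != 0 for edge j -> i
  }
  ev <- eigen(A, only.values = TRUE)$values
  ord <- order(Re(ev), Im(ev))
  ev <- ev[ord]
  # greedy grouping of numerically equal eigenvalues
  grp <- integer(length(ev)); gi <- 0L
  for (i in seq_along(ev)) {
    if (i == 1L || Mod(ev[i] - rep_ev) > eig_tol) {
      gi <- gi + 1L
      rep_ev <- ev[i]
    }
    grp[i] <- gi
  }
  counts <- tabulate(grp)
  cand <- vapply(which(counts >= 2L), function(k) mean(ev[grp == k]),
                 complex(1))
  # lambda = 0 is always evaluated exactly: a defective zero eigenvalue
  # (nilpotent structure from acyclic parts) scatters numerically over a
  # radius far beyond any fixed grouping tolerance, but its geometric
  # multiplicity n - rank(A) is computed reliably at 0 itself
  cand <- unique(c(cand, 0 + 0i))
  best <- 1L
  for (lambda in cand) {
    M <- diag(lambda, n) - A
    d <- svd(M, nu = 0, nv = 0)$d
    rk <- sum(d > max(dim(M)) * .Machine$double.eps * d[1L])
    best <- max(best, n - rk)
  }
  as.integer(best)
}
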