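# Brute-force oracles, independent of the package's algorithms. All operate
# on `digraph` objects but use only exhaustive enumeration.

random_digraph <- function(n, p, seed) {
  withr::with_seed(seed, {
    src <- rep(seq_len(n), each = n - 1L)
    dst <- unlist(lapply(seq_len(n), function(i) seq_len(n)[-i]), use.names = FALSE)
    keep <- stats::runif(length(src)) < p
    digraph(cbind(src[keep], dst[keep]), n = n)
  })
}

# Enumerate every matching by include/exclude recursion over edges.
# Returns max cardinality and the list of all maximum matchings
# (edge-index sets, sorted).
brute_matchings <- function(g) {
  m <- g$m
  best <- 0L
  maxima <- list()
  rec <- function(e, used_src, used_tgt, chosen) {
    if (e > m) {
      k <- length(chosen)
      if (k > best) {
        best <<- k
        maxima <<- list(sort(chosen))
      } else if (k == best) {
        maxima[[length(maxima) + 1L]] <<- sort(chosen)
      }
      return(invisible(NULL))
    }
    u <- g$edges[e, 1L]; v <- g$edges[e, 2L]
    if (!used_src[u] && !used_tgt[v]) {
      used_src[u] <- TRUE; used_tgt[v] <- TRUE
      rec(e + 1L, used_src, used_tgt, c(chosen, e))
      used_src[u] <- FALSE; used_tgt[v] <- FALSE
    }
    rec(e + 1L, used_src, used_tgt, chosen)
  }
  if (m == 0L) return(list(size = 0L, maxima = list(integer(0))))
  rec(1L, rep(FALSE, g$n), rep(FALSE, g$n), integer(0))
  list(size = best, maxima = unique(maxima))
}

brute_nd <- function(g) {
  max(g$n - brute_matchings(g)$size, 1L)
}

# Remove-and-recount for critical; membership in enumerated maximum
# matchings for redundant.
brute_classify <- function(g) {
  base <- brute_matchings(g)
  nd0 <- max(g$n - base$size, 1L)
  in_some <- rep(FALSE, g$m)
  for (mm in base$maxima) in_some[mm] <- TRUE
  out <- character(g$m)
  for (e in seq_len(g$m)) {
    ge <- edge_subgraph(g, setdiff(seq_len(g$m), e))
    nd_e <- brute_nd(ge)
    if (nd_e > nd0) {
      out[e] <- "critical"
    } else if (!in_some[e]) {
      out[e] <- "redundant"
    } else {
      out[e] <- "ordinary"
    }
  }
  out
}

# All simple directed paths s -> t by DFS; raw shortest-path edge loads by
# enumerating every pair's minimum-length paths.
brute_loads <- function(g) {
  load <- numeric(g$m)
  if (g$m == 0L) return(load)
  adj <- lapply(seq_len(g$n), function(u) which(g$edges[, 1L] == u))
  paths_from <- function(s, t) {
    found <- list()
    dfs <- function(v, edge_trail, visited) {
      if (v == t) {
        found[[length(found) + 1L]] <<- edge_trail
        return(invisible(NULL))
      }
      for (e in adj[[v]]) {
        w <- g$edges[e, 2L]
        if (!visited[w]) {
          visited[w] <- TRUE
          dfs(w, c(edge_trail, e), visited)
          visited[w] <- FALSE
        }
      }
    }
    vis <- rep(FALSE, g$n); vis[s] <- TRUE
    dfs(s, integer(0), vis)
    found
  }
  for (s in seq_len(g$n)) for (t in seq_len(g$n)) {
    if (s == t) next
    ps <- paths_from(s, t)
    if (length(ps) == 0L) next
    lens <- vapply(ps, length, integer(1))
    for (pp in ps[lens == min(lens)]) load[pp] <- load[pp] + 1
  }
  load
}

# Pairwise-reachability SCC edge count.
brute_scc_edges <- function(g, largest_only = FALSE) {
  if (g$m == 0L) return(0L)
  reach <- diag(TRUE, g$n)
  for (e in seq_len(g$m)) reach[g$edges[e, 1L], g$edges[e, 2L]] <- TRUE
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  mutual <- reach & t(reach)
  if (!largest_only) {
    return(sum(mutual[cbind(g$edges[, 1L], g$edges[, 2L])]))
  }
  comp <- integer(g$n); cid <- 0L
  for (v in seq_len(g$n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      comp[mutual[v, ]] <- cid
    }
  }
  sizes <- tabulate(comp)
  big <- max(sizes)
  if (big < 2L) return(0L)
  cand <- which(sizes == big)
  first_node <- vapply(cand, function(cc) min(which(comp == cc)), integer(1))
  keep <- cand[which.min(first_node)]
  sum(comp[g$edges[, 1L]] == keep & comp[g$edges[, 2L]] == keep)
}

# Straight-line reference cascade: same update rules, written independently
# around the brute-force load oracle (for small fixtures only).
reference_cascade_final <- function(g, alpha, removed) {
  cap <- (1 + alpha) * brute_loads(g)
  alive <- rep(TRUE, g$m)
  alive[removed] <- FALSE
  failed <- list()
  repeat {
    res <- edge_subgraph(g, alive)
    loads_full <- numeric(g$m)
    loads_full[alive] <- brute_loads(res)
    over <- which(alive & loads_full > cap)
    if (length(over) == 0L) break
    alive[over] <- FALSE
    failed[[length(failed) + 1L]] <- over
  }
  list(alive = alive, failed = failed,
       total_failed = sum(!alive) - length(removed))
}
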