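#' Construct a directed graph
#'
#' The basic container used throughout the package: a simple directed graph
#' with consecutive integer node ids `1..n` and an ordered edge list.
#' Self-loops and duplicate directed edges are disallowed (the matching-based
#' controllability criterion and the shortest-path load model never use them).
#'
#' @param edges two-column integer matrix (or data.frame) of directed edges,
#'   one `(source, target)` row per edge, ids in `1..n`. May have zero rows.
#' @param n number of nodes. Defaults to the largest id appearing in `edges`.
#' @param id_map optional vector of length `n` with the original (external)
#'   node labels; kept for reporting after reading relabelled edge lists.
#' @return an object of class `digraph` with fields `n`, `edges`, `m`,
#'   and `id_map`.
#' @export
digraph <- function(edges, n = NULL, id_map = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(0), ncol = 2L)
  if (ncol(edges) != 2L) stop("`edges` must have two columns (source, target)")
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  if (is.null(n)) n <- if (nrow(edges) > 0L) max(edges) else 1L
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("graph must have at least one node")
  if (nrow(edges) > 0L) {
    if (anyNA(edges)) stop("edge endpoints must be integers")
    if (min(edges) < 1L || max(edges) > n) stop("edge endpoint outside 1..n")
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    if (anyDuplicated(paste(edges[, 1L], edges[, 2L]))) {
      stop("duplicate directed edges are not allowed")
    }
  }
  structure(
    list(n = n, edges = edges, m = nrow(edges), id_map = id_map),
    class = "digraph"
  )
}

#' @export
print.digraph <- function(x, ...) {
  cat(sprintf("directed graph: %d nodes, %d edges\n", x$n, x$m))
  invisible(x)
}

is_digraph <- function(x) inherits(x, "digraph")

stopifnot_digraph <- function(g) {
  if (!is_digraph(g)) stop("expected a `digraph` object")
  invisible(g)
}

#' Convert a digraph to an igraph object
#'
#' @param g a `digraph`.
#' @return an `igraph` directed graph with the same vertex ids and edge order.
#' @export
as_igraph <- function(g) {
  stopifnot_digraph(g)
  if (g$m == 0L) return(igraph::make_empty_graph(n = g$n, directed = TRUE))
  ig <- igraph::graph_from_edgelist(g$edges, directed = TRUE)
  if (igraph::vcount(ig) < g$n) {
    ig <- igraph::add_vertices(ig, g$n - igraph::vcount(ig))
  }
  ig
}

#' Read a directed edge list from a plain-text file
#'
#' Format: one `source target` pair per line (whitespace separated, 0-based
#' non-negative integer labels), `#`-prefixed comment lines, and an optional
#' `#nodes N` header declaring the node count (needed to represent isolated
#' nodes). Duplicate edges and self-loops are dropped with a message. Node
#' labels are relabelled to consecutive internal ids `1..n`; the original
#' labels are kept in `id_map`.
#'
#' @param path path to the edge-list file.
#' @param quiet suppress the dropped-line message.
#' @return a `digraph`.
#' @export
read_edge_list <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  n_declared <- NA_integer_
  hdr <- grep("^#nodes\\b", lines)
  if (length(hdr) > 0L) {
    tok <- strsplit(trimws(lines[hdr[1L]]), "\\s+")[[1L]]
    n_declared <- suppressWarnings(as.integer(tok[2L]))
    if (is.na(n_declared) || n_declared < 1L) {
      stop("invalid #nodes header at line ", hdr[1L])
    }
  }
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body) == 0L && is.na(n_declared)) {
    stop("empty edge-list file: ", path)
  }
  src <- integer(length(body)); dst <- integer(length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(lines[body[i]]), "\\s+")[[1L]]
    vals <- suppressWarnings(as.integer(tok))
    if (length(vals) != 2L || anyNA(vals) || any(vals < 0L)) {
      stop("malformed edge line ", body[i], ": '", lines[body[i]], "'")
    }
    src[i] <- vals[1L]; dst[i] <- vals[2L]
  }
  all_endpoints <- c(src, dst)  # dropped lines still declare their nodes
  keep_self <- src != dst
  keep_dup <- !duplicated(paste(src, dst))
  keep <- keep_self & keep_dup
  n_dropped <- sum(!keep)
  if (n_dropped > 0L && !quiet) {
    message(n_dropped, " self-loop/duplicate line(s) dropped")
  }
  src <- src[keep]; dst <- dst[keep]
  if (!is.na(n_declared)) {
    if (length(src) > 0L && max(c(src, dst)) >= n_declared) {
      stop("edge endpoint exceeds declared #nodes ", n_declared)
    }
    labels <- 0:(n_declared - 1L)
  } else {
    labels <- sort(unique(all_endpoints))
  }
  idx <- stats::setNames(seq_along(labels), labels)
  edges <- cbind(idx[as.character(src)], idx[as.character(dst)])
  digraph(edges, n = length(labels), id_map = labels)
}

#' Write a directed edge list to a plain-text file
#'
#' Writes the format accepted by [read_edge_list()]: a `#nodes N` header
#' followed by one 0-based `source target` pair per line. Reading the file
#' back reproduces the node and edge sets exactly.
#'
#' @param g a `digraph`.
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot_digraph(g)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("#nodes %d", g$n), con)
  if (g$m > 0L) {
    writeLines(sprintf("%d %d", g$edges[, 1L] - 1L, g$edges[, 2L] - 1L), con)
  }
  invisible(NULL)
}

#' Count edges inside strongly connected components
#'
#' Cascading failures concentrate in the strongly connected part of a
#' directed network, so the number of edges whose two endpoints share a
#' strongly connected component (SCC) of size at least 2 is tracked along
#' every cascade. By default edges inside *all* nontrivial SCCs are counted;
#' `largest_only = TRUE` restricts to a largest SCC (ties broken by smallest
#' contained node id, so the statistic stays deterministic after heavy damage).
#'
#' @param g a `digraph`.
#' @param largest_only count only edges inside one largest SCC.
#' @return a non-negative integer.
#' @export
scc_edge_count <- function(g, largest_only = FALSE) {
  stopifnot_digraph(g)
  if (g$m == 0L) return(0L)
  comp <- igraph::components(as_igraph(g), mode = "strong")
  memb <- comp$membership
  if (largest_only) {
    big <- max(comp$csize)
    cand <- which(comp$csize == big)
    if (big < 2L) return(0L)
    # deterministic tie-break: component containing the smallest node id
    first_node <- vapply(cand, function(cc) min(which(memb == cc)), integer(1))
    keep <- cand[which.min(first_node)]
    same <- memb[g$edges[, 1L]] == keep & memb[g$edges[, 2L]] == keep
  } else {
    nontrivial <- which(comp$csize >= 2L)
    same <- memb[g$edges[, 1L]] == memb[g$edges[, 2L]] &
      memb[g$edges[, 1L]] %in% nontrivial
  }
  sum(same)
}

#' Induced subgraph on a subset of edges
#'
#' Keeps all `n` nodes and the selected edges (used to form the residual
#' graph after attack/failure stages without relabelling nodes).
#'
#' @param g a `digraph`.
#' @param keep logical or integer index into the edge rows.
#' @return a `digraph` with the same node set.
#' @export
edge_subgraph <- function(g, keep) {
  stopifnot_digraph(g)
  digraph(g$edges[keep, , drop = FALSE], n = g$n, id_map = g$id_map)
}
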