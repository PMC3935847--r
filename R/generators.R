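#' Directed Erdos-Renyi graph
#'
#' Every ordered pair `(i, j)`, `i != j`, receives an edge independently with
#' probability `p = mean_degree / (n - 1)`, so the expected edge count is
#' `n * mean_degree` under the degree convention `<k> = m / n` (average
#' out-degree = average in-degree).
#'
#' @param n number of nodes (`>= 2`).
#' @param mean_degree target average degree `<k> = m / n`.
#' @param seed integer seed; the generator is a pure function of
#'   `(n, mean_degree, seed)`.
#' @return a `digraph`.
#' @export
generate_er <- function(n, mean_degree, seed) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (mean_degree < 0) stop("mean_degree must be >= 0")
  p <- mean_degree / (n - 1)
  if (p > 1) stop("mean_degree/(n-1) exceeds 1: not realizable")
  withr::with_seed(seed, {
    src <- rep(seq_len(n), each = n - 1L)
    dst <- unlist(lapply(seq_len(n), function(i) seq_len(n)[-i]),
                  use.names = FALSE)
    keep <- stats::runif(length(src)) < p
    digraph(cbind(src[keep], dst[keep]), n = n)
  })
}

#' Directed scale-free graph (static model)
#'
#' Static-model construction: node `i` gets weight `w_i = i^(-1/(gamma-1))`,
#' and `m = round(n * mean_degree)` distinct directed edges are drawn by
#' sampling source and target independently in proportion to the weights,
#' rejecting self-loops and duplicates. Both in- and out-degree distributions
#' then follow a power law with exponent `gamma` asymptotically, with `gamma`
#' and `<k>` controlled independently.
#'
#' @param n number of nodes.
#' @param mean_degree target average degree `<k> = m / n`.
#' @param gamma power-law exponent (`> 2`).
#' @param seed integer seed.
#' @param max_rounds sampling rounds before declaring a rejection stall.
#' @return a `digraph`.
#' @export
generate_sf <- function(n, mean_degree, gamma, seed, max_rounds = 200L) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (gamma <= 2) stop("gamma must be > 2")
  m_target <- round(n * mean_degree)
  if (m_target > n * (n - 1L)) stop("requested edge count exceeds n*(n-1)")
  w <- seq_len(n)^(-1 / (gamma - 1))
  withr::with_seed(seed, {
    src <- integer(0); dst <- integer(0)
    rounds <- 0L
    while (length(src) < m_target) {
      rounds <- rounds + 1L
      if (rounds > max_rounds) {
        stop("edge sampling stalled: duplicate rate too high for requested density")
      }
      need <- m_target - length(src)
      batch <- max(2L * need, 100L)
      s <- sample.int(n, batch, replace = TRUE, prob = w)
      t <- sample.int(n, batch, replace = TRUE, prob = w)
      ok <- s != t
      src <- c(src, s[ok]); dst <- c(dst, t[ok])
      first <- !duplicated(paste(src, dst))
      src <- src[first]; dst <- dst[first]
      if (length(src) > m_target) {
        src <- src[seq_len(m_target)]; dst <- dst[seq_len(m_target)]
      }
    }
    digraph(cbind(src, dst), n = n)
  })
}

#' Deterministic toy graphs
#'
#' Small hand-built fixtures used in examples and tests:
#' \describe{
#'   \item{`path3`}{directed path 1 -> 2 -> 3.}
#'   \item{`cycle3`}{directed 3-cycle.}
#'   \item{`star_out5`}{hub node 1 pointing to 4 leaves.}
#'   \item{`matching_demo`}{8 nodes with a nontrivial strongly connected
#'     component and at least one critical, one ordinary and one redundant
#'     edge under the matching-based classification.}
#' }
#'
#' @param name fixture name.
#' @return a `digraph`.
#' @export
toy_fixture <- function(name) {
  catalogue <- list(
    path3 = cbind(c(1L, 2L), c(2L, 3L)),
    cycle3 = cbind(c(1L, 2L, 3L), c(2L, 3L, 1L)),
    star_out5 = cbind(rep(1L, 4L), 2:5),
    matching_demo = cbind(
      c(1L, 2L, 3L, 3L, 4L, 4L, 4L, 6L, 7L),
      c(2L, 3L, 1L, 4L, 5L, 7L, 8L, 5L, 8L)
    )
  )
  if (!name %in% names(catalogue)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(catalogue), collapse = ", "))
  }
  e <- catalogue[[name]]
  digraph(e, n = max(e, if (name == "star_out5") 5L else 0L))
}
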