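test_that("raw-count loads match hand enumeration on fixtures", {
  expect_equal(compute_loads(toy_fixture("path3")), c(2, 2))
  expect_equal(compute_loads(toy_fixture("cycle3")), c(3, 3, 3))
  expect_equal(compute_loads(digraph(matrix(integer(0), ncol = 2), n = 3)),
               numeric(0))
})

test_that("raw-count loads match the brute-force path-enumeration oracle", {
  for (seed in 1:60) {
    n <- 3L + (seed %% 6L)
    g <- random_digraph(n, p = 0.3, seed = 5000 + seed)
    expect_equal(compute_loads(g), brute_loads(g))
  }
})

test_that("load total equals paths times lengths (conservation identity)", {
  for (seed in 1:10) {
    g <- random_digraph(7, p = 0.3, seed = 6000 + seed)
    # independent tally: sum over pairs of (#shortest paths) * length
    total <- 0
    for (s in seq_len(g$n)) for (t in seq_len(g$n)) {
      if (s == t) next
      adj <- lapply(seq_len(g$n), function(u) which(g$edges[, 1] == u))
      found_len <- integer(0)
      dfs <- function(v, len, visited) {
        if (v == t) { found_len <<- c(found_len, len); return(invisible(NULL)) }
        for (e in adj[[v]]) {
          w <- g$edges[e, 2]
          if (!visited[w]) { visited[w] <- TRUE; dfs(w, len + 1L, visited); visited[w] <- FALSE }
        }
      }
      vis <- rep(FALSE, g$n); vis[s] <- TRUE
      dfs(s, 0L, vis)
      if (length(found_len)) {
        dmin <- min(found_len)
        total <- total + sum(found_len == dmin) * dmin
      }
    }
    expect_equal(sum(compute_loads(g)), total)
  }
})

test_that("capacity assignment follows the proportional rule", {
  cm <- assign_capacities(c(10, 0, 4), alpha = 0.3)
  expect_equal(cm$capacity, c(13, 0, 5.2))
  cm0 <- assign_capacities(c(2, 5), alpha = 0)
  expect_equal(cm0$capacity, c(2, 5))
  expect_equal(assign_capacities(numeric(3), 0.5)$capacity, numeric(3))
  expect_error(assign_capacities(c(1, 2), alpha = -0.1), "non-negative")
})

test_that("cascades terminate, respect capacities, and record stage 0", {
  g <- toy_fixture("path3")
  caps <- assign_capacities(compute_loads(g), alpha = 0.5)
  tr <- run_cascade(g, caps, removed_edges = 1L)
  expect_equal(tr$total_failed, 0L)  # residual load 1 <= capacity 3
  expect_equal(nrow(tr$stages), 1L)
  expect_equal(tr$stages$n_drivers[1], 2L)

  # no attack: intact report and no failures
  tr0 <- run_cascade(g, caps)
  expect_equal(tr0$total_failed, 0L)
  expect_equal(tr0$stages$n_drivers[1], driver_report(g)$n_drivers)

  # huge tolerance: no overload possible on any graph
  g2 <- generate_er(80, 4, seed = 5)
  loads2 <- compute_loads(g2)
  tr2 <- run_cascade(g2, assign_capacities(loads2, alpha = 1e6),
                     removed_edges = which.max(loads2))
  expect_equal(tr2$total_failed, 0L)
  expect_equal(nrow(tr2$stages), 1L)
})

test_that("cascade agrees with an independent reference implementation", {
  for (seed in 1:12) {
    g <- random_digraph(7, p = 0.4, seed = 7000 + seed)
    if (g$m < 2L) next
    loads <- compute_loads(g)
    for (alpha in c(0, 0.1, 0.5)) {
      caps <- assign_capacities(loads, alpha)
      trig <- which.max(loads)
      got <- run_cascade(g, caps, trig)
      ref <- reference_cascade_final(g, alpha, trig)
      expect_equal(got$total_failed, ref$total_failed)
      expect_equal(as.integer(sort(unlist(got$failed_edges))),
                   as.integer(sort(unlist(ref$failed))))
      expect_lte(nrow(got$stages) - 1L, g$m)
    }
  }
})

test_that("golden cascade on the matching_demo fixture", {
  g <- toy_fixture("matching_demo")
  loads <- compute_loads(g)
  caps <- assign_capacities(loads, alpha = 0.1)
  trig <- which.max(loads)
  tr <- run_cascade(g, caps, trig)
  ref <- reference_cascade_final(g, 0.1, trig)
  expect_equal(tr$total_failed, ref$total_failed)
  expect_equal(as.integer(unlist(tr$failed_edges)),
               as.integer(unlist(ref$failed)))
  expect_true(all(diff(tr$stages$n_drivers) >= 0))
})

test_that("per-stage driver count never decreases along a cascade", {
  for (seed in 1:6) {
    g <- generate_er(120, 4, seed = 8000 + seed)
    loads <- compute_loads(g)
    caps <- assign_capacities(loads, alpha = 0.1)
    tr <- run_cascade(g, caps, highest_load_edge(g, loads, 1))
    expect_true(all(diff(tr$stages$n_drivers) >= 0))
    expect_true(all(diff(tr$stages$cumulative_failed) >= 0))
  }
})

test_that("total damage is non-increasing in the tolerance parameter", {
  g <- generate_er(150, 5, seed = 31)
  loads <- compute_loads(g)
  trig <- highest_load_edge(g, loads, 1)
  damage <- vapply(c(0, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6), function(a) {
    run_cascade(g, assign_capacities(loads, a), trig, instrument = FALSE)$total_failed
  }, numeric(1))
  expect_true(all(diff(damage) <= 0))
})
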