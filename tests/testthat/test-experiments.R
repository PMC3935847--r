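small_cfg <- function(...) {
  experiment_config("er", n = 60, mean_degree = 4, alpha = 0.3,
                    f_grid = c(0, 0.2, 1), n_realizations = 3,
                    master_seed = 101, ...)
}

test_that("sweep endpoints: f = 0 gives intact N_D, f = 1 gives N_D = N", {
  sw <- fraction_sweep(small_cfg())
  c0 <- sw$cells[sw$cells$f == 0, ]
  expect_equal(c0$n_drivers_final, c0$intact_nd)
  expect_equal(c0$total_failed, rep(0L, nrow(c0)))
  c1 <- sw$cells[sw$cells$f == 1, ]
  expect_equal(c1$n_drivers_final, rep(60L, nrow(c1)))
  expect_true(all(sw$cells$n_drivers_final >= sw$cells$intact_nd))
})

test_that("failed-edge census fractions sum to 1 and flag the empty case", {
  sw <- fraction_sweep(small_cfg())
  def <- sw$cells[sw$cells$census_defined, ]
  expect_gt(nrow(def), 0L)
  expect_equal(def$density_critical + def$density_ordinary + def$density_redundant,
               rep(1, nrow(def)))
  undef <- sw$cells[!sw$cells$census_defined, ]
  expect_true(all(is.na(undef$density_critical)))
  expect_true(all(undef$f == 0))

  g <- digraph(rbind(c(1L, 2L)))
  cats <- classify_edges(g)
  tr <- run_cascade(g, assign_capacities(compute_loads(g), 0.3), 1L)
  cen <- failed_edge_census(cats, tr)
  expect_equal(cen$critical, 1)  # a lone edge is critical
  expect_equal(cen$ordinary + cen$redundant, 0)
})

test_that("realization aggregation computes means and standard errors", {
  cells <- data.frame(
    realization = 1:3, strategy = "RA", f = 0.1,
    intact_nd = 5L, n_drivers_final = c(1, 2, 3), total_failed = c(2, 2, 2),
    n_attacked = 1L, density_critical = c(1, 1, NA),
    density_ordinary = c(0, 0, NA), density_redundant = c(0, 0, NA),
    census_defined = c(TRUE, TRUE, FALSE)
  )
  agg <- aggregate_realizations(cells)
  expect_equal(agg$mean_nd_final, 2)
  expect_equal(agg$se_nd_final, stats::sd(1:3) / sqrt(3))
  expect_equal(round(agg$se_nd_final, 3), 0.577)
  expect_equal(agg$se_total_failed, 0)
  expect_equal(agg$n_census_defined, 2L)
  expect_equal(agg$mean_density_critical, 1)
  # single realization: mean is the record, SE reported as 0
  agg1 <- aggregate_realizations(cells[1, ])
  expect_equal(agg1$mean_nd_final, 1)
  expect_equal(agg1$se_nd_final, 0)
  expect_error(aggregate_realizations(cells[0, ]), "no realization")
})

test_that("single-trigger experiment pads and averages stage traces", {
  cfg <- experiment_config("er", n = 80, mean_degree = 4, alpha = 0.2,
                           n_realizations = 4, master_seed = 7)
  r <- single_trigger_experiment(cfg)
  expect_equal(nrow(r$realizations), 4L)
  expect_equal(r$realizations$delta_nd,
               r$realizations$final_nd - r$realizations$intact_nd)
  expect_equal(nrow(r$stage_summary), max(r$realizations$n_stages) + 1L)
  # padded averages are bounded by the per-realization extremes
  expect_true(all(r$stage_summary$mean_n_drivers <= max(r$realizations$final_nd)))
  expect_true(all(diff(r$stage_summary$mean_n_drivers) >= 0))

  # with a huge tolerance every trace is exactly stage 0
  cfg2 <- experiment_config("er", n = 80, mean_degree = 4, alpha = 1e9,
                            n_realizations = 3, master_seed = 7)
  r2 <- single_trigger_experiment(cfg2)
  expect_equal(nrow(r2$stage_summary), 1L)
  expect_equal(r2$realizations$total_failed, rep(0L, 3L))
})

test_that("experiments are byte-identical under the same master seed", {
  sw1 <- fraction_sweep(small_cfg())
  sw2 <- fraction_sweep(small_cfg())
  expect_identical(sw1$cells, sw2$cells)
  expect_identical(sw1$summary, sw2$summary)
  r1 <- single_trigger_experiment(small_cfg())
  r2 <- single_trigger_experiment(small_cfg())
  expect_identical(r1$realizations, r2$realizations)
  expect_identical(r1$stage_summary, r2$stage_summary)
  # a different master seed changes the realizations
  sw3 <- fraction_sweep(experiment_config("er", n = 60, mean_degree = 4,
                                          alpha = 0.3, f_grid = c(0, 0.2, 1),
                                          n_realizations = 3, master_seed = 102))
  expect_false(identical(sw1$cells, sw3$cells))
})

test_that("a fixed user-supplied graph varies only through attack seeds", {
  g <- generate_er(60, 4, seed = 1)
  cfg <- experiment_config(graph = g, alpha = 0.3, f_grid = c(0.3),
                           strategies = "RA", n_realizations = 4,
                           master_seed = 5)
  sw <- fraction_sweep(cfg)
  expect_equal(unique(sw$cells$intact_nd), driver_report(g)$n_drivers)
  expect_gt(length(unique(sw$cells$n_drivers_final)), 0L)
})
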