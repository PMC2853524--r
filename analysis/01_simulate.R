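#!/usr/bin/env Rscript
# Build the synthetic study: a toy metabolic network with analytically known
# optima, a phosphate-depletion constraint schedule (switch at 34 h), and a
# 200-gene expression matrix derived from the closed-form flux series with
# injected anticorrelated, constant-flux, unexpressed and zero-flux genes.
# Everything downstream (02-05) consumes the files written here.

library(switchFBA)

seed <- as.integer(Sys.getenv("SWITCHFBA_SEED", "1"))
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(n_genes = 200, noise_sd = 0.1, seed = seed)
tm <- make_toy_model(spec)
sch <- make_schedule(spec)

write_sbml(tm$model, file.path(out, "toy_model.xml"))
write_model_tables(tm$model, file.path(out, "metabolites.tsv"),
                   file.path(out, "reactions.tsv"))

# schedule as the measurement table it was built from
meas <- data.frame(time_h = sch$times,
                   glucose = -sch$exchange_bounds$EX_glc[, 1],
                   phosphate = -sch$exchange_bounds$EX_pho[, 1],
                   oxygen = -sch$exchange_bounds$EX_o2[, 1],
                   actinorhodin = sch$antibiotic_rates$EX_act)
write.table(meas, file.path(out, "schedule.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ats <- toy_flux_series(tm$record, sch)
matching <- match_genes(tm$model, ats)
sim <- simulate_expression(ats, matching, spec)
write_expression(sim$expr, file.path(out, "expression.tsv"))
write.table(sim$truth, file.path(out, "truth_labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
saveRDS(list(spec = spec, record = tm$record), file.path(out, "generator.rds"))

s <- model_summary(tm$model)
cat(sprintf("toy model: %d metabolites, %d reactions, %d genes\n",
            s$n_metabolites, s$n_reactions, s$n_genes))
cat(sprintf("closed-form optimum at initial rates: mu* = %.4f /h\n",
            tm$record$mu_star))
cat(sprintf("schedule: %d time points (%g-%g h), phosphate depleted at %g h\n",
            length(sch$times), min(sch$times), max(sch$times), sch$switch_time))
cat(sprintf("expression: %d genes + %d controls; injected %d anticorrelated\n",
            nrow(sim$truth), length(sim$expr$control_rows),
            sum(sim$truth$label == "anticorrelated")))
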