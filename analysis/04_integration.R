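#!/usr/bin/env Rscript
# Transcriptome-flux integration: match every gene to its dominant reaction,
# correlate predicted flux with observed expression over time, classify at
# r = +/-0.5, and run the zero-flux and essentiality screens. Results are
# compared against the generator's injected truth labels.

library(switchFBA)

out <- "results/integration"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
model <- read_sbml("results/synthetic/toy_model.xml")
expr <- read_expression("results/synthetic/expression.tsv")
truth <- read.delim("results/synthetic/truth_labels.tsv")
flux <- read.delim("results/dynamic_fba/flux_matrix.tsv", check.names = FALSE)
growth <- read.delim("results/dynamic_fba/growth_curve.tsv")

fm <- as.matrix(flux[, -1]); rownames(fm) <- flux$reaction
ts <- structure(list(times = growth$time_h, flux_matrix = fm,
                     growth_curve = growth$mu, status = growth$status,
                     resolution_method = "parsimonious"),
                class = "flux_time_series")
# controls are the probe rows absent from the truth table
expr$control_rows <- setdiff(rownames(expr$values), truth$gene)

matching <- match_genes(model, ts)
report <- classify(correlate(ts, expr, matching))
write.table(report$profiles, file.path(out, "gene_correlations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cc <- report$class_counts
fr <- attr(cc, "fractions")
cat(sprintf("matched %d genes; %d excluded (%s)\n", length(matching),
            sum(report$profiles$excluded),
            paste(names(table(report$profiles$reason)),
                  table(report$profiles$reason), collapse = ", ")))
cat(sprintf("classes: %d correlated (%.0f%%), %d uncorrelated (%.0f%%), %d anticorrelated\n",
            cc["correlated"], 100 * fr["correlated"],
            cc["uncorrelated"], 100 * fr["uncorrelated"],
            cc["anticorrelated"]))

p <- merge(report$profiles, truth, by = "gene")
anti_rec <- mean(p$class[p$label == "anticorrelated"] == "anticorrelated",
                 na.rm = TRUE)
cor_rec <- mean(p$class[p$label == "correlated"] == "correlated", na.rm = TRUE)
cat(sprintf("recovery: %.0f%% of injected correlated, %.0f%% of injected anticorrelated\n",
            100 * cor_rec, 100 * anti_rec))

zf <- zero_flux_genes(matching, ts)
ess <- essential_expression_summary(ts, expr, matching)
write.table(data.frame(gene = zf), file.path(out, "zero_flux_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(gene = ess$essential_genes),
            file.path(out, "essential_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("zero-flux screen: %d genes; essentiality screen: %d genes\n",
            length(zf), length(ess$essential_genes)))
cat(sprintf("median log2 expression: essential %.2f, non-essential %.2f, controls %.2f\n",
            ess$median_essential, ess$median_non_essential,
            ess$median_controls))
cat(sprintf("essential genes below the %.1f cutoff: %d\n",
            ess$low_cutoff, length(ess$low_expressed_essential)))
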