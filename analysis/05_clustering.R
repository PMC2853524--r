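#!/usr/bin/env Rscript
# Unsupervised hierarchical clustering of the expression profiles that enter
# the correlation analysis (12 clusters, correlation distance on z-scored
# profiles, average linkage) and the genome-order track joining cluster
# membership with correlation class -- the tabular form of the two-track
# genome map.

library(switchFBA)

out <- "results/clustering"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
expr <- read_expression("results/synthetic/expression.tsv")
truth <- read.delim("results/synthetic/truth_labels.tsv")
cors <- read.delim("results/integration/gene_correlations.tsv")

genes <- cors$gene
sub <- expression_matrix(expr$values[genes, , drop = FALSE], expr$times)
assignment <- hierarchical_clusters(sub, k = 12)

write.table(data.frame(gene = names(assignment$cluster),
                       cluster = unname(assignment$cluster)),
            file.path(out, "clusters.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cluster = rownames(assignment$mean_profiles),
                       size = assignment$sizes, assignment$mean_profiles,
                       check.names = FALSE),
            file.path(out, "cluster_mean_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

report <- list(profiles = cors)
class(report) <- "correlation_report"
track <- genome_track(assignment, report, gene_order = sort(genes))
write.table(track, file.path(out, "genome_track.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("%d profiles in %d clusters; sizes: %s\n", length(genes),
            assignment$k, paste(assignment$sizes, collapse = ", ")))
anti <- track$gene[!is.na(track$class) & track$class == "anticorrelated"]
cl_anti <- table(track$cluster[match(anti, track$gene)])
cat(sprintf("anticorrelated genes concentrate in %d of %d clusters\n",
            length(cl_anti), assignment$k))
up <- truth$gene[truth$label %in% c("zero_flux", "constant_flux")]
cat(sprintf("%d expressed-but-unpredicted genes (zero/constant flux) for follow-up\n",
            length(up)))
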