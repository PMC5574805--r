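#!/usr/bin/env Rscript
# The four-step concordance analysis across the five models (all traits,
# NA-excluded species, and the habitat / trophic / behavior subdatabases):
# Mantel test of distance matrices, tree-topology comparison on normalized
# trees, phylogenetic signal of Brownian functional identity, and the
# correlation of phylogenetic vs functional singularity.

suppressPackageStartupMessages(library(phylofunc))

in_dir <- "results/synthetic"
out_dir <- "results/concordance"

tree <- read_newick(file = file.path(in_dir, "tree.nwk"))
schema <- read_trait_schema(file.path(in_dir, "schema.yaml"))
traits <- read_trait_table(file.path(in_dir, "traits.csv"), schema)

report <- run_full_analysis(tree, traits,
                            config = list(seed = 20260926L, n_perm = 999,
                                          n_replicates = 50))
write_report(report, out_dir)
print(report)

tabs <- report_tables(report)
cat("\nDistance-matrix concordance (Mantel):\n")
print(tabs$mantel, row.names = FALSE)
cat("\nTree comparison on normalized trees:\n")
print(tabs$tree_comparison, row.names = FALSE)
cat("\nPhylogenetic signal of functional identity:\n")
print(tabs$signal, row.names = FALSE)
cat("\nSingularity correlation (PS ~ FS):\n")
print(tabs$singularity, row.names = FALSE)

cat("\nReading: under Brownian (conservative) traits the Mantel r is",
    "positive and significant, yet RTD stays high - pairwise distances",
    "agree while exact topologies differ, the dissociation the analysis",
    "is designed to expose.\nTables and report.json written to", out_dir, "\n")
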