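#!/usr/bin/env Rscript
# Stage 4: node importance, the functional response space, and the
# un-optimized effective targets.
#
# Each node's importance (Nim) is its shortest-path betweenness term
# multiplied by a squared community-proximity factor.  Nodes at or above
# the mean importance form the functional response space (FRS); its gene
# nodes are the key response proteins, subtyped by membership in the
# disease-gene and ingredient-target sets.  The UET reference is the
# plain intersection of the two sets.

library(cfig)

study <- read_study("results/study")
merged_nodes <- read.delim("results/merged_nodes.tsv")
merged_edges <- read.delim("results/merged_edges.tsv")
merged <- weighted_network(merged_nodes, merged_edges)

nim <- compute_nim(merged, assign_communities(merged))
for (m in c("degree", "closeness", "clustering_coefficient")) {
  nim[[m]] <- baseline_centrality(merged, m)$score
}

disease_genes <- study$evidence$gene[study$evidence$gene %in% merged$nodes$id]
target_genes <- unique(study$associations$target_gene)
frs <- select_frs(nim, merged, mode = "mean",
                  disease_genes = disease_genes, target_genes = target_genes)
print(frs)

nim$kept <- nim$id %in% frs$kept
write.table(nim, "results/nim.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

uet <- compute_uet(disease_genes, target_genes)
writeLines(uet, "results/uet.txt")
writeLines(frs$key_proteins, "results/key_proteins.txt")

cat(sprintf("\nFRS: %d / %d nodes kept; %d key response proteins; %d UETs\n",
            length(frs$kept), nrow(nim), length(frs$key_proteins),
            length(uet)))
cat(sprintf("rank correlation of Nim with degree: %.2f, with closeness: %.2f\n",
            cor(nim$nim, nim$degree, method = "spearman"),
            cor(nim$nim, nim$closeness, method = "spearman")))
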