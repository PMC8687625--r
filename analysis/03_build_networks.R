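#!/usr/bin/env Rscript
# Stage 3: network construction.
#
# Three networks: (1) the weighted disease gene regulatory network - the
# evidence genes mapped onto the base interactome, each weighted by
# induced degree x relevance score x literature count; (2) the bipartite
# ingredient-target (I-T) network of the retained ingredients; (3) their
# merge, which also retains base-interactome edges among all mapped genes.

library(cfig)

study <- read_study("results/study")
decisions <- read.delim("results/filter_decisions.tsv")
retained <- decisions$ingredient_id[decisions$retained]
assoc <- study$associations[study$associations$ingredient_id %in% retained, ]

dres <- build_disease_network(study$base_ppi, study$evidence)
cat(sprintf("disease network: %d nodes, %d edges (%d evidence genes not mappable)\n",
            nrow(dres$network$nodes), nrow(dres$network$edges),
            length(dres$dropped)))
top <- dres$network$nodes[order(-dres$network$nodes$weight), ][1:5, ]
cat("heaviest disease genes (degree x relevance x reports):\n")
print(top, row.names = FALSE)

itres <- build_it_network(retained, assoc)
cat(sprintf("\nI-T network: %d associations over %d ingredients, mean %.2f targets/ingredient\n",
            itres$n_associations, length(itres$target_counts),
            itres$mean_targets))

merged <- merge_networks(dres$network, itres$network, base_ppi = study$base_ppi)
print(merged)

write.table(merged$nodes, "results/merged_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(merged$edges, "results/merged_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
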