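#!/usr/bin/env Rscript
# Stage 5: validate the key response proteins against the UET reference.
#
# Three indicators: gene-set coverage of the UETs by the key proteins,
# and coverage of the UET-enriched annotation terms by the key-protein
# enriched terms (exact hypergeometric upper-tail test at alpha = 0.05,
# no multiple-testing correction by default).

library(cfig)

study <- read_study("results/study")
merged_nodes <- read.delim("results/merged_nodes.tsv")
background <- merged_nodes$id[merged_nodes$role == "gene"]
key <- readLines("results/key_proteins.txt")
uet <- readLines("results/uet.txt")

enr <- enrich(intersect(key, background), study$annotations, background)
write.table(enr, "results/enrichment_key_proteins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("key response proteins: %d/%d terms significant at p < 0.05\n",
            sum(enr$significant), nrow(enr)))

ind <- evaluate_frs(key, uet, list(terms = study$annotations), background)
cat(sprintf("indicator 1 - UET gene coverage:        %6.2f%% (%d/%d)\n",
            ind$genes$percent, ind$genes$shared, ind$genes$n_reference))
cat(sprintf("indicator 2 - enriched-term coverage:   %6.2f%% (%d/%d)\n",
            ind$terms$percent, ind$terms$shared, ind$terms$n_reference))

jsonlite::write_json(lapply(ind, unclass), "results/coverage_indicators.json",
                     auto_unbox = TRUE)
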