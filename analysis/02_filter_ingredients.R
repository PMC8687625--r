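#!/usr/bin/env Rscript
# Stage 2: ADME admission of candidate ingredients.
#
# The rule is Caco-2 permeability > -0.4 (strict) and drug-likeness
# >= 0.18 (inclusive); compounds detected in the preparation and reported
# in the literature are whitelisted past the rule.  Applied both to the
# synthetic study and, as a sanity check, to the packaged 60-ingredient
# CFIG reference table, every member of which is either ADME-admissible
# or a literature compound.

library(cfig)

study <- read_study("results/study")
decisions <- filter_ingredients(study$ingredients)
write.table(decisions, "results/filter_decisions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("synthetic study: retained %d / %d ingredients (%d by ADME, %d whitelisted)\n",
            sum(decisions$retained), nrow(decisions),
            sum(decisions$reason == "adme"),
            sum(decisions$reason %in% c("literature", "adme+literature"))))

t3 <- read_ingredients(cfig_fixture("table3_cfig"))
d3 <- filter_ingredients(t3)
cat(sprintf("reference CFIG table: %d/60 retained, %d via the literature whitelist\n",
            sum(d3$retained), sum(!d3$passed_adme)))
stopifnot(all(d3$retained))
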