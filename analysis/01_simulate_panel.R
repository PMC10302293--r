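#!/usr/bin/env Rscript
# Build the synthetic accession panel that stands in for the field-collected
# cherry dataset: five groups (CC, WC, RC, EC, MC) across 12 populations in
# four geographic regions, 908 accessions, one ITS-sized 710-bp locus.
# History: Microcerasus diverges first, European cherries second, wild
# Chinese cherry splits from the wild relatives ~34,200 years ago, and the
# cultivated group is domesticated ~2,660 years ago.

library(cherrypop)

dir.create("results", showWarnings = FALSE)
panel <- make_fixture("five_group", seed = 1)
write_dataset(panel, "results/panel")

cat("Panel:", nrow(panel$samples), "accessions,",
    length(unique(panel$samples$deme)), "populations,",
    length(unique(panel$samples$group)), "groups\n")
print(table(panel$samples$group))
cat("Wrote results/panel.fasta, results/panel.tsv, results/panel.truth.json\n")
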