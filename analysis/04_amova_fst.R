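#!/usr/bin/env Rscript
# Hierarchical AMOVA (groups / populations within groups / within
# populations) on Tamura-Nei distances, plus pairwise Phi-ST matrices at the
# group and subgroup level. Run 01_simulate_panel.R first.

library(cherrypop)

ds <- read_dataset("results/panel.fasta", "results/panel.tsv")
ht <- collapse_haplotypes(recode_indels(ds), relabel = "by_frequency")
dm <- suppressWarnings(tn93(ht))

cat("AMOVA over the five groups:\n")
am5 <- amova(ht, dm, n_perm = 1000, seed = 21)
print(am5)
write_amova_table(am5, "results/amova_groups.tsv", label = "five groups")

cat("\nAMOVA over the three Chinese groups (CC, WC, RC):\n")
ht3 <- subset_haplotypes(ht, group = c("CC", "WC", "RC"))
dm3 <- suppressWarnings(tn93(ht3))
am3 <- amova(ht3, dm3, n_perm = 1000, seed = 23)
print(am3)
write_amova_table(am3, "results/amova_chinese.tsv",
                  label = "three groups (CC, WC, RC)")

cat("\nPairwise Phi-ST between groups:\n")
fst_g <- pairwise_fst(ht, dm, n_perm = 500, seed = 25, level = "group")
print(round(fst_g$fst, 4))
write_fst_matrix(fst_g, "results/fst_groups.tsv")

fst_s <- pairwise_fst(ht, dm, n_perm = 200, seed = 27, level = "deme")
write_fst_matrix(fst_s, "results/fst_populations.tsv")
cat("\nPopulation-level Phi-ST range:",
    sprintf("%.4f..%.4f\n", min(fst_s$fst[upper.tri(fst_s$fst)]),
            max(fst_s$fst[upper.tri(fst_s$fst)])))
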