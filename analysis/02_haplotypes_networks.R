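#!/usr/bin/env Rscript
# Collapse the panel into haplotypes and draw the median-joining network of
# the Chinese groups (CC + WC + RC) -- the phylogeographic network on which
# domestication structure is read. Run 01_simulate_panel.R first.

library(cherrypop)

ds <- read_dataset("results/panel.fasta", "results/panel.tsv")
ra <- recode_indels(ds)
ht <- collapse_haplotypes(ra, relabel = "by_frequency")
print(summarize_alignment(ra))
write_haplotype_table(ht, "results/haplotypes.tsv")
write_haplotype_fasta(ht, "results/haplotypes.fasta")

ht3 <- subset_haplotypes(ht, group = c("CC", "WC", "RC"))
net <- median_joining(ht3)
print(net)
export_network(net, "results/network_chinese.graphml", "graphml")
export_network(net, "results/network_chinese_edges.tsv", "edgelist")
export_network(net, "results/network_chinese_nodes.tsv", "nodes")

ns <- network_summaries(net)
hubs <- head(ns$nodes[order(-ns$nodes$betweenness), c("id", "frequency",
                                                      "degree")], 5)
cat("Most central haplotypes (candidates for ancestral nodes):\n")
print(hubs, row.names = FALSE)
if (!is.null(ns$composition)) {
  top <- rownames(ns$composition)[1]
  cat(sprintf("Group composition of %s: %s\n", top,
              paste(sprintf("%s %.1f%%", colnames(ns$composition),
                            ns$composition[1, ]), collapse = ", ")))
}

# graph-based sub-lineages after cutting links longer than 8 steps (a
# purely topological delimitation, not a model-based clustering)
memb <- cut_sublineages(net, threshold = 8)
cat("Sub-networks after cutting links > 8 steps:",
    length(unique(memb)), "\n")
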