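#!/usr/bin/env Rscript
# Build the bipartite miRNA-target network over the differentially
# expressed miRNAs, report the miRNAs excluded for lack of multi-database
# support, partition targets by regulator direction (Venn), and select hub
# mRNAs with at least 4 interacting miRNAs. Writes the edge list, GraphML,
# hub table, Venn counts and exclusion report under results/.

suppressPackageStartupMessages(library(mirhub))

scored_tab <- readr::read_tsv("results/scored_interactions.tsv",
                              show_col_types = FALSE)
scored <- tibble::tibble(
  mirna_id = scored_tab$mirna_id, gene_id = scored_tab$gene_id,
  dbs_present = strsplit(scored_tab$dbs_present, ";", fixed = TRUE),
  compound_score = scored_tab$compound_score,
  retained = scored_tab$retained
)
expressions <- read_expression_table("results/sim_inputs/expression.tsv")

net <- build_network(scored, expressions)
print(net)
export_edge_list(net, "results/edge_list.tsv")
export_graphml(net, "results/network.graphml")

excl <- excluded_mirnas(expressions, net)
readr::write_tsv(
  tibble::tibble(
    mirna_id = c(excl$up, excl$down),
    direction = c(rep("UP", length(excl$up)), rep("DOWN", length(excl$down)))
  ),
  "results/excluded_mirnas.tsv"
)
cat(sprintf("excluded for lack of support: %d upregulated, %d downregulated\n",
            length(excl$up), length(excl$down)))

venn <- venn_partition(net)
readr::write_tsv(
  tibble::tibble(class = c("up_only", "down_only", "both", "union_total",
                           "naive_sum"),
                 count = c(venn$up_only, venn$down_only, venn$both,
                           venn$union_total, venn$naive_sum)),
  "results/venn_counts.tsv"
)
cat(sprintf(
  "targets: %d by up only, %d by down only, %d by both (union %d, naive sum %d)\n",
  venn$up_only, venn$down_only, venn$both, venn$union_total, venn$naive_sum
))

hubs <- select_hubs(net, scoring_config(), mode = "TOTAL")
readr::write_tsv(hubs, "results/hub_table.tsv")
cat(sprintf("%d hub mRNAs with >= 4 interactions:\n", sum(hubs$is_hub)))
print(hubs[hubs$is_hub, ], n = Inf)
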