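#!/usr/bin/env Rscript
# GO over-representation of the target study sets against the annotation
# background: one-sided hypergeometric test per term with Bonferroni
# correction over the terms tested. Study sets mirror the Venn partition
# (up-targets, down-targets, common targets) plus the hub genes.
# Writes results/enrichment_<set>.tsv.

suppressPackageStartupMessages(library(mirhub))

annotation <- read_annotation("results/sim_inputs/annotation.tsv")
venn_genes <- local({
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
  v <- venn_partition(net)
  hubs <- select_hubs(net)
  list(
    up_targets = c(v$genes_up_only, v$genes_both),
    down_targets = c(v$genes_down_only, v$genes_both),
    common_targets = v$genes_both,
    hubs = hubs$gene_id[hubs$is_hub]
  )
})

for (nm in names(venn_genes)) {
  study <- intersect(venn_genes[[nm]], annotation$background)
  if (length(study) == 0L) {
    cat(sprintf("%s: no annotated genes, skipped\n", nm))
    next
  }
  res <- enrich(study, annotation, alpha = 0.05, method = "HYPERGEOMETRIC")
  write_enrichment(res, sprintf("results/enrichment_%s.tsv", nm))
  top <- res[res$enriched, ]
  cat(sprintf("%s (n = %d annotated genes): %d terms enriched after Bonferroni\n",
              nm, length(study), nrow(top)))
  if (nrow(top) > 0) {
    print(top[, c("term_id", "k", "n", "K", "N", "p_raw", "p_adj")],
          n = min(nrow(top), 10))
  }
}
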