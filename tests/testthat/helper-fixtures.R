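# builders and independent oracles shared across test files

rec <- function(mirna, gene, db, score = NA_real_) {
  tibble::tibble(
    mirna_id = mirna, gene_id = gene, db_name = db,
    db_class = ifelse(db == "MIRTARBASE", "VALIDATED", "PREDICTED"),
    score = score
  )
}

# random raw record table for property tests
random_records <- function(n, n_mirna = 8, n_gene = 10) {
  db <- sample(c("MIRDB", "MICRORNA_ORG", "MIRTARBASE"), n, replace = TRUE)
  score <- rep(NA_real_, n)
  score[db == "MIRDB"] <- runif(sum(db == "MIRDB"), 50, 100)
  score[db == "MICRORNA_ORG"] <- runif(sum(db == "MICRORNA_ORG"), -3, 0)
  rec(
    sprintf("rno-mir-%d", sample.int(n_mirna, n, replace = TRUE)),
    sprintf("G%d", sample.int(n_gene, n, replace = TRUE)),
    db, score
  )
}

# brute-force retention oracle: enumerates every (miRNA, gene, db) triple
# independently of the scoring module's grouped implementation
oracle_retained <- function(records, config = scoring_config()) {
  pairs <- unique(records[, c("mirna_id", "gene_id")])
  keep <- character(0)
  for (i in seq_len(nrow(pairs))) {
    mi <- pairs$mirna_id[i]; ge <- pairs$gene_id[i]
    dbs <- character(0)
    for (j in seq_len(nrow(records))) {
      if (records$mirna_id[j] != mi || records$gene_id[j] != ge) next
      db <- records$db_name[j]
      ok <- switch(db,
        MIRDB = records$score[j] > config$mirdb_min_exclusive,
        MICRORNA_ORG = records$score[j] < config$mirsvr_max_exclusive,
        MIRTARBASE = TRUE)
      if (ok) dbs <- union(dbs, db)
    }
    s <- config$points_per_predicted_db *
      sum(dbs %in% c("MIRDB", "MICRORNA_ORG")) +
      config$points_validated * ("MIRTARBASE" %in% dbs)
    if (s >= config$retention_min_score) keep <- c(keep, paste(mi, ge))
  }
  sort(keep)
}

# exhaustive hypergeometric upper tail, independent of stats::phyper
oracle_hyper_tail <- function(k, N, K, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# minimal evidence tibble for a set of databases
ev <- function(mirna, gene, dbs) {
  tibble::tibble(mirna_id = mirna, gene_id = gene,
                 dbs_present = list(sort(dbs)),
                 mirdb_score = NA_real_, mirsvr_score = NA_real_)
}

# ingest the four database files named in an emit_files() manifest
ingest_from_manifest <- function(manifest) {
  paths <- attr(manifest, "paths")
  read_all_databases(list(
    mirdb = paths[["mirdb.tsv"]],
    microrna_org_conserved = paths[["microrna_org_conserved.tsv"]],
    microrna_org_nonconserved = paths[["microrna_org_nonconserved.tsv"]],
    mirtarbase = paths[["mirtarbase.tsv"]]
  ))
}

# run ingest -> filter -> collate -> score on an emitted synthetic study
score_emitted <- function(manifest, config = scoring_config()) {
  recs <- ingest_from_manifest(manifest)
  retain_interactions(collate_evidence(apply_quality_filter(recs, config)),
                      config)
}

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
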