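# small scored tibble builder: all rows retained unless stated
scored_edges <- function(...) {
  rows <- list(...)
  tibble::tibble(
    mirna_id = vapply(rows, `[[`, character(1), 1),
    gene_id = vapply(rows, `[[`, character(1), 2),
    dbs_present = lapply(rows, function(r)
      if (length(r) > 3) r[[4]] else c("MIRDB", "MICRORNA_ORG")),
    compound_score = 1.0,
    retained = vapply(rows, function(r)
      if (length(r) > 2) as.logical(r[[3]]) else TRUE, logical(1))
  )
}

expr_tab <- function(ids, dirs) tibble::tibble(mirna_id = ids, direction = dirs)

test_that("network keeps retained edges of expressed miRNAs only", {
  scored <- scored_edges(
    list("rno-mir-1", "G1"), list("rno-mir-2", "G1"),
    list("rno-mir-3", "G2"),              # not differentially expressed
    list("rno-mir-1", "G3", FALSE)        # not retained
  )
  expr <- expr_tab(c("rno-mir-1", "rno-mir-2"), c("UP", "UP"))
  net <- build_network(scored, expr)
  expect_equal(nrow(net$mirna_nodes), 2L)
  expect_equal(net$gene_nodes, "G1")
  expect_equal(nrow(net$edges), 2L)
  expect_equal(net$n_dropped_foreign_mirna, 1L)
  # bipartite: every edge joins a miRNA node to a gene node
  expect_true(all(net$edges$mirna_id %in% net$mirna_nodes$mirna_id))
  expect_true(all(net$edges$gene_id %in% net$gene_nodes))
})

test_that("an empty retained set yields an empty network with a warning", {
  scored <- scored_edges(list("rno-mir-1", "G1", FALSE))
  expect_warning(net <- build_network(scored, expr_tab("rno-mir-1", "UP")),
                 "no edges")
  expect_equal(nrow(net$edges), 0L)
  expect_equal(length(net$gene_nodes), 0L)
})

test_that("excluded miRNAs partition by direction, disjoint from the network", {
  scored <- scored_edges(list("rno-mir-1", "G1"))
  expr <- expr_tab(c("rno-mir-1", "rno-mir-2", "rno-mir-3"),
                   c("UP", "UP", "DOWN"))
  net <- build_network(scored, expr)
  excl <- excluded_mirnas(expr, net)
  expect_equal(excl$up, "rno-mir-2")
  expect_equal(excl$down, "rno-mir-3")
  expect_length(intersect(c(excl$up, excl$down),
                          net$mirna_nodes$mirna_id), 0)
  # all covered -> both empty
  full <- build_network(scored, expr_tab("rno-mir-1", "UP"))
  expect_equal(excluded_mirnas(expr_tab("rno-mir-1", "UP"), full),
               list(up = character(0), down = character(0)))
})

test_that("Venn partition classifies each gene exactly once", {
  scored <- scored_edges(
    list("rno-mir-u1", "A"), list("rno-mir-u1", "C"),
    list("rno-mir-d1", "B"), list("rno-mir-d1", "C")
  )
  expr <- expr_tab(c("rno-mir-u1", "rno-mir-d1"), c("UP", "DOWN"))
  v <- venn_partition(build_network(scored, expr))
  expect_equal(c(v$up_only, v$down_only, v$both), c(1, 1, 1))
  expect_equal(v$union_total, 3)
  expect_equal(v$naive_sum, 4)
  expect_equal(v$genes_both, "C")
})

test_that("Venn counts match brute-force per-gene classification randomly", {
  set.seed(31)
  for (trial in 1:5) {
    n_m <- 12; n_g <- 25
    ids <- sprintf("rno-mir-%d", 1:n_m)
    dirs <- sample(c("UP", "DOWN"), n_m, replace = TRUE)
    e <- unique(tibble::tibble(
      mirna_id = sample(ids, 60, replace = TRUE),
      gene_id = sprintf("G%d", sample.int(n_g, 60, replace = TRUE))
    ))
    scored <- tibble::tibble(
      mirna_id = e$mirna_id, gene_id = e$gene_id,
      dbs_present = replicate(nrow(e), c("MIRDB", "MICRORNA_ORG"),
                              simplify = FALSE),
      compound_score = 1.0, retained = TRUE
    )
    net <- build_network(scored, expr_tab(ids, dirs))
    v <- venn_partition(net)
    # brute force: classify every gene from the raw edge list
    cls <- vapply(net$gene_nodes, function(g) {
      d <- unique(dirs[match(e$mirna_id[e$gene_id == g], ids)])
      if (all(c("UP", "DOWN") %in% d)) "both" else if (d == "UP") "up" else "down"
    }, character(1))
    expect_equal(v$up_only, sum(cls == "up"))
    expect_equal(v$down_only, sum(cls == "down"))
    expect_equal(v$both, sum(cls == "both"))
    expect_equal(v$up_only + v$down_only + v$both, length(net$gene_nodes))
  }
})

test_that("hub selection applies the degree threshold in both modes", {
  # gene Gk has total degree k; G5/G6 mix in DOWN partners
  rows <- list()
  for (k in 1:6) {
    ups <- min(k, 4)
    for (i in seq_len(ups)) rows <- c(rows, list(list(sprintf("rno-mir-u%d", i),
                                                      sprintf("G%d", k))))
    for (i in seq_len(k - ups)) rows <- c(rows, list(list(sprintf("rno-mir-d%d", i),
                                                          sprintf("G%d", k))))
  }
  scored <- do.call(scored_edges, rows)
  expr <- expr_tab(c(sprintf("rno-mir-u%d", 1:4), sprintf("rno-mir-d%d", 1:2)),
                   c(rep("UP", 4), rep("DOWN", 2)))
  net <- build_network(scored, expr)
  hubs <- select_hubs(net, scoring_config(), mode = "TOTAL")
  expect_equal(hubs$gene_id[hubs$is_hub], c("G6", "G5", "G4"))
  expect_equal(min(hubs$degree_total[hubs$is_hub]), 4L)
  expect_equal(hubs$degree_total, hubs$degree_up + hubs$degree_down)
  # sorted by degree desc, gene asc
  expect_equal(hubs$gene_id, sprintf("G%d", 6:1))

  up_only <- select_hubs(net, scoring_config(), mode = "UP_ONLY")
  # G5 has degree_up 4 -> hub in UP_ONLY too; a 3-up/2-down gene would not be
  expect_true(all(up_only$gene_id[up_only$is_hub] %in%
                    hubs$gene_id[hubs$is_hub]))
  mixed <- do.call(scored_edges, c(
    lapply(1:3, function(i) list(sprintf("rno-mir-u%d", i), "GX")),
    lapply(1:2, function(i) list(sprintf("rno-mir-d%d", i), "GX"))))
  net2 <- build_network(mixed, expr)
  expect_true(select_hubs(net2, mode = "TOTAL")$is_hub[1])
  expect_false(select_hubs(net2, mode = "UP_ONLY")$is_hub[1])
  # threshold 1 makes every gene a hub
  all_hubs <- select_hubs(net, scoring_config(hub_min_degree = 1))
  expect_true(all(all_hubs$is_hub))
})

test_that("hub sets shrink monotonically with the threshold", {
  set.seed(77)
  truth <- generate_ground_truth(generator_config(seed = 77, n_genes = 120,
                                                  non_hub_target_frac = 0.3))
  man <- emit_files(truth, withr::local_tempdir())
  paths <- attr(man, "paths")
  recs <- read_all_databases(list(
    mirdb = paths[["mirdb.tsv"]],
    microrna_org_conserved = paths[["microrna_org_conserved.tsv"]],
    microrna_org_nonconserved = paths[["microrna_org_nonconserved.tsv"]],
    mirtarbase = paths[["mirtarbase.tsv"]]))
  scored <- retain_interactions(collate_evidence(apply_quality_filter(recs)))
  net <- build_network(scored, truth$expressions)
  prev <- NULL
  for (k in 1:7) {
    hk <- select_hubs(net, scoring_config(hub_min_degree = k))
    hub_set <- hk$gene_id[hk$is_hub]
    if (!is.null(prev)) expect_true(all(hub_set %in% prev))
    up <- select_hubs(net, scoring_config(hub_min_degree = k),
                      mode = "UP_ONLY")
    expect_true(all(up$gene_id[up$is_hub] %in% hub_set))
    prev <- hub_set
  }
})

test_that("GraphML export round-trips node and edge sets", {
  scored <- scored_edges(list("rno-mir-1", "G1"), list("rno-mir-1", "G2"),
                         list("rno-mir-2", "G1"))
  net <- build_network(scored, expr_tab(c("rno-mir-1", "rno-mir-2"),
                                        c("UP", "DOWN")))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, f)
  g <- igraph::read_graph(f, format = "graphml")
  expect_setequal(igraph::V(g)$name,
                  c(net$mirna_nodes$mirna_id, net$gene_nodes))
  got_edges <- apply(igraph::as_edgelist(g), 1, function(x)
    paste(sort(x), collapse = "|"))
  want_edges <- paste(pmin(net$edges$mirna_id, net$edges$gene_id),
                      pmax(net$edges$mirna_id, net$edges$gene_id), sep = "|")
  expect_setequal(got_edges, want_edges)
  expect_setequal(igraph::V(g)$type, c("mirna", "gene"))
  expect_equal(sort(igraph::E(g)$compound_score), sort(net$edges$compound_score))

  # empty network still writes a valid document
  empty <- suppressWarnings(build_network(scored_edges(list("m", "g", FALSE)),
                                          expr_tab("m", "UP")))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(empty, f2)
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::vcount(g2), 0)
})

test_that("edge-list export is deterministic and re-parseable", {
  scored <- scored_edges(list("rno-mir-2", "G2"), list("rno-mir-1", "G1"))
  net <- build_network(scored, expr_tab(c("rno-mir-1", "rno-mir-2"),
                                        c("UP", "DOWN")))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  export_edge_list(net, f1)
  export_edge_list(net, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- readr::read_tsv(f1, show_col_types = FALSE)
  expect_equal(nrow(back), 2L)
  expect_setequal(paste(back$mirna_id, back$gene_id),
                  paste(net$edges$mirna_id, net$edges$gene_id))
})
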