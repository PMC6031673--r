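test_that("miRNA id normalization canonicalizes case, prefix and whitespace", {
  expect_equal(normalize_mirna_id("miR-195"), "rno-mir-195")
  expect_equal(normalize_mirna_id("rno-mir-322"), "rno-mir-322")
  expect_equal(normalize_mirna_id("RNO-miR-30a-5p"), "rno-mir-30a-5p")
  expect_equal(normalize_mirna_id("miR-7a", species_prefix = "rno"),
               normalize_mirna_id("rno-miR-7a"))
  expect_error(normalize_mirna_id("  "), "empty")
})

test_that("gene symbol normalization uppercases and keeps the original", {
  expect_equal(as.character(normalize_gene_id("Adrb2")), "ADRB2")
  expect_equal(as.character(normalize_gene_id(" ppp3r1 ")), "PPP3R1")
  x <- normalize_gene_id(c("Adrb2", "ADRB2"))
  expect_equal(x[[1]], x[[2]])  # join-consistency across databases
  expect_equal(attr(x, "original"), c("Adrb2", "ADRB2"))
  expect_error(normalize_gene_id(""), "empty")
})

test_that("id normalizers are idempotent on fuzzed inputs", {
  set.seed(42)
  alphabet <- c(letters, LETTERS, 0:9, "-", " ", ".")
  raw <- vapply(seq_len(1000), function(i) {
    paste(sample(alphabet, sample(3:15, 1), replace = TRUE), collapse = "")
  }, character(1))
  raw <- raw[nzchar(gsub("[[:space:]]", "", raw))]
  once <- normalize_mirna_id(raw)
  expect_equal(normalize_mirna_id(once), once)
  g_once <- as.character(normalize_gene_id(raw))
  expect_equal(as.character(normalize_gene_id(g_once)), g_once)
})

test_that("expression table reader validates directions and duplicates", {
  f <- write_lines_tmp(c("mirna_id\tdirection",
                         "rno-miR-322\tup", "miR-195\tDOWN"))
  tab <- read_expression_table(f)
  expect_equal(tab$mirna_id, c("rno-mir-322", "rno-mir-195"))
  expect_equal(tab$direction, c("UP", "DOWN"))

  empty <- write_lines_tmp("mirna_id\tdirection")
  expect_equal(nrow(read_expression_table(empty)), 0L)

  dup <- write_lines_tmp(c("mirna_id\tdirection",
                           "miR-7a\tUP", "rno-miR-7a\tup"))
  expect_error(read_expression_table(dup), "duplicate")

  bad <- write_lines_tmp(c("mirna_id\tdirection", "miR-1\tsideways"))
  expect_error(read_expression_table(bad), "direction token.*row 1")
  expect_error(read_expression_table("no/such/file.tsv"), "not found")
})

test_that("interaction-db reader maps dialect columns and parses scores", {
  dialects <- default_dialects()
  f <- write_lines_tmp(c("mirna\tgene\tscore", "rno-miR-30a\tAdrb2\t92.5"))
  r <- read_interaction_db(f, dialects$mirdb)
  expect_equal(r$mirna_id, "rno-mir-30a")
  expect_equal(r$gene_id, "ADRB2")
  expect_equal(r$db_name, "MIRDB")
  expect_equal(r$db_class, "PREDICTED")
  expect_equal(r$score, 92.5)

  # validated dialect needs no score column
  v <- write_lines_tmp(c("mirna\tgene", "miR-195\tCask"))
  rv <- read_interaction_db(v, dialects$mirtarbase)
  expect_true(is.na(rv$score))
  expect_equal(rv$db_class, "VALIDATED")
})

test_that("blank-field rows are skipped and counted in the parse report", {
  f <- write_lines_tmp(c("mirna\tgene\tscore",
                         "miR-1\tG1\t90", "\tG2\t91", "miR-3\t\t92"))
  r <- read_interaction_db(f, default_dialects()$mirdb)
  pr <- attr(r, "parse_report")
  expect_equal(nrow(r), 1L)
  expect_equal(pr$rows_read, 3L)
  expect_equal(pr$rows_kept, 1L)
  expect_equal(pr$rows_skipped, 2L)
  expect_equal(pr$rows_read, pr$rows_kept + pr$rows_skipped +
                 pr$duplicates_collapsed)
})

test_that("duplicate pairs collapse to the best per-database score", {
  # miRDB keeps the maximum target score
  f <- write_lines_tmp(c("mirna\tgene\tscore",
                         "miR-1\tG1\t85", "miR-1\tG1\t95"))
  r <- read_interaction_db(f, default_dialects()$mirdb)
  expect_equal(nrow(r), 1L)
  expect_equal(r$score, 95)
  expect_equal(attr(r, "parse_report")$duplicates_collapsed, 1L)

  # microRNA.org keeps the most negative mirSVR score
  g <- write_lines_tmp(c("mirna\tgene\tscore",
                         "miR-1\tG1\t-1.5", "miR-1\tG1\t-2.5"))
  r2 <- read_interaction_db(g, default_dialects()$microrna_org_conserved)
  expect_equal(r2$score, -2.5)
})

test_that("foreign-species records are dropped, prefix-less ones adopted", {
  f <- write_lines_tmp(c("mirna\tgene\tscore",
                         "hsa-miR-21\tG1\t90", "miR-22\tG2\t91",
                         "rno-miR-23\tG3\t92"))
  r <- read_interaction_db(f, default_dialects()$mirdb)
  expect_equal(sort(r$mirna_id), c("rno-mir-22", "rno-mir-23"))
  expect_equal(attr(r, "parse_report")$rows_skipped, 1L)
})

test_that("malformed scores abort only above the tolerated fraction", {
  f <- write_lines_tmp(c("mirna\tgene\tscore",
                         "miR-1\tG1\tnot_a_number", "miR-2\tG2\t90"))
  expect_error(read_interaction_db(f, default_dialects()$mirdb), "malformed")
  ok <- c("mirna\tgene\tscore",
          sprintf("miR-%d\tG%d\t%d", 1:200, 1:200, 81:280),
          "miR-x\tGx\tbad")
  r <- read_interaction_db(write_lines_tmp(ok), default_dialects()$mirdb,
                           max_malformed_frac = 0.01)
  expect_equal(nrow(r), 200L)
})

test_that("the two microRNA.org bundles concatenate additively", {
  d <- default_dialects()
  f1 <- write_lines_tmp(c("mirna\tgene\tscore", "miR-1\tG1\t-2.0",
                          "miR-1\tG2\t-1.8"))
  f2 <- write_lines_tmp(c("mirna\tgene\tscore", "miR-2\tG1\t-2.2"))
  all <- read_all_databases(
    list(microrna_org_conserved = f1, microrna_org_nonconserved = f2), d)
  expect_equal(nrow(all), 3L)
  pr <- attr(all, "parse_report")
  expect_equal(sum(pr$rows_kept), 3L)
})

test_that("records round-trip through a dialect file unchanged", {
  set.seed(11)
  r <- random_records(40)
  r <- r[r$db_name == "MIRDB", ]
  r <- r[!duplicated(paste(r$mirna_id, r$gene_id)), ]
  f <- withr::local_tempfile(fileext = ".tsv")
  write_interaction_db(r, f, default_dialects()$mirdb)
  back <- read_interaction_db(f, default_dialects()$mirdb)
  ord <- function(d) d[order(d$mirna_id, d$gene_id), ]
  expect_equal(ord(back)[, names(r)], ord(r), ignore_attr = TRUE)
})

test_that("dialect construction enforces its structural invariants", {
  expect_error(db_dialect("MIRDB", list(mirna = 0, gene = 1)), "score")
  expect_error(db_dialect("MIRDB", list(mirna = 0, gene = 0, score = 2)),
               "distinct")
  d <- db_dialect("MIRTARBASE", list(mirna = 0, gene = 1))
  expect_equal(d$db_class, "VALIDATED")
})

test_that("dialect config files load from YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    mirdb = list(db_name = "MIRDB",
                 column_map = list(mirna = 0, gene = 2, score = 4),
                 header_rows = 2, delimiter = ","),
    mirtarbase = list(db_name = "MIRTARBASE",
                      column_map = list(mirna = 1, gene = 3))
  ), f)
  d <- read_dialect_config(f)
  expect_equal(d$mirdb$column_map$score, 4L)
  expect_equal(d$mirdb$delimiter, ",")
  expect_equal(d$mirtarbase$db_class, "VALIDATED")
})
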