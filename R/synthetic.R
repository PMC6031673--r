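#' Synthetic-data generator configuration
#'
#' Defines the study-shaped simulation: 47 upregulated and 10 downregulated
#' miRNAs, of which 4 up and 2 down are planted to fail the inclusion
#' criteria (their only evidence sits in a single predicted database); 11
#' planted hub mRNAs each receiving at least \code{planted_hub_degree}
#' retained interactions; partially overlapping database support; and a GO
#' annotation with a small number of terms planted to be enriched among
#' network target genes.
#'
#' Score ranges are defined relative to the quality-filter boundaries so
#' boundary behavior is exercised by construction: true miRDB scores are
#' drawn strictly above 80, failing decoy scores from (50, 80] including
#' the exact boundary 80.0; true mirSVR scores strictly below -1.2,
#' failing decoys from [-1.2, 0) including the exact boundary -1.2.
#'
#' @param seed Integer RNG seed.
#' @param n_up,n_down Differentially expressed miRNA counts (47, 10).
#' @param n_genes Annotation background gene count (500).
#' @param n_planted_hubs Hub mRNAs planted (11).
#' @param planted_hub_degree Retained interactions per planted hub (5);
#'   must be at least \code{hub_min_degree}.
#' @param n_excluded_up,n_excluded_down miRNAs planted with only
#'   single-predicted-database evidence (4, 2).
#' @param db_overlap_prob Probability a true interaction is echoed in the
#'   second predicted database (0.7).
#' @param validated_frac Fraction of true interactions given validated
#'   (miRTarBase) membership (0.3); a true interaction left with a single
#'   predicted database and no validation is forced into miRTarBase so the
#'   planted interaction set is retained by construction.
#' @param decoy_rate Per-predicted-database rate of decoy records relative
#'   to the true interaction count (0.3); half the decoys are
#'   single-database records with passing scores, half carry failing
#'   scores.
#' @param non_hub_target_frac Fraction of non-hub genes that become
#'   network targets with degree below the hub threshold (0.5).
#' @param mirdb_true_range,mirdb_fail_range miRDB score ranges
#'   (c(81, 100), c(50, 80)).
#' @param mirsvr_true_range,mirsvr_fail_range mirSVR score ranges
#'   (c(-3, -1.2), c(-1.2, 0)).
#' @param n_terms GO terms in the annotation (40).
#' @param planted_term_count Terms planted as enriched (3).
#' @param planted_term_effect Probability a network target gene carries a
#'   planted term (0.8).
#' @param background_term_rate Probability any gene carries any term at
#'   background (0.1).
#' @param hub_min_degree Hub threshold the plant must respect (4).
#' @param use_printed_hub_names Use real hub gene symbols for the plant
#'   instead of synthetic GENE ids (documentation examples only).
#' @return A \code{generator_config} object.
#' @export
generator_config <- function(seed = 1L, n_up = 47L, n_down = 10L,
                             n_genes = 500L, n_planted_hubs = 11L,
                             planted_hub_degree = 5L,
                             n_excluded_up = 4L, n_excluded_down = 2L,
                             db_overlap_prob = 0.7, validated_frac = 0.3,
                             decoy_rate = 0.3, non_hub_target_frac = 0.5,
                             mirdb_true_range = c(81, 100),
                             mirdb_fail_range = c(50, 80),
                             mirsvr_true_range = c(-3, -1.2),
                             mirsvr_fail_range = c(-1.2, 0),
                             n_terms = 40L, planted_term_count = 3L,
                             planted_term_effect = 0.8,
                             background_term_rate = 0.1,
                             hub_min_degree = 4L,
                             use_printed_hub_names = FALSE) {
  probs <- c(db_overlap_prob, validated_frac, decoy_rate,
             non_hub_target_frac, planted_term_effect, background_term_rate)
  stopifnot(all(probs >= 0 & probs <= 1),
            planted_hub_degree >= hub_min_degree,
            n_planted_hubs >= 0L, n_terms >= planted_term_count)
  structure(as.list(environment()), class = "generator_config")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

printed_hub_names <- function() {
  c("ADRB2", "CASK", "LPPR4", "MOB4", "MYT1L", "PPP3R1", "PTH", "PTPRZ1",
    "SGK1", "STX1A", "WEE1")
}

runif_open <- function(n, lo, hi) {
  # open at both ends; round to 3 decimals but keep off the boundaries
  x <- round(stats::runif(n, lo, hi), 3)
  pmin(pmax(x, lo + 0.001), hi - 0.001)
}

#' Generate a ground-truth synthetic study
#'
#' Deterministic for a fixed seed. Plants, by construction: hub genes with
#' \code{planted_hub_degree} retained interactions each; non-hub target
#' genes with degree strictly below \code{hub_min_degree}; excluded miRNAs
#' whose only records sit in one predicted database; decoy records that
#' either fail the quality filters or lack a second supporting database;
#' and GO terms carried by network target genes at an elevated rate.
#'
#' @param config A [generator_config()].
#' @return A \code{ground_truth} object: list with \code{config},
#'   \code{expressions}, \code{true_interactions} (tibble with planted
#'   database membership), per-database record tibbles
#'   (\code{mirdb_records}, \code{morg_conserved_records},
#'   \code{morg_nonconserved_records}, \code{mirtarbase_records}),
#'   \code{annotation} (gene/term/term_name tibble), and the planted sets
#'   \code{hub_genes}, \code{excluded_up}, \code{excluded_down},
#'   \code{planted_terms}, \code{target_genes}.
#' @export
generate_ground_truth <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cf) {
  n_mirna <- cf$n_up + cf$n_down
  mirnas <- sprintf("rno-mir-sim-%03d", seq_len(n_mirna))
  directions <- c(rep("UP", cf$n_up), rep("DOWN", cf$n_down))
  expressions <- tibble::tibble(mirna_id = mirnas, direction = directions)

  up_ids <- mirnas[directions == "UP"]
  down_ids <- mirnas[directions == "DOWN"]
  stopifnot(cf$n_excluded_up <= cf$n_up, cf$n_excluded_down <= cf$n_down)
  excluded_up <- sort(sample(up_ids, cf$n_excluded_up))
  excluded_down <- sort(sample(down_ids, cf$n_excluded_down))
  excluded <- c(excluded_up, excluded_down)
  eligible <- setdiff(mirnas, excluded)
  if (cf$planted_hub_degree > length(eligible)) {
    stop("infeasible config: planted_hub_degree exceeds eligible miRNA count")
  }

  genes <- sprintf("GENE%04d", seq_len(cf$n_genes))
  if (cf$use_printed_hub_names) {
    hub_genes <- printed_hub_names()[seq_len(cf$n_planted_hubs)]
    genes <- c(hub_genes, genes[seq_len(cf$n_genes - length(hub_genes))])
  } else {
    hub_genes <- if (cf$n_planted_hubs > 0L)
      sort(sample(genes, cf$n_planted_hubs)) else character()
  }

  # planted interactions: hubs at planted_hub_degree, other targets below
  # the hub threshold so no non-planted gene can qualify
  pairs <- list()
  for (h in hub_genes) {
    pairs[[h]] <- sample(eligible, cf$planted_hub_degree)
  }
  non_hub <- setdiff(genes, hub_genes)
  n_targets <- round(cf$non_hub_target_frac * length(non_hub))
  other_targets <- if (n_targets > 0L) sort(sample(non_hub, n_targets)) else character()
  max_other <- max(1L, cf$hub_min_degree - 1L)
  for (g in other_targets) {
    d <- sample.int(max_other, 1L)
    pairs[[g]] <- sample(eligible, d)
  }
  true_int <- tibble::tibble(
    gene_id = rep(names(pairs), lengths(pairs)),
    mirna_id = unlist(pairs, use.names = FALSE)
  )

  # every eligible miRNA must retain at least one interaction; top up
  # uncovered miRNAs on genes still safely below the hub threshold
  uncovered <- setdiff(eligible, unique(true_int$mirna_id))
  if (length(uncovered) > 0L) {
    deg <- table(true_int$gene_id)
    room <- other_targets[deg[other_targets] < max_other]
    spare <- setdiff(non_hub, names(pairs))
    hosts <- c(room, spare)
    stopifnot(length(hosts) >= length(uncovered))
    true_int <- dplyr::bind_rows(true_int, tibble::tibble(
      gene_id = hosts[seq_along(uncovered)], mirna_id = uncovered
    ))
  }
  target_genes <- sort(unique(true_int$gene_id))

  # database membership for each true interaction
  n_true <- nrow(true_int)
  primary <- sample(c("MIRDB", "MICRORNA_ORG"), n_true, replace = TRUE)
  echoed <- stats::runif(n_true) < cf$db_overlap_prob
  validated <- stats::runif(n_true) < cf$validated_frac
  validated[!echoed & !validated] <- TRUE  # guarantee retention
  true_int$in_mirdb <- primary == "MIRDB" | (primary == "MICRORNA_ORG" & echoed)
  true_int$in_morg <- primary == "MICRORNA_ORG" | (primary == "MIRDB" & echoed)
  true_int$in_mirtarbase <- validated
  true_int$mirdb_score <- ifelse(
    true_int$in_mirdb,
    runif_open(n_true, cf$mirdb_true_range[1], cf$mirdb_true_range[2]),
    NA_real_)
  true_int$mirsvr_score <- ifelse(
    true_int$in_morg,
    runif_open(n_true, cf$mirsvr_true_range[1], cf$mirsvr_true_range[2]),
    NA_real_)

  # records planted for excluded miRNAs: 1-3 passing records each,
  # confined to one predicted database and absent everywhere else
  excl_rec <- list()
  for (mi in excluded) {
    db <- sample(c("MIRDB", "MICRORNA_ORG"), 1L)
    k <- sample.int(3L, 1L)
    gs <- sample(genes, k)
    sc <- if (db == "MIRDB") {
      runif_open(k, cf$mirdb_true_range[1], cf$mirdb_true_range[2])
    } else {
      runif_open(k, cf$mirsvr_true_range[1], cf$mirsvr_true_range[2])
    }
    excl_rec[[mi]] <- tibble::tibble(mirna_id = mi, gene_id = gs,
                                     db_name = db, score = sc)
  }
  excl_rec <- dplyr::bind_rows(excl_rec)

  # decoy records: unique non-true pairs over eligible miRNAs; half pass
  # the quality filter but sit in one database, half carry failing scores
  n_decoy <- round(cf$decoy_rate * n_true)
  decoys <- make_decoys(cf, n_decoy, eligible, genes, true_int)

  # assemble per-database tables
  mirdb_records <- dplyr::bind_rows(
    true_int[true_int$in_mirdb, c("mirna_id", "gene_id")] |>
      dplyr::mutate(score = true_int$mirdb_score[true_int$in_mirdb]),
    excl_rec[excl_rec$db_name == "MIRDB", c("mirna_id", "gene_id", "score")],
    decoys$mirdb
  )
  morg_records <- dplyr::bind_rows(
    true_int[true_int$in_morg, c("mirna_id", "gene_id")] |>
      dplyr::mutate(score = true_int$mirsvr_score[true_int$in_morg]),
    excl_rec[excl_rec$db_name == "MICRORNA_ORG",
             c("mirna_id", "gene_id", "score")],
    decoys$morg
  )
  conserved <- stats::runif(nrow(morg_records)) < 0.5
  mirtarbase_records <- true_int[true_int$in_mirtarbase,
                                 c("mirna_id", "gene_id")]
  mirtarbase_records$support_type <- sample(
    c("Functional MTI", "Functional MTI (Weak)"),
    nrow(mirtarbase_records), replace = TRUE, prob = c(0.4, 0.6))

  annotation <- make_annotation(cf, genes, target_genes)

  structure(
    list(
      config = cf,
      expressions = expressions,
      true_interactions = true_int,
      mirdb_records = sort_records(mirdb_records),
      morg_conserved_records = sort_records(morg_records[conserved, ]),
      morg_nonconserved_records = sort_records(morg_records[!conserved, ]),
      mirtarbase_records = sort_records(mirtarbase_records),
      annotation = annotation$table,
      hub_genes = hub_genes,
      excluded_up = excluded_up,
      excluded_down = excluded_down,
      planted_terms = annotation$planted_terms,
      target_genes = target_genes
    ),
    class = "ground_truth"
  )
}

sort_records <- function(df) {
  df[order(df$mirna_id, df$gene_id), , drop = FALSE]
}

make_decoys <- function(cf, n_decoy, eligible, genes, true_int) {
  out <- list(mirdb = NULL, morg = NULL)
  if (n_decoy == 0L) {
    empty <- tibble::tibble(mirna_id = character(), gene_id = character(),
                            score = numeric())
    return(list(mirdb = empty, morg = empty))
  }
  true_key <- paste(true_int$mirna_id, true_int$gene_id)
  used <- true_key
  draw_pairs <- function(n) {
    got <- character(0)
    pairs <- NULL
    while (length(got) < n) {
      cand <- tibble::tibble(
        mirna_id = sample(eligible, 2L * n, replace = TRUE),
        gene_id = sample(genes, 2L * n, replace = TRUE)
      )
      key <- paste(cand$mirna_id, cand$gene_id)
      ok <- !(key %in% used) & !duplicated(key)
      cand <- cand[ok, ]
      take <- utils::head(cand, n - length(got))
      used <<- c(used, paste(take$mirna_id, take$gene_id))
      got <- c(got, paste(take$mirna_id, take$gene_id))
      pairs <- dplyr::bind_rows(pairs, take)
    }
    pairs
  }
  for (db in c("mirdb", "morg")) {
    p <- draw_pairs(n_decoy)
    n_pass <- ceiling(n_decoy / 2)
    rng_true <- if (db == "mirdb") cf$mirdb_true_range else cf$mirsvr_true_range
    rng_fail <- if (db == "mirdb") cf$mirdb_fail_range else cf$mirsvr_fail_range
    pass_scores <- runif_open(n_pass, rng_true[1], rng_true[2])
    n_fail <- n_decoy - n_pass
    if (db == "mirdb") {
      fail_scores <- round(stats::runif(n_fail, rng_fail[1], rng_fail[2]), 3)
      if (n_fail > 0L) fail_scores[1L] <- rng_fail[2]  # exact boundary 80.0
    } else {
      fail_scores <- round(stats::runif(n_fail, rng_fail[1], rng_fail[2]), 3)
      fail_scores <- pmax(fail_scores, rng_fail[1])
      if (n_fail > 0L) fail_scores[1L] <- rng_fail[1]  # exact boundary -1.2
    }
    p$score <- c(pass_scores, fail_scores)
    out[[db]] <- p
  }
  out
}

make_annotation <- function(cf, genes, target_genes) {
  terms <- sprintf("TERM%03d", seq_len(cf$n_terms))
  planted <- terms[seq_len(cf$planted_term_count)]
  assoc <- list()
  for (t in terms) {
    if (t %in% planted) {
      hit_t <- target_genes[stats::runif(length(target_genes)) <
                              cf$planted_term_effect]
      rest <- setdiff(genes, target_genes)
      hit_b <- rest[stats::runif(length(rest)) < cf$background_term_rate]
      carriers <- c(hit_t, hit_b)
    } else {
      carriers <- genes[stats::runif(length(genes)) < cf$background_term_rate]
    }
    if (length(carriers) == 0L) carriers <- sample(genes, 1L)
    assoc[[t]] <- tibble::tibble(
      gene_id = sort(carriers), term_id = t,
      term_name = paste("synthetic process", sub("TERM", "", t))
    )
  }
  list(table = dplyr::bind_rows(assoc), planted_terms = planted)
}

#' Write the synthetic study to pipeline input files
#'
#' Emits the six input files in the default database dialects, a
#' ground-truth JSON for test harnesses, and a manifest TSV of row counts.
#'
#' @param truth A \code{ground_truth} from [generate_ground_truth()].
#' @param out_dir Output directory (created if missing).
#' @return Tibble manifest (file, rows) with full paths in the
#'   \code{"paths"} attribute.
#' @export
emit_files <- function(truth, out_dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dialects <- default_dialects()
  p <- function(f) file.path(out_dir, f)

  write_db <- function(df, file, dialect_name) {
    rec <- tibble::tibble(mirna_id = df$mirna_id, gene_id = df$gene_id,
                          score = if ("score" %in% names(df)) df$score else NA_real_)
    if (dialect_name == "mirtarbase") {
      # validated dialect: no score column, support type rides along
      lines <- c("mirna\tgene\tsupport_type",
                 paste(df$mirna_id, df$gene_id, df$support_type, sep = "\t"))
      con <- file(p(file), "wb"); on.exit(close(con))
      writeLines(lines, con)
    } else {
      write_interaction_db(rec, p(file), dialects[[dialect_name]])
    }
    nrow(df)
  }
  rows <- c(
    mirdb.tsv = write_db(truth$mirdb_records, "mirdb.tsv", "mirdb"),
    microrna_org_conserved.tsv = write_db(
      truth$morg_conserved_records, "microrna_org_conserved.tsv",
      "microrna_org_conserved"),
    microrna_org_nonconserved.tsv = write_db(
      truth$morg_nonconserved_records, "microrna_org_nonconserved.tsv",
      "microrna_org_nonconserved"),
    mirtarbase.tsv = write_db(truth$mirtarbase_records, "mirtarbase.tsv",
                              "mirtarbase")
  )
  readr::write_tsv(truth$expressions, p("expression.tsv"))
  readr::write_tsv(truth$annotation, p("annotation.tsv"))
  rows <- c(rows,
            expression.tsv = nrow(truth$expressions),
            annotation.tsv = nrow(truth$annotation))

  jsonlite::write_json(
    list(
      seed = truth$config$seed,
      hub_genes = truth$hub_genes,
      excluded_up = truth$excluded_up,
      excluded_down = truth$excluded_down,
      planted_terms = truth$planted_terms,
      target_genes = truth$target_genes,
      true_pairs = paste(truth$true_interactions$mirna_id,
                         truth$true_interactions$gene_id, sep = "|")
    ),
    p("truth.json"), auto_unbox = TRUE, pretty = TRUE
  )
  manifest <- tibble::tibble(file = names(rows), rows = as.integer(rows))
  readr::write_tsv(manifest, p("manifest.tsv"))
  attr(manifest, "paths") <- stats::setNames(
    vapply(manifest$file, p, character(1)), manifest$file)
  manifest
}
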