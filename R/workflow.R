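#' Run the full target-prediction pipeline
#'
#' Orchestrates ingest, quality filtering, evidence collation, compound
#' scoring, retention, network construction, Venn partition, hub selection
#' and GO over-representation, writing every table under \code{out_dir}
#' and returning a run report. The pipeline is deterministic: reruns on
#' identical inputs produce identical data outputs.
#'
#' The configuration may be a YAML/JSON file path or an equivalent list
#' with elements:
#' \describe{
#'   \item{inputs}{named paths: \code{mirdb},
#'     \code{microrna_org_conserved}, \code{microrna_org_nonconserved},
#'     \code{mirtarbase}, \code{expression}, \code{annotation} (annotation
#'     optional).}
#'   \item{dialects}{optional path to a dialect config
#'     ([read_dialect_config()]); defaults to [default_dialects()].}
#'   \item{scoring}{optional named list of [scoring_config()] overrides.}
#'   \item{hub_mode}{\code{"TOTAL"} (default) or \code{"UP_ONLY"}.}
#'   \item{enrich_method}{\code{"HYPERGEOMETRIC"} (default) or
#'     \code{"BINOMIAL"}.}
#'   \item{alpha}{significance level for enrichment (default 0.05).}
#' }
#'
#' Enrichment runs over four study sets reflecting the Venn partition and
#' the hub selection: targets of upregulated miRNAs, targets of
#' downregulated miRNAs, common targets of both, and hub genes.
#'
#' @param config Path to a YAML/JSON config or an equivalent list.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages (default FALSE).
#' @return The pipeline report (list), invisibly written to
#'   \code{report.json}.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$inputs))
  inputs <- config$inputs
  need <- c("mirdb", "microrna_org_conserved", "microrna_org_nonconserved",
            "mirtarbase", "expression")
  missing <- setdiff(need, names(inputs))
  if (length(missing) > 0L) {
    stop("config$inputs missing: ", paste(missing, collapse = ", "))
  }
  dialects <- if (!is.null(config$dialects)) {
    read_dialect_config(config$dialects)
  } else default_dialects()
  sc <- do.call(scoring_config, as.list(config$scoring))
  hub_mode <- if (is.null(config$hub_mode)) "TOTAL" else toupper(config$hub_mode)
  enrich_method <- if (is.null(config$enrich_method)) "HYPERGEOMETRIC" else
    toupper(config$enrich_method)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  expressions <- read_expression_table(inputs$expression)
  db_paths <- inputs[intersect(need[1:4], names(inputs))]
  records <- read_all_databases(db_paths, dialects)
  parse_report <- attr(records, "parse_report")
  readr::write_tsv(parse_report, file.path(out_dir, "parse_report.tsv"))
  say(sprintf("read %d interaction records from %d files",
              nrow(records), length(db_paths)))

  filtered <- apply_quality_filter(records, sc)
  evidence <- collate_evidence(filtered)
  scored <- retain_interactions(evidence, sc)
  write_scored_interactions(scored, file.path(out_dir, "scored_interactions.tsv"))
  say(sprintf("%d records pass quality filters; %d distinct pairs; %d retained",
              nrow(filtered), nrow(scored), sum(scored$retained)))

  network <- suppressWarnings(build_network(scored, expressions))
  export_edge_list(network, file.path(out_dir, "edge_list.tsv"))
  export_graphml(network, file.path(out_dir, "network.graphml"))
  excl <- excluded_mirnas(expressions, network)
  readr::write_tsv(
    tibble::tibble(
      mirna_id = c(excl$up, excl$down),
      direction = c(rep("UP", length(excl$up)), rep("DOWN", length(excl$down)))
    ),
    file.path(out_dir, "excluded_mirnas.tsv")
  )
  venn <- venn_partition(network)
  readr::write_tsv(
    tibble::tibble(
      class = c("up_only", "down_only", "both", "union_total", "naive_sum"),
      count = c(venn$up_only, venn$down_only, venn$both,
                venn$union_total, venn$naive_sum)
    ),
    file.path(out_dir, "venn_counts.tsv")
  )
  hubs <- select_hubs(network, sc, mode = hub_mode)
  readr::write_tsv(hubs, file.path(out_dir, "hub_table.tsv"))
  say(sprintf("network: %d miRNAs, %d genes, %d edges; %d hubs (mode %s)",
              nrow(network$mirna_nodes), length(network$gene_nodes),
              nrow(network$edges), sum(hubs$is_hub), hub_mode))

  n_enriched <- NA_integer_
  if (!is.null(inputs$annotation)) {
    annotation <- read_annotation(inputs$annotation)
    study_sets <- list(
      up_targets = unique(c(venn$genes_up_only, venn$genes_both)),
      down_targets = unique(c(venn$genes_down_only, venn$genes_both)),
      common_targets = venn$genes_both,
      hubs = hubs$gene_id[hubs$is_hub]
    )
    n_enriched <- 0L
    for (nm in names(study_sets)) {
      ss <- intersect(study_sets[[nm]], annotation$background)
      if (length(ss) == 0L) {
        say("study set ", nm, " has no annotated genes; skipped")
        next
      }
      res <- enrich(ss, annotation, alpha = alpha, method = enrich_method)
      write_enrichment(res, file.path(out_dir,
                                      paste0("enrichment_", nm, ".tsv")))
      n_enriched <- n_enriched + sum(res$enriched)
    }
  }

  report <- list(
    tool = "mirhub",
    version = as.character(utils::packageVersion("mirhub")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = list(scoring = unclass(sc), hub_mode = hub_mode,
                  enrich_method = enrich_method, alpha = alpha),
    input_checksums = vapply(unlist(inputs), function(f) {
      unname(tools::md5sum(f))
    }, character(1)),
    counts = list(
      records_read = nrow(records),
      records_after_quality_filter = nrow(filtered),
      distinct_pairs = nrow(scored),
      retained_pairs = sum(scored$retained),
      network_mirnas = nrow(network$mirna_nodes),
      network_genes = length(network$gene_nodes),
      network_edges = nrow(network$edges),
      excluded_up = length(excl$up),
      excluded_down = length(excl$down),
      venn = venn[c("up_only", "down_only", "both", "union_total",
                    "naive_sum")],
      hub_count = sum(hubs$is_hub),
      enriched_terms_total = n_enriched
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
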