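#' Build the bipartite miRNA-target network
#'
#' Nodes are differentially expressed miRNAs (annotated with their
#' regulation direction) and their retained target mRNAs; edges are
#' retained miRNA-target interactions, annotated with the compound score
#' and contributing databases. Edges whose miRNA is absent from the
#' expression table are dropped with a count (such a miRNA is not
#' differentially expressed); miRNAs with no surviving edge are excluded
#' from the network and can be listed with [excluded_mirnas()].
#'
#' @param scored Scored-interaction tibble from [retain_interactions()];
#'   only rows with \code{retained == TRUE} enter the network.
#' @param expressions Expression tibble from [read_expression_table()].
#' @return A \code{bipartite_network} object: list with \code{mirna_nodes}
#'   (tibble: mirna_id, direction), \code{gene_nodes} (character),
#'   \code{edges} (tibble: mirna_id, gene_id, compound_score, dbs_present),
#'   and \code{n_dropped_foreign_mirna}.
#' @export
build_network <- function(scored, expressions) {
  stopifnot(all(c("mirna_id", "direction") %in% names(expressions)))
  edges <- scored[scored$retained, , drop = FALSE]
  in_expr <- edges$mirna_id %in% expressions$mirna_id
  n_dropped <- sum(!in_expr)
  edges <- edges[in_expr, , drop = FALSE]
  edges <- dplyr::arrange(edges, .data$mirna_id, .data$gene_id)
  if (nrow(edges) == 0L) {
    warning("network has no edges (empty retained set after expression join)")
  }
  mirna_nodes <- expressions[expressions$mirna_id %in% edges$mirna_id,
                             c("mirna_id", "direction")]
  mirna_nodes <- dplyr::arrange(mirna_nodes, .data$mirna_id)
  structure(
    list(
      mirna_nodes = mirna_nodes,
      gene_nodes = sort(unique(edges$gene_id)),
      edges = tibble::tibble(
        mirna_id = edges$mirna_id,
        gene_id = edges$gene_id,
        compound_score = edges$compound_score,
        dbs_present = vapply(edges$dbs_present, paste, character(1),
                             collapse = ";")
      ),
      n_dropped_foreign_mirna = n_dropped
    ),
    class = "bipartite_network"
  )
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "bipartite miRNA-target network: %d miRNAs (%d up, %d down), %d genes, %d edges\n",
    nrow(x$mirna_nodes), sum(x$mirna_nodes$direction == "UP"),
    sum(x$mirna_nodes$direction == "DOWN"),
    length(x$gene_nodes), nrow(x$edges)
  ))
  invisible(x)
}

#' Differentially expressed miRNAs excluded from the network
#'
#' miRNAs from the expression table that retained no interaction (no
#' support from at least two predicted databases or one validated
#' database), partitioned by regulation direction.
#'
#' @param expressions Expression tibble.
#' @param network A \code{bipartite_network} built from \code{expressions}.
#' @return List with character vectors \code{up} and \code{down}.
#' @export
excluded_mirnas <- function(expressions, network) {
  stopifnot(inherits(network, "bipartite_network"))
  absent <- expressions[!expressions$mirna_id %in% network$mirna_nodes$mirna_id, ]
  list(
    up = sort(absent$mirna_id[absent$direction == "UP"]),
    down = sort(absent$mirna_id[absent$direction == "DOWN"])
  )
}

#' Venn partition of target genes by regulator direction
#'
#' Assigns each target mRNA to exactly one class: targeted only by
#' upregulated miRNAs, only by downregulated miRNAs, or by at least one of
#' each. \code{union_total} is the distinct gene count;
#' \code{naive_sum} double-counts the shared class (the per-direction
#' totals added as printed in per-direction target counts).
#'
#' @param network A \code{bipartite_network}.
#' @return List with counts \code{up_only}, \code{down_only}, \code{both},
#'   \code{union_total}, \code{naive_sum}, and character-vector members
#'   \code{genes_up_only}, \code{genes_down_only}, \code{genes_both}.
#' @export
venn_partition <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  dir_of <- stats::setNames(network$mirna_nodes$direction,
                            network$mirna_nodes$mirna_id)
  edge_dir <- dir_of[network$edges$mirna_id]
  genes <- network$gene_nodes
  by_up <- unique(network$edges$gene_id[edge_dir == "UP"])
  by_down <- unique(network$edges$gene_id[edge_dir == "DOWN"])
  both <- intersect(by_up, by_down)
  up_only <- setdiff(by_up, by_down)
  down_only <- setdiff(by_down, by_up)
  list(
    up_only = length(up_only), down_only = length(down_only),
    both = length(both), union_total = length(genes),
    naive_sum = length(by_up) + length(by_down),
    genes_up_only = sort(up_only), genes_down_only = sort(down_only),
    genes_both = sort(both)
  )
}

#' Select hub mRNAs by interaction degree
#'
#' A hub is an mRNA with at least \code{hub_min_degree} interacting
#' differentially expressed miRNAs. Two degree definitions are supported:
#' \code{"TOTAL"} counts all interacting miRNAs; \code{"UP_ONLY"} counts
#' only upregulated miRNAs. Both appear in the field's usage (hubs are
#' variously described by total interactions or by interacting upregulated
#' miRNAs); the default is \code{"TOTAL"}.
#'
#' @param network A \code{bipartite_network}.
#' @param config A [scoring_config()]; supplies \code{hub_min_degree}.
#' @param mode \code{"TOTAL"} or \code{"UP_ONLY"}.
#' @return Tibble with one row per gene: \code{gene_id},
#'   \code{degree_total}, \code{degree_up}, \code{degree_down},
#'   \code{is_hub}; sorted by the mode's degree descending, ties broken by
#'   gene id ascending.
#' @export
select_hubs <- function(network, config = scoring_config(),
                        mode = c("TOTAL", "UP_ONLY")) {
  stopifnot(inherits(network, "bipartite_network"),
            inherits(config, "scoring_config"))
  mode <- match.arg(mode)
  dir_of <- stats::setNames(network$mirna_nodes$direction,
                            network$mirna_nodes$mirna_id)
  edge_dir <- dir_of[network$edges$mirna_id]
  tab <- tibble::tibble(gene_id = network$gene_nodes)
  cnt <- function(sel) {
    t <- table(factor(network$edges$gene_id[sel], levels = tab$gene_id))
    as.integer(t)
  }
  tab$degree_up <- cnt(edge_dir == "UP")
  tab$degree_down <- cnt(edge_dir == "DOWN")
  tab$degree_total <- tab$degree_up + tab$degree_down
  deg <- if (mode == "TOTAL") tab$degree_total else tab$degree_up
  tab$is_hub <- deg >= config$hub_min_degree
  tab <- tab[order(-deg, tab$gene_id), ]
  tab[, c("gene_id", "degree_total", "degree_up", "degree_down", "is_hub")]
}

net_to_igraph <- function(network) {
  g <- igraph::make_empty_graph(directed = FALSE)
  if (nrow(network$mirna_nodes) > 0L) {
    g <- igraph::add_vertices(
      g, nrow(network$mirna_nodes),
      name = network$mirna_nodes$mirna_id, type = "mirna",
      direction = network$mirna_nodes$direction
    )
  }
  if (length(network$gene_nodes) > 0L) {
    g <- igraph::add_vertices(
      g, length(network$gene_nodes),
      name = network$gene_nodes, type = "gene", direction = ""
    )
  }
  if (nrow(network$edges) > 0L) {
    g <- igraph::add_edges(
      g, rbind(network$edges$mirna_id, network$edges$gene_id),
      compound_score = network$edges$compound_score,
      dbs_present = network$edges$dbs_present
    )
  }
  g
}

#' Export the network as GraphML
#'
#' Nodes carry \code{type} (\code{mirna}/\code{gene}) and, for miRNAs,
#' \code{direction}; edges carry \code{compound_score} and
#' \code{dbs_present}. The file re-imports (e.g. with
#' \code{igraph::read_graph}) to the same node and edge sets, and is ready
#' for external layout tools.
#'
#' @param network A \code{bipartite_network}.
#' @param path Output path.
#' @export
export_graphml <- function(network, path) {
  stopifnot(inherits(network, "bipartite_network"))
  igraph::write_graph(net_to_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Export the network edge list as TSV
#'
#' Columns: miRNA, its direction, gene, compound score, contributing
#' databases. Rows are sorted so identical networks export byte-identical
#' files.
#'
#' @param network A \code{bipartite_network}.
#' @param path Output path.
#' @export
export_edge_list <- function(network, path) {
  stopifnot(inherits(network, "bipartite_network"))
  dir_of <- stats::setNames(network$mirna_nodes$direction,
                            network$mirna_nodes$mirna_id)
  out <- tibble::tibble(
    mirna_id = network$edges$mirna_id,
    direction = unname(dir_of[network$edges$mirna_id]),
    gene_id = network$edges$gene_id,
    compound_score = network$edges$compound_score,
    dbs_present = network$edges$dbs_present
  )
  out <- dplyr::arrange(out, .data$mirna_id, .data$gene_id)
  readr::write_tsv(out, path)
  invisible(path)
}
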