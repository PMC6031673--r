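#' Scoring configuration
#'
#' Houses every numeric constant of the evidence-integration procedure:
#' per-database quality cutoffs, the compound-score point scheme, the
#' retention threshold, and the hub degree threshold.
#'
#' Quality cutoffs are exclusive in the direction of removal: miRDB records
#' with target score \eqn{\le} \code{mirdb_min_exclusive} are removed
#' (higher target scores mean more confident predictions), and microRNA.org
#' records with mirSVR score \eqn{\ge} \code{mirsvr_max_exclusive} are
#' removed (more negative mirSVR scores mean stronger predicted repression).
#' The compound score awards \code{points_per_predicted_db} per supporting
#' predicted database and \code{points_validated} for validated support;
#' a pair is retained when its score reaches \code{retention_min_score},
#' which by design a single predicted database cannot.
#'
#' @param mirdb_min_exclusive Remove miRDB records scoring at or below this
#'   (default 80.0).
#' @param mirsvr_max_exclusive Remove microRNA.org records scoring at or
#'   above this (default -1.2).
#' @param points_per_predicted_db Points per supporting predicted database
#'   (default 0.5).
#' @param points_validated Points for validated support (default 1).
#' @param retention_min_score Minimum compound score to retain a pair
#'   (default 1).
#' @param hub_min_degree Minimum interaction degree for a hub mRNA
#'   (default 4).
#' @return A \code{scoring_config} object (named list).
#' @export
scoring_config <- function(mirdb_min_exclusive = 80.0,
                           mirsvr_max_exclusive = -1.2,
                           points_per_predicted_db = 0.5,
                           points_validated = 1.0,
                           retention_min_score = 1.0,
                           hub_min_degree = 4L) {
  stopifnot(
    points_per_predicted_db > 0, points_validated > 0,
    retention_min_score > points_per_predicted_db,
    hub_min_degree >= 1L
  )
  structure(
    list(
      mirdb_min_exclusive = mirdb_min_exclusive,
      mirsvr_max_exclusive = mirsvr_max_exclusive,
      points_per_predicted_db = points_per_predicted_db,
      points_validated = points_validated,
      retention_min_score = retention_min_score,
      hub_min_degree = as.integer(hub_min_degree)
    ),
    class = "scoring_config"
  )
}

#' Apply per-database quality filters
#'
#' Keeps miRDB records scoring strictly above \code{mirdb_min_exclusive}
#' and microRNA.org records scoring strictly below
#' \code{mirsvr_max_exclusive}; boundary values are removed. Validated
#' records pass unchanged (the validated source carries no comparable
#' score). Order-preserving and idempotent.
#'
#' @param records Interaction-record tibble from [read_interaction_db()].
#' @param config A [scoring_config()].
#' @return Filtered record tibble.
#' @export
apply_quality_filter <- function(records, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  if (nrow(records) == 0L) return(records)
  keep <- rep(TRUE, nrow(records))
  is_mirdb <- records$db_name == "MIRDB"
  is_morg <- records$db_name == "MICRORNA_ORG"
  keep[is_mirdb] <- records$score[is_mirdb] > config$mirdb_min_exclusive
  keep[is_morg] <- records$score[is_morg] < config$mirsvr_max_exclusive
  records[keep, , drop = FALSE]
}

#' Collate evidence per (miRNA, gene) pair
#'
#' Groups quality-filtered records into one evidence set per distinct pair:
#' the set of contributing databases and, for predicted databases, the best
#' surviving score. Output is sorted by miRNA then gene for determinism.
#'
#' @param records Quality-filtered, id-normalized record tibble.
#' @return Tibble with columns \code{mirna_id}, \code{gene_id},
#'   \code{dbs_present} (list of character), \code{mirdb_score},
#'   \code{mirsvr_score} (NA when the database is absent).
#' @export
collate_evidence <- function(records) {
  if (nrow(records) == 0L) {
    return(tibble::tibble(
      mirna_id = character(), gene_id = character(),
      dbs_present = list(), mirdb_score = numeric(), mirsvr_score = numeric()
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(records, .data$mirna_id, .data$gene_id),
    dbs_present = list(sort(unique(.data$db_name))),
    mirdb_score = if (any(.data$db_name == "MIRDB"))
      max(.data$score[.data$db_name == "MIRDB"]) else NA_real_,
    mirsvr_score = if (any(.data$db_name == "MICRORNA_ORG"))
      min(.data$score[.data$db_name == "MICRORNA_ORG"]) else NA_real_,
    .groups = "drop"
  )
  dplyr::arrange(out, .data$mirna_id, .data$gene_id)
}

#' Compound interaction score
#'
#' The evidence score of a (miRNA, gene) pair:
#' \code{points_per_predicted_db} for each predicted database present
#' (each counted once, however many binding-site rows it contributed) plus
#' \code{points_validated} if the validated database is present. Under the
#' defaults this is 0.5 per predicted database and 1 for validated support,
#' bounded by 2.
#'
#' @param evidence Evidence tibble from [collate_evidence()] (or any tibble
#'   with a \code{dbs_present} list-column).
#' @param config A [scoring_config()].
#' @return Numeric vector of compound scores, one per evidence set.
#' @export
compound_score <- function(evidence, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  if (any(lengths(evidence$dbs_present) == 0L)) {
    stop("evidence set with no contributing database")
  }
  n_pred <- vapply(evidence$dbs_present, function(d) {
    sum(d %in% c("MIRDB", "MICRORNA_ORG"))
  }, integer(1))
  has_val <- vapply(evidence$dbs_present, function(d) {
    "MIRTARBASE" %in% d
  }, logical(1))
  config$points_per_predicted_db * n_pred +
    config$points_validated * as.numeric(has_val)
}

#' Score evidence sets and flag retained interactions
#'
#' Attaches the compound score to every pair and flags those reaching the
#' retention threshold. With the default point scheme this implements the
#' exclusion of pairs supported by a single predicted database and nothing
#' else: such pairs score 0.5 < 1.
#'
#' @param evidence Evidence tibble from [collate_evidence()].
#' @param config A [scoring_config()].
#' @return The evidence tibble with added columns \code{compound_score}
#'   and \code{retained}.
#' @export
retain_interactions <- function(evidence, config = scoring_config()) {
  evidence$compound_score <- if (nrow(evidence) > 0L) {
    compound_score(evidence, config)
  } else numeric()
  # sums of halves are exactly representable: exact >= is safe
  evidence$retained <- evidence$compound_score >= config$retention_min_score
  evidence
}

#' Write the scored-interactions table
#'
#' @param scored Tibble from [retain_interactions()].
#' @param path Output TSV path.
#' @export
write_scored_interactions <- function(scored, path) {
  out <- tibble::tibble(
    mirna_id = scored$mirna_id,
    gene_id = scored$gene_id,
    dbs_present = vapply(scored$dbs_present, paste, character(1),
                         collapse = ";"),
    compound_score = scored$compound_score,
    retained = scored$retained
  )
  readr::write_tsv(out, path)
  invisible(path)
}
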