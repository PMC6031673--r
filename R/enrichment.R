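#' Read a flat gene-to-GO-term annotation table
#'
#' Expects a TSV with columns \code{gene_id}, \code{term_id} and an
#' optional \code{term_name}, one association per row. Associations are
#' taken as given (no ontology-graph propagation); supply pre-propagated
#' annotations if term ancestry should count. Gene ids are canonicalized
#' with [normalize_gene_id()]; duplicate associations collapse to one.
#'
#' @param path Path to the annotation TSV.
#' @return An \code{annotation_map}: list with \code{gene2terms} (named
#'   list gene -> character vector of terms), \code{term2genes} (inverse),
#'   \code{background} (character vector of annotated genes),
#'   \code{term_names} (named character, possibly empty),
#'   \code{n_skipped} rows with missing fields.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) stop("annotation file has no associations: ", path)
  gene <- trimws(df[[1L]])
  term <- trimws(df[[2L]])
  ok <- nzchar(gene) & nzchar(term)
  n_skipped <- sum(!ok)
  gene <- as.character(normalize_gene_id(gene[ok]))
  term <- term[ok]
  term_names <- character()
  if (ncol(df) >= 3L) {
    nm <- trimws(df[[3L]])[ok]
    has <- nzchar(nm) & !duplicated(term)
    term_names <- stats::setNames(nm[has], term[has])
  }
  annotation_map(gene, term, term_names, n_skipped)
}

#' Build an annotation map from association vectors
#'
#' @param gene,term Parallel character vectors, one association per
#'   element.
#' @param term_names Optional named character vector of term labels.
#' @param n_skipped Bookkeeping count of malformed source rows.
#' @return An \code{annotation_map} (see [read_annotation()]).
#' @export
annotation_map <- function(gene, term, term_names = character(),
                           n_skipped = 0L) {
  stopifnot(length(gene) == length(term))
  dup <- duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[!dup]
  term <- term[!dup]
  structure(
    list(
      gene2terms = split(term, gene),
      term2genes = split(gene, term),
      background = sort(unique(gene)),
      term_names = term_names,
      n_skipped = as.integer(n_skipped)
    ),
    class = "annotation_map"
  )
}

#' Gene-ontology over-representation analysis
#'
#' Tests each annotated term for over-representation in a study gene set
#' against the annotation background, with Bonferroni correction over the
#' number of terms tested. The default statistic is the one-sided
#' hypergeometric (Fisher) upper tail
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, n)};
#' a binomial approximation \eqn{P(X \ge k)}, \eqn{X \sim B(n, K/N)},
#' is available as historical annotation-portal releases used it.
#' Study genes absent from the background do not count toward the study
#' size \code{n} and are reported in the \code{"unannotated"} attribute.
#'
#' @param study_set Character vector of gene ids.
#' @param annotation An \code{annotation_map}.
#' @param alpha Significance level for the \code{enriched} flag applied to
#'   the Bonferroni-adjusted p (default 0.05).
#' @param method \code{"HYPERGEOMETRIC"} (default) or \code{"BINOMIAL"}.
#' @return Tibble with one row per tested term: \code{term_id},
#'   \code{term_name}, \code{k} (study genes with term), \code{n}
#'   (annotated study size), \code{K} (background genes with term),
#'   \code{N} (background size), \code{p_raw}, \code{p_adj},
#'   \code{enriched}; sorted by \code{p_adj} then \code{term_id}.
#' @export
enrich <- function(study_set, annotation, alpha = 0.05,
                   method = c("HYPERGEOMETRIC", "BINOMIAL")) {
  stopifnot(inherits(annotation, "annotation_map"),
            alpha > 0, alpha < 1)
  method <- match.arg(method)
  study <- unique(as.character(study_set))
  unannotated <- setdiff(study, annotation$background)
  study <- intersect(study, annotation$background)
  if (length(study) == 0L) {
    stop("no study genes present in the annotation background")
  }
  n <- length(study)
  N <- length(annotation$background)
  terms <- sort(names(annotation$term2genes))
  K <- vapply(annotation$term2genes[terms], length, integer(1))
  k <- vapply(annotation$term2genes[terms], function(g) {
    length(intersect(g, study))
  }, integer(1))
  p_raw <- if (method == "HYPERGEOMETRIC") {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  } else {
    stats::pbinom(k - 1L, n, K / N, lower.tail = FALSE)
  }
  m <- length(terms)
  p_adj <- bonferroni(p_raw, m)
  out <- tibble::tibble(
    term_id = terms,
    term_name = unname(ifelse(terms %in% names(annotation$term_names),
                              annotation$term_names[terms], "")),
    k = unname(k), n = n, K = unname(K), N = N,
    p_raw = unname(p_raw), p_adj = unname(p_adj),
    enriched = p_adj < alpha
  )
  out <- out[order(out$p_adj, out$term_id), ]
  attr(out, "unannotated") <- sort(unannotated)
  attr(out, "m_tested") <- m
  out
}

#' Bonferroni correction
#'
#' Elementwise \code{min(1, p * m)}; order-preserving.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param m Number of tests; must be at least \code{length(p_values)}.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p_values, m) {
  stopifnot(m >= length(p_values), m >= 1)
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  pmin(1, p_values * m)
}

#' Write an enrichment-result table with significance stars
#'
#' Stars encode the adjusted p-value: \code{*} < 0.05, \code{**} < 0.01,
#' \code{***} < 0.001.
#'
#' @param results Tibble from [enrich()].
#' @param path Output TSV path.
#' @export
write_enrichment <- function(results, path) {
  stars <- ifelse(results$p_adj < 0.001, "***",
                  ifelse(results$p_adj < 0.01, "**",
                         ifelse(results$p_adj < 0.05, "*", "")))
  out <- dplyr::mutate(results, significance = stars)
  readr::write_tsv(out, path)
  invisible(path)
}
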