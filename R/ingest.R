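#' Normalize a miRNA identifier
#'
#' Canonicalizes miRNA names so records from different databases join on the
#' same key: lowercases, strips all whitespace, and prepends the species
#' prefix (default \code{"rno"}, Rattus norvegicus) when absent. Arm suffixes
#' such as \code{-5p}/\code{-3p} are preserved verbatim. The function is
#' idempotent.
#'
#' @param raw Character vector of raw miRNA names.
#' @param species_prefix Species prefix to enforce (default \code{"rno"}).
#' @return Character vector of canonical miRNA names.
#' @examples
#' normalize_mirna_id("miR-195")        # "rno-mir-195"
#' normalize_mirna_id("RNO-miR-30a-5p") # "rno-mir-30a-5p"
#' @export
normalize_mirna_id <- function(raw, species_prefix = "rno") {
  stopifnot(is.character(raw))
  x <- tolower(gsub("[[:space:]]+", "", raw))
  if (any(!nzchar(x))) {
    stop("miRNA identifier empty after whitespace stripping")
  }
  pref <- paste0(tolower(species_prefix), "-")
  has_pref <- startsWith(x, pref)
  x[!has_pref] <- paste0(pref, x[!has_pref])
  x
}

#' Normalize a gene symbol
#'
#' Uppercases and strips surrounding whitespace so symbols from different
#' databases join on the same key. The original spelling is retained in the
#' \code{"original"} attribute for reporting. Idempotent.
#'
#' @param raw Character vector of raw gene symbols.
#' @return Character vector of canonical symbols with attribute
#'   \code{"original"}.
#' @export
normalize_gene_id <- function(raw) {
  stopifnot(is.character(raw))
  x <- toupper(trimws(raw))
  if (any(!nzchar(x))) {
    stop("gene identifier empty after whitespace stripping")
  }
  attr(x, "original") <- as.character(raw)
  x
}

#' Define an interaction-database dialect
#'
#' A dialect describes how one database release lays out its delimited file:
#' which 0-based columns hold the miRNA, gene and (for predicted databases)
#' score fields, how many header rows to skip, and the delimiter. Predicted
#' databases (\code{MIRDB}, \code{MICRORNA_ORG}) must declare a score column;
#' the validated database (\code{MIRTARBASE}) needs none.
#'
#' @param db_name One of \code{"MIRDB"}, \code{"MICRORNA_ORG"},
#'   \code{"MIRTARBASE"}.
#' @param column_map Named list of 0-based column indices with elements
#'   \code{mirna}, \code{gene} and, for predicted databases, \code{score}.
#' @param header_rows Number of header rows to skip (default 1).
#' @param delimiter Field delimiter (default tab).
#' @return A \code{db_dialect} object.
#' @export
db_dialect <- function(db_name, column_map, header_rows = 1L, delimiter = "\t") {
  db_name <- match.arg(db_name, c("MIRDB", "MICRORNA_ORG", "MIRTARBASE"))
  db_class <- if (db_name == "MIRTARBASE") "VALIDATED" else "PREDICTED"
  stopifnot(
    is.list(column_map),
    all(c("mirna", "gene") %in% names(column_map)),
    nchar(delimiter) == 1L, header_rows >= 0L
  )
  if (db_class == "PREDICTED" && is.null(column_map$score)) {
    stop("predicted database dialect requires a score column")
  }
  idx <- unlist(column_map)
  if (anyDuplicated(idx)) stop("dialect column indices must be distinct")
  structure(
    list(
      db_name = db_name, db_class = db_class,
      column_map = lapply(column_map, as.integer),
      header_rows = as.integer(header_rows), delimiter = delimiter
    ),
    class = "db_dialect"
  )
}

#' Default dialect set for the three supported databases
#'
#' Columns follow the synthetic-file layout: miRNA, gene, score (predicted)
#' or support type (validated), tab-delimited with one header row.
#'
#' @return Named list of \code{db_dialect} objects with entries
#'   \code{mirdb}, \code{microrna_org_conserved},
#'   \code{microrna_org_nonconserved}, \code{mirtarbase}.
#' @export
default_dialects <- function() {
  morg <- db_dialect("MICRORNA_ORG", list(mirna = 0, gene = 1, score = 2))
  list(
    mirdb = db_dialect("MIRDB", list(mirna = 0, gene = 1, score = 2)),
    microrna_org_conserved = morg,
    microrna_org_nonconserved = morg,
    mirtarbase = db_dialect("MIRTARBASE", list(mirna = 0, gene = 1))
  )
}

#' Read dialect definitions from a YAML or JSON config
#'
#' @param path Config file with keys \code{mirdb},
#'   \code{microrna_org_conserved}, \code{microrna_org_nonconserved},
#'   \code{mirtarbase}, each holding \code{db_name}, \code{column_map},
#'   and optionally \code{header_rows} and \code{delimiter}.
#' @return Named list of \code{db_dialect} objects.
#' @export
read_dialect_config <- function(path) {
  if (!file.exists(path)) stop("dialect config not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  lapply(cfg, function(d) {
    db_dialect(
      db_name = d$db_name,
      column_map = d$column_map,
      header_rows = if (is.null(d$header_rows)) 1L else d$header_rows,
      delimiter = if (is.null(d$delimiter)) "\t" else d$delimiter
    )
  })
}

#' Read a differential-miRNA expression table
#'
#' Expects a delimited text file with at least two columns: miRNA id and a
#' regulation direction token (\code{up}/\code{down}, case-insensitive).
#' Identifiers are canonicalized with [normalize_mirna_id()]; duplicates
#' after normalization are an error.
#'
#' @param path Path to the expression table.
#' @param delimiter Field delimiter (default tab).
#' @param species_prefix Passed to [normalize_mirna_id()].
#' @return Tibble with columns \code{mirna_id}, \code{direction}
#'   (\code{"UP"}/\code{"DOWN"}).
#' @export
read_expression_table <- function(path, delimiter = "\t", species_prefix = "rno") {
  if (!file.exists(path)) stop("expression table not found: ", path)
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (nrow(df) == 0L) {
    return(tibble::tibble(mirna_id = character(), direction = character()))
  }
  if (ncol(df) < 2L) stop("expression table needs >= 2 columns (id, direction)")
  dir_tok <- toupper(trimws(df[[2L]]))
  bad <- which(!dir_tok %in% c("UP", "DOWN"))
  if (length(bad) > 0L) {
    stop(sprintf("unparseable direction token %s at data row %d",
                 dQuote(df[[2L]][bad[1L]]), bad[1L]))
  }
  ids <- normalize_mirna_id(df[[1L]], species_prefix)
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate miRNA id after normalization: ", dup)
  }
  tibble::tibble(mirna_id = ids, direction = dir_tok)
}

#' Read one interaction-database file under a dialect
#'
#' Parses each data row into a uniform interaction record with normalized
#' identifiers. Rows with a blank miRNA or gene are skipped and counted.
#' Prefix-less miRNA names acquire the configured species prefix; records
#' carrying a different species prefix are dropped (with a count) when
#' \code{species_filter} is TRUE, mirroring restriction to the rat-specific
#' subset of each database. Duplicate
#' rows for one (miRNA, gene) pair within the file collapse to a single
#' record keeping the best score: maximum for \code{MIRDB} (higher target
#' score is better), minimum for \code{MICRORNA_ORG} (more negative mirSVR
#' is stronger).
#'
#' @param path Path to the database file.
#' @param dialect A [db_dialect()] object.
#' @param species_prefix Species prefix for miRNA normalization.
#' @param species_filter Drop records carrying a different species prefix
#'   (default TRUE).
#' @param gene_map Optional named character vector mapping accessions to
#'   symbols, applied to the raw gene column before normalization.
#' @param max_malformed_frac Abort if more than this fraction of data rows
#'   carries a malformed score (default 0.01).
#' @return Tibble with columns \code{mirna_id}, \code{gene_id},
#'   \code{db_name}, \code{db_class}, \code{score} (NA for validated
#'   records), carrying a \code{"parse_report"} attribute (one-row tibble:
#'   file, rows_read, rows_kept, rows_skipped, duplicates_collapsed).
#' @export
read_interaction_db <- function(path, dialect, species_prefix = "rno",
                                species_filter = TRUE, gene_map = NULL,
                                max_malformed_frac = 0.01) {
  stopifnot(inherits(dialect, "db_dialect"))
  if (!file.exists(path)) stop("database file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect$header_rows > 0L && length(lines) >= dialect$header_rows) {
    lines <- lines[-seq_len(dialect$header_rows)]
  }
  lines <- lines[nzchar(lines)]
  rows_read <- length(lines)
  empty_rec <- tibble::tibble(
    mirna_id = character(), gene_id = character(),
    db_name = character(), db_class = character(), score = numeric()
  )
  if (rows_read == 0L) {
    warning("no data rows in ", path)
    attr(empty_rec, "parse_report") <- parse_report_row(path, 0L, 0L, 0L, 0L)
    return(empty_rec)
  }
  fields <- strsplit(lines, dialect$delimiter, fixed = TRUE)
  need <- max(unlist(dialect$column_map)) + 1L
  width_ok <- lengths(fields) >= need
  cm <- dialect$column_map
  get_col <- function(i) {
    vapply(fields, function(f) if (length(f) >= i + 1L) f[[i + 1L]] else "",
           character(1))
  }
  mirna_raw <- trimws(get_col(cm$mirna))
  gene_raw <- trimws(get_col(cm$gene))
  keep <- width_ok & nzchar(mirna_raw) & nzchar(gene_raw)

  score <- rep(NA_real_, rows_read)
  if (dialect$db_class == "PREDICTED") {
    score_raw <- get_col(cm$score)
    score <- suppressWarnings(as.numeric(score_raw))
    malformed <- keep & !is.finite(score)
    if (sum(malformed) / rows_read > max_malformed_frac) {
      stop(sprintf("%d/%d rows with malformed score in %s",
                   sum(malformed), rows_read, path))
    }
    keep <- keep & is.finite(score)
  }

  mirna_kept <- mirna_raw[keep]
  if (species_filter && length(mirna_kept) > 0L) {
    # a record prefixed with another species code is foreign; names that
    # open with the mir/let family token are merely prefix-less
    low <- tolower(mirna_kept)
    tok <- sub("-.*$", "", low)
    other <- grepl("^[a-z]{3}-", low) &
      !tok %in% c(tolower(species_prefix), "mir", "let")
    idx_keep <- which(keep)
    keep[idx_keep[other]] <- FALSE
  }
  rows_skipped <- rows_read - sum(keep)

  gene_kept <- gene_raw[keep]
  if (!is.null(gene_map)) {
    hit <- gene_kept %in% names(gene_map)
    gene_kept[hit] <- unname(gene_map[gene_kept[hit]])
  }
  rec <- tibble::tibble(
    mirna_id = if (sum(keep)) normalize_mirna_id(mirna_raw[keep], species_prefix) else character(),
    gene_id = if (sum(keep)) as.character(normalize_gene_id(gene_kept)) else character(),
    db_name = rep(dialect$db_name, sum(keep)),
    db_class = rep(dialect$db_class, sum(keep)),
    score = score[keep]
  )

  # collapse duplicate (miRNA, gene) rows keeping the best per-database score
  dup_n <- 0L
  if (nrow(rec) > 0L) {
    key <- paste(rec$mirna_id, rec$gene_id, sep = "\r")
    dup_n <- sum(duplicated(key))
    if (dup_n > 0L) {
      best <- if (dialect$db_name == "MIRDB") max else min
      rec <- dplyr::summarise(
        dplyr::group_by(rec, .data$mirna_id, .data$gene_id,
                        .data$db_name, .data$db_class),
        score = if (all(is.na(.data$score))) NA_real_ else best(.data$score),
        .groups = "drop"
      )
    }
  }
  if (nrow(rec) == 0L) warning("empty record set from ", path)
  attr(rec, "parse_report") <-
    parse_report_row(path, rows_read, nrow(rec), rows_skipped, dup_n)
  rec
}

parse_report_row <- function(file, rows_read, rows_kept, rows_skipped,
                             duplicates_collapsed) {
  tibble::tibble(
    file = basename(file), rows_read = as.integer(rows_read),
    rows_kept = as.integer(rows_kept), rows_skipped = as.integer(rows_skipped),
    duplicates_collapsed = as.integer(duplicates_collapsed)
  )
}

#' Read all configured databases and bind their records
#'
#' @param paths Named list/vector of file paths; names must match
#'   \code{dialects} entries.
#' @param dialects Named list of [db_dialect()] objects (see
#'   [default_dialects()]).
#' @param ... Passed to [read_interaction_db()].
#' @return Tibble of interaction records with a combined
#'   \code{"parse_report"} attribute.
#' @export
read_all_databases <- function(paths, dialects = default_dialects(), ...) {
  stopifnot(all(names(paths) %in% names(dialects)))
  recs <- lapply(names(paths), function(nm) {
    read_interaction_db(paths[[nm]], dialects[[nm]], ...)
  })
  out <- dplyr::bind_rows(lapply(recs, function(r) { attributes(r)$parse_report <- NULL; r }))
  attr(out, "parse_report") <-
    dplyr::bind_rows(lapply(recs, attr, "parse_report"))
  out
}

#' Write interaction records back to a dialect file
#'
#' Inverse of [read_interaction_db()] for round-trip testing and export.
#'
#' @param records Tibble of interaction records.
#' @param path Output path.
#' @param dialect A [db_dialect()] object.
#' @export
write_interaction_db <- function(records, path, dialect) {
  stopifnot(inherits(dialect, "db_dialect"))
  cm <- dialect$column_map
  ncols <- max(unlist(cm)) + 1L
  m <- matrix("", nrow = nrow(records), ncol = ncols)
  m[, cm$mirna + 1L] <- records$mirna_id
  m[, cm$gene + 1L] <- records$gene_id
  if (!is.null(cm$score)) {
    m[, cm$score + 1L] <- format_score(records$score)
  }
  header <- rep(paste(rep("col", ncols), seq_len(ncols), sep = "_"),
                length.out = ncols)
  con <- file(path, "wb")
  on.exit(close(con))
  if (dialect$header_rows > 0L) {
    writeLines(rep(paste(header, collapse = dialect$delimiter),
                   dialect$header_rows), con)
  }
  if (nrow(records) > 0L) {
    writeLines(apply(m, 1L, paste, collapse = dialect$delimiter), con)
  }
  invisible(path)
}

format_score <- function(x) {
  ifelse(is.na(x), "", formatC(x, format = "fg", digits = 15))
}
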