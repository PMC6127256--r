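#' Read a three-cell-type expression matrix
#'
#' Reads a tab-separated expression table whose first column holds gene
#' symbols and whose remaining column headers identify replicates of the
#' three cell types. A column belongs to a cell type when its header starts
#' with `"Progenitor"`, `"Daughter1"` or `"Daughter2"` (e.g. `Daughter1_r2`),
#' so arbitrary replicate suffixes are accepted. Values must be non-negative,
#' numeric and on linear scale (the NRD statistic divides expression values,
#' which is meaningless for log-scale data that can be zero or negative).
#'
#' @param path Path to a UTF-8, tab-delimited file with a header row.
#'
#' @return A tibble in long form with columns `gene`, `replicate`,
#'   `cell_type` and `value`, preserving the file's gene and column order.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "gene\tProgenitor_1\tDaughter1_1\tDaughter2_1",
#'   "GATA1\t5\t9\t1",
#'   "SPI1\t5\t1\t9"
#' ), f)
#' read_expression(f)
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 2) abort("expression file needs a gene column plus at least one replicate column")

  genes <- stringr::str_trim(raw[[1]])
  replicates <- colnames(raw)[-1]
  if (anyDuplicated(replicates)) {
    abort(sprintf("duplicate replicate column label(s): %s",
                  paste(unique(replicates[duplicated(replicates)]), collapse = ", ")))
  }

  cell_type <- dplyr::case_when(
    startsWith(replicates, "Progenitor") ~ "Progenitor",
    startsWith(replicates, "Daughter1") ~ "Daughter1",
    startsWith(replicates, "Daughter2") ~ "Daughter2",
    TRUE ~ NA_character_
  )
  if (anyNA(cell_type)) {
    abort(sprintf(
      "replicate column(s) not assignable to a cell type (header must start with %s): %s",
      paste(CELL_TYPES, collapse = ", "),
      paste(replicates[is.na(cell_type)], collapse = ", ")
    ))
  }
  for (ct in CELL_TYPES) {
    if (!any(cell_type == ct)) abort(sprintf("no replicates for %s", ct))
  }

  dup <- unique(genes[duplicated(genes)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene symbol(s): %s", paste(dup, collapse = ", ")))
  }

  values <- matrix(NA_real_, nrow = nrow(raw), ncol = length(replicates))
  for (j in seq_along(replicates)) {
    col_chr <- stringr::str_trim(raw[[j + 1]])
    col_num <- suppressWarnings(as.numeric(col_chr))
    bad <- which(is.na(col_num))
    if (length(bad) > 0) {
      abort(sprintf(
        "non-numeric or missing expression value at gene '%s', column '%s'",
        genes[bad[1]], replicates[j]
      ))
    }
    neg <- which(col_num < 0)
    if (length(neg) > 0) {
      abort(sprintf(
        "negative expression value (%g) at gene '%s', column '%s'",
        col_num[neg[1]], genes[neg[1]], replicates[j]
      ))
    }
    values[, j] <- col_num
  }

  tibble(
    gene = rep(genes, each = length(replicates)),
    replicate = rep(replicates, times = length(genes)),
    cell_type = rep(cell_type, times = length(genes)),
    value = as.vector(t(values))
  )
}

#' Write an expression matrix back to the tab-separated layout
#'
#' @param expr Long-form expression tibble as returned by [read_expression()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  validate_expression(expr)
  wide <- tidyr::pivot_wider(
    expr[, c("gene", "replicate", "value")],
    names_from = "replicate", values_from = "value"
  )
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

validate_expression <- function(expr) {
  needed <- c("gene", "replicate", "cell_type", "value")
  if (!all(needed %in% colnames(expr))) {
    abort(sprintf("expression data must have columns %s", paste(needed, collapse = ", ")))
  }
  if (!all(expr$cell_type %in% CELL_TYPES)) abort("unknown cell_type label in expression data")
  for (ct in CELL_TYPES) {
    if (!any(expr$cell_type == ct)) abort(sprintf("no replicates for %s", ct))
  }
  if (anyNA(expr$value) || any(expr$value < 0)) abort("expression values must be non-negative and complete")
  invisible(expr)
}

#' Read a prior-knowledge network (PKN)
#'
#' Reads a tab-separated edge list of directed TF-TF interactions: source TF,
#' interaction type, target TF. The interaction type must be one of
#' `"Activation"`, `"Inhibition"` or `"Unspecified"`. No header is required;
#' a first row whose type field is outside that vocabulary is treated as a
#' header and skipped with a warning. Exact duplicate rows are collapsed to a
#' single edge; duplicate source/target rows with *different* signs are kept
#' as distinct edges, since curated networks legitimately report both.
#' Self-loops are permitted.
#'
#' @param path Path to a tab-delimited file with at least three columns.
#' @return A tibble with columns `source`, `sign`, `target`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("GATA1\tInhibition\tSPI1", "SPI1\tInhibition\tGATA1"), f)
#' read_pkn(f)
#' @export
read_pkn <- function(path) {
  if (!file.exists(path)) abort(sprintf("PKN file not found: %s", path))
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 3) abort("PKN file must have three tab-separated columns: source, type, target")
  if (ncol(raw) > 3) warn("PKN file has more than three columns; extra columns ignored")

  pkn <- tibble(
    source = stringr::str_trim(raw[[1]]),
    sign = stringr::str_trim(raw[[2]]),
    target = stringr::str_trim(raw[[3]])
  )
  bad <- !(pkn$sign %in% INTERACTION_SIGNS)
  if (any(bad) && bad[1]) {
    warn(sprintf("skipping header row: '%s'", paste(raw[1, ], collapse = "\t")))
    pkn <- pkn[-1, , drop = FALSE]
    bad <- bad[-1]
  }
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf(
      "unknown interaction type '%s' on line '%s' (allowed: %s)",
      pkn$sign[i], paste(pkn[i, ], collapse = "\t"),
      paste(INTERACTION_SIGNS, collapse = ", ")
    ))
  }
  n_before <- nrow(pkn)
  pkn <- dplyr::distinct(pkn)
  n_dup <- n_before - nrow(pkn)
  if (n_dup > 0) inform(sprintf("collapsed %d duplicate interaction(s)", n_dup))
  pkn
}

#' Write a PKN edge list
#'
#' @param pkn Tibble with columns `source`, `sign`, `target`.
#' @param path Output file path. Written without a header, matching the
#'   three-column input dialect.
#' @return `path`, invisibly.
#' @export
write_pkn <- function(pkn, path) {
  validate_pkn(pkn)
  readr::write_tsv(pkn[, c("source", "sign", "target")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

validate_pkn <- function(pkn) {
  needed <- c("source", "sign", "target")
  if (!all(needed %in% colnames(pkn))) {
    abort("PKN must have columns source, sign, target")
  }
  if (!all(pkn$sign %in% INTERACTION_SIGNS)) abort("PKN sign outside the closed vocabulary")
  invisible(pkn)
}

#' Node set of a PKN
#'
#' @param pkn PKN tibble.
#' @return Character vector: the union of sources and targets, in first
#'   appearance order.
#' @export
pkn_nodes <- function(pkn) {
  unique(c(rbind(pkn$source, pkn$target)))
}

prediction_cols <- c("tf_a", "tf_b", "frac_scc_cooccur", "frac_scc_direct",
                     "min_outdegree", "score", "rank")

#' Write ranked TF-pair predictions
#'
#' Writes the ranked pair report as a TSV with header columns `tf_a`, `tf_b`,
#' `frac_scc_cooccur`, `frac_scc_direct`, `min_outdegree`, `score`, `rank`,
#' sorted by rank. An empty report yields a header-only file.
#'
#' @param report Pair-score report tibble, as produced by [rank_pairs()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(report, path) {
  if (!all(prediction_cols %in% colnames(report))) {
    abort(sprintf("report must have columns %s", paste(prediction_cols, collapse = ", ")))
  }
  out <- dplyr::arrange(report[, prediction_cols], .data$rank)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a predictions file
#'
#' @param path Path written by [write_predictions()].
#' @return The pair-score report tibble.
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    tf_a = readr::col_character(),
    tf_b = readr::col_character(),
    frac_scc_cooccur = readr::col_double(),
    frac_scc_direct = readr::col_double(),
    min_outdegree = readr::col_integer(),
    score = readr::col_double(),
    rank = readr::col_integer()
  ), progress = FALSE)
}

#' Read ranked TF lists from other predictors
#'
#' Each file is either a plain list with one TF symbol per line (rank =
#' line number; the method name defaults to the file name without
#' extension), or a two-column TSV `method<TAB>tf` in rank order.
#'
#' @param paths Character vector of file paths.
#' @return A rankings tibble with columns `method`, `rank`, `tf`.
#' @export
read_rankings <- function(paths) {
  purrr::map(paths, function(p) {
    if (!file.exists(p)) abort(sprintf("ranking file not found: %s", p))
    lines <- readr::read_lines(p, progress = FALSE)
    lines <- lines[stringr::str_trim(lines) != ""]
    if (length(lines) == 0) abort(sprintf("ranking file is empty: %s", p))
    parts <- stringr::str_split(lines, "\t")
    if (all(lengths(parts) >= 2)) {
      tibble(
        method = stringr::str_trim(purrr::map_chr(parts, 1)),
        tf = stringr::str_trim(purrr::map_chr(parts, 2))
      ) |>
        dplyr::group_by(.data$method) |>
        dplyr::mutate(rank = dplyr::row_number()) |>
        dplyr::ungroup() |>
        dplyr::select("method", "rank", "tf")
    } else {
      tibble(
        method = tools::file_path_sans_ext(basename(p)),
        rank = seq_along(lines),
        tf = stringr::str_trim(lines)
      )
    }
  }) |>
    purrr::list_rbind()
}
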