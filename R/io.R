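#' Read a long-format drug-combination response table
#'
#' One row per measured (drug1, drug2, dose1, dose2, cell line, response)
#' tuple. The on-disk file is a comma-separated table with a header row;
#' column names are mapped onto the canonical names through `columns`, so
#' exports from different screens can be ingested without renaming files.
#' Extra columns are ignored.
#'
#' @param path Path to a CSV file.
#' @param columns Named character vector mapping canonical names
#'   (`drug1`, `drug2`, `dose1`, `dose2`, `cell`, `response`) to the file's
#'   column names. Entries may be omitted when the file already uses the
#'   canonical name.
#' @return A `data.frame` with columns `drug1`, `drug2`, `dose1`, `dose2`,
#'   `cell`, `response`, rows in file order.
#' @export
read_combo_table <- function(path, columns = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("drug1", "drug2", "dose1", "dose2", "cell", "response")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) map[names(columns)] <- columns
  missing <- map[!map %in% names(df)]
  if (length(missing) > 0L) {
    stop("combo table is missing required column(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  out <- df[, map, drop = FALSE]
  names(out) <- canonical
  for (col in c("dose1", "dose2", "response")) {
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))
  }
  out$drug1 <- as.character(out$drug1)
  out$drug2 <- as.character(out$drug2)
  out$cell <- as.character(out$cell)
  validate_combo_table(out)
  out
}

#' @rdname read_combo_table
#' @param x A combo table `data.frame`.
#' @export
write_combo_table <- function(x, path) {
  validate_combo_table(x)
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a combo table against its invariants
#'
#' Doses must be strictly positive and responses finite; violations are
#' reported with the offending row index.
#'
#' @param x A `data.frame` with the canonical combo columns.
#' @return `x`, invisibly, if valid.
#' @export
validate_combo_table <- function(x) {
  req <- c("drug1", "drug2", "dose1", "dose2", "cell", "response")
  if (!all(req %in% names(x))) {
    stop("combo table is missing required column(s): ",
         paste(sprintf("'%s'", setdiff(req, names(x))), collapse = ", "),
         call. = FALSE)
  }
  for (col in c("dose1", "dose2", "response")) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("non-finite or non-numeric '%s' at row %d", col, bad[1L]),
           call. = FALSE)
    }
  }
  for (col in c("dose1", "dose2")) {
    bad <- which(x[[col]] <= 0)
    if (length(bad) > 0L) {
      stop(sprintf("non-positive '%s' at row %d (doses must be > 0)", col, bad[1L]),
           call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a monotherapy response table
#'
#' Single-drug dose-response measurements: one row per
#' (drug, dose, cell line, response).
#'
#' @inheritParams read_combo_table
#' @param columns Named map onto canonical names `drug`, `dose`, `cell`,
#'   `response`.
#' @return A `data.frame` with columns `drug`, `dose`, `cell`, `response`.
#' @export
read_mono_table <- function(path, columns = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("drug", "dose", "cell", "response")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(columns)) map[names(columns)] <- columns
  missing <- map[!map %in% names(df)]
  if (length(missing) > 0L) {
    stop("mono table is missing required column(s): ",
         paste(sprintf("'%s'", missing), collapse = ", "), call. = FALSE)
  }
  out <- df[, map, drop = FALSE]
  names(out) <- canonical
  out$dose <- suppressWarnings(as.numeric(out$dose))
  out$response <- suppressWarnings(as.numeric(out$response))
  out$drug <- as.character(out$drug)
  out$cell <- as.character(out$cell)
  bad <- which(!is.finite(out$dose) | out$dose <= 0)
  if (length(bad) > 0L) stop("non-positive or non-numeric dose at row ", bad[1L], call. = FALSE)
  bad <- which(!is.finite(out$response))
  if (length(bad) > 0L) stop("non-finite response at row ", bad[1L], call. = FALSE)
  out
}

#' Read a drug library (SMILES strings)
#'
#' @param path CSV with columns `drug_id` and `smiles` (further columns are
#'   ignored).
#' @return A `data.frame` with character columns `drug_id` and `smiles`.
#' @export
read_drug_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c("drug_id", "smiles")) {
    if (!col %in% names(df)) stop("drug library is missing column '", col, "'", call. = FALSE)
  }
  out <- data.frame(drug_id = as.character(df$drug_id),
                    smiles = as.character(df$smiles),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$drug_id)) {
    stop("duplicated drug_id in drug library: '",
         out$drug_id[duplicated(out$drug_id)][1L], "'", call. = FALSE)
  }
  if (any(!nzchar(out$smiles))) {
    stop("empty SMILES for drug_id '", out$drug_id[!nzchar(out$smiles)][1L], "'", call. = FALSE)
  }
  out
}

#' Read a cell-line expression matrix
#'
#' A rectangular numeric matrix, cell lines in rows (first column = row
#' label), genes in columns. All profiles in one file must have the same
#' length; the default screening panel uses 78 high-variance genes but the
#' length is data-driven.
#'
#' @param path CSV or TSV file; the separator is sniffed from the header line.
#' @return A numeric matrix with `rownames` = cell-line identifiers.
#' @export
read_expression_matrix <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) != 1L) {
    stop("ragged expression matrix: rows have differing field counts", call. = FALSE)
  }
  df <- utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels)) {
    stop("duplicated cell-line label: '", labels[duplicated(labels)][1L], "'", call. = FALSE)
  }
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value for cell '%s', column %d",
                 labels[bad[1L]], bad[2L]), call. = FALSE)
  }
  rownames(mat) <- labels
  mat
}

#' Canonical unordered drug-pair key
#'
#' Matching of combination measurements is on the *unordered* drug pair
#' within a cell line: the record (A, B, doseA, doseB, c) denotes the same
#' physical experiment as (B, A, doseB, doseA, c). The key orders the two
#' drug identifiers lexicographically so that both orientations map to the
#' same string; doses travel with their drug and are not part of the key.
#'
#' @param drug1,drug2 Character vectors of drug identifiers (recycled), or
#'   `drug1` may be a combo-table `data.frame`, in which case its columns are
#'   used and the remaining arguments are ignored.
#' @param cell Character vector of cell-line identifiers.
#' @return A character vector of keys; equal keys identify the same
#'   (unordered pair, cell line).
#' @export
#' @examples
#' canonical_pair_key("B", "A", "cellX") == canonical_pair_key("A", "B", "cellX")
canonical_pair_key <- function(drug1, drug2 = NULL, cell = NULL) {
  if (is.data.frame(drug1)) {
    df <- drug1
    drug1 <- df$drug1
    drug2 <- df$drug2
    cell <- df$cell
  }
  lo <- ifelse(as.character(drug1) <= as.character(drug2), drug1, drug2)
  hi <- ifelse(as.character(drug1) <= as.character(drug2), drug2, drug1)
  paste(lo, hi, cell, sep = "\x1f")
}
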