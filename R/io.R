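#' Read a delimited numeric matrix
#'
#' Reads a connectome or time-series matrix from delimited text (comma or
#' whitespace separated). An optional header row and/or leading label column
#' of region names is detected and stripped; labels, when present, are kept
#' as dimnames.
#'
#' @param path Path to the file.
#' @param expect_square If `TRUE`, error unless the matrix is square.
#' @param symmetrize_tol Non-negative tolerance: for square matrices, any
#'   asymmetry `max |A - t(A)|` at or below this is averaged away via
#'   `(A + t(A))/2`; larger asymmetry is an error. Use `NULL` (default) to
#'   skip the symmetry check entirely (e.g. for time series).
#' @return A numeric matrix.
#' @examples
#' f <- tempfile()
#' writeLines(c("0,2", "2,0"), f)
#' read_matrix(f, expect_square = TRUE, symmetrize_tol = 0.01)
#' @export
read_matrix <- function(path, expect_square = FALSE, symmetrize_tol = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)

  split_row <- function(x) {
    x <- trimws(x)
    if (grepl(",", x, fixed = TRUE)) strsplit(x, "\\s*,\\s*")[[1]]
    else strsplit(x, "\\s+")[[1]]
  }
  cells <- lapply(lines, split_row)

  is_num <- function(v) !any(is.na(suppressWarnings(as.numeric(v))))
  none_num <- function(v) all(is.na(suppressWarnings(as.numeric(v))))
  col_labels <- NULL
  row_labels <- NULL
  # header row: no cell of the first row parses as numeric (a single stray
  # non-numeric cell in a data row must stay a parse error, not a header)
  if (none_num(cells[[1]]) && length(cells) > 1) {
    col_labels <- cells[[1]]
    cells <- cells[-1]
  }
  # label column: the first cell of every row is non-numeric
  firsts <- vapply(cells, `[`, character(1), 1L)
  if (none_num(firsts)) {
    row_labels <- firsts
    cells <- lapply(cells, `[`, -1L)
    if (!is.null(col_labels) && length(col_labels) == length(cells[[1]]) + 1L)
      col_labels <- col_labels[-1L]
  }

  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in ", path, ": widths ", paste(unique(widths), collapse = ", "))
  nc <- widths[1]
  out <- matrix(NA_real_, nrow = length(cells), ncol = nc)
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric cell at row ", i, ", column ", j, " of ", path,
           ": '", cells[[i]][j], "'")
    }
    out[i, ] <- v
  }
  if (!is.null(row_labels)) rownames(out) <- row_labels
  if (!is.null(col_labels) && length(col_labels) == nc) colnames(out) <- col_labels

  if (expect_square && nrow(out) != ncol(out))
    stop("expected a square matrix, got ", nrow(out), "x", ncol(out), ": ", path)
  if (!is.null(symmetrize_tol)) {
    stopifnot(symmetrize_tol >= 0)
    if (nrow(out) != ncol(out))
      stop("symmetrize_tol given but matrix is not square: ", path)
    asym <- max(abs(out - t(out)))
    if (asym > symmetrize_tol)
      stop("asymmetry ", format(asym), " exceeds tolerance ",
           format(symmetrize_tol), ": ", path)
    out <- (out + t(out)) / 2
  }
  out
}

#' Write a delimited matrix
#'
#' Companion writer for [read_matrix()]: comma-delimited, with dimnames
#' written as header row / label column when present.
#'
#' @param x Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  fmt <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  rows <- apply(x, 1L, function(r) paste(fmt(r), collapse = ","))
  if (!is.null(rownames(x))) rows <- paste(rownames(x), rows, sep = ",")
  header <- NULL
  if (!is.null(colnames(x))) {
    header <- paste(colnames(x), collapse = ",")
    if (!is.null(rownames(x))) header <- paste("region", header, sep = ",")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

.groups <- c("HC", "VS_UWS", "MCS_MINUS", "MCS_PLUS")

#' Read a subject manifest
#'
#' The manifest is a delimited table (TSV or CSV, with header) with columns
#' `subject_id`, `group`, `connectome_path`, `bold_t1_path` and optionally
#' `bold_t2_path`. Group labels must be one of `HC`, `VS_UWS`, `MCS_MINUS`,
#' `MCS_PLUS`. Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @param check_files If `TRUE` (default), error when a referenced data file
#'   does not exist.
#' @return A list of subject records, each a list with elements
#'   `subject_id`, `group`, `connectome_path`, `bold_paths` (named list with
#'   entries `t1` and, when present, `t2`).
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("subject_id", "group", "connectome_path", "bold_t1_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$subject_id)) {
    dup <- unique(df$subject_id[duplicated(df$subject_id)])
    stop("duplicate subject_id in manifest: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), .groups)
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(.groups, collapse = ", "), ")")

  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | !nzchar(p), NA_character_,
           ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p)))
  }
  records <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    paths <- list(t1 = resolve(row$bold_t1_path))
    if ("bold_t2_path" %in% names(df)) {
      t2 <- resolve(row$bold_t2_path)
      if (!is.na(t2)) paths$t2 <- t2
    }
    rec <- list(subject_id = as.character(row$subject_id),
                group = as.character(row$group),
                connectome_path = resolve(row$connectome_path),
                bold_paths = paths)
    if (check_files) {
      for (p in c(rec$connectome_path, unlist(paths))) {
        if (is.na(p) || !file.exists(p))
          stop("missing file for subject ", rec$subject_id, ": ", p)
      }
    }
    rec
  })
  names(records) <- vapply(records, `[[`, character(1), "subject_id")
  records
}

#' Load a subject record's matrices
#'
#' Reads the connectome and BOLD series referenced by a manifest record and
#' validates that region counts agree.
#'
#' @param record One element of the list returned by [read_manifest()].
#' @param symmetrize_tol Tolerance passed to [read_matrix()] for the
#'   connectome.
#' @return The record with `connectome` (matrix) and `bold` (named list of
#'   time-by-region matrices) filled in.
#' @export
load_subject <- function(record, symmetrize_tol = 1e-8) {
  record$connectome <- read_matrix(record$connectome_path, expect_square = TRUE,
                                   symmetrize_tol = symmetrize_tol)
  record$bold <- lapply(record$bold_paths, read_matrix)
  n <- nrow(record$connectome)
  for (lab in names(record$bold)) {
    b <- record$bold[[lab]]
    if (ncol(b) != n)
      stop("subject ", record$subject_id, " scan ", lab, ": ", ncol(b),
           " regions, connectome has ", n)
    if (nrow(b) < 3)
      stop("subject ", record$subject_id, " scan ", lab, ": fewer than 3 time points")
    if (!all(is.finite(b)))
      stop("subject ", record$subject_id, " scan ", lab, ": non-finite values")
  }
  record
}

#' Write a results table
#'
#' Writes a list of keyed records (named lists sharing one key set) as a
#' tab-separated table with a deterministic column order (sorted keys).
#' Numeric values round-trip through [read_results_table()] to at least 12
#' significant digits.
#'
#' @param rows Non-empty list of named lists with identical key sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!length(rows)) stop("nothing to write: empty row list")
  keys <- sort(names(rows[[1]]))
  if (is.null(keys) || any(!nzchar(keys))) stop("rows must have named fields")
  for (i in seq_along(rows)) {
    if (!identical(sort(names(rows[[i]])), keys))
      stop("row ", i, " has a different key set")
  }
  fmt <- function(v) {
    if (is.numeric(v)) format(v, digits = 15, trim = TRUE) else as.character(v)
  }
  lines <- vapply(rows, function(r)
    paste(vapply(keys, function(k) fmt(r[[k]]), character(1)), collapse = "\t"),
    character(1))
  writeLines(c(paste(keys, collapse = "\t"), lines), path)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to a TSV results table.
#' @return A data.frame; columns that parse as numeric are numeric.
#' @export
read_results_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}
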