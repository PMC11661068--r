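#' Read a delimited expression matrix
#'
#' Parses a text matrix with a header row of sample ids and the first
#' column holding feature labels. Tab-delimited by default; comma is used
#' for a `.csv` extension. Empty cells, `"NA"` and `"NaN"` are treated as
#' missing (acquisition software varies in its missing token).
#'
#' @param path File path.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`
#'   for transposed inputs, which are transposed back on read.
#' @param scale Declared measurement scale of the file (`"raw"` unless the
#'   file is known to already be log2).
#' @return An [expr_mat()].
#' @export
read_expression <- function(path,
                            orientation = c("features_in_rows", "samples_in_rows"),
                            scale = c("raw", "log2")) {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  sep <- matrix_delim(path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("expression file has no data rows: ", path, call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  col_ids <- header[-1L]
  if (anyDuplicated(col_ids)) {
    dup <- unique(col_ids[duplicated(col_ids)])
    stop("duplicate column header(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  n_col <- length(header)
  body <- fields[-1L]
  widths <- lengths(body)
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    stop(sprintf(
      "ragged row at line %d: %d fields, expected %d",
      bad + 1L, widths[bad], n_col
    ), call. = FALSE)
  }
  row_ids <- trimws(vapply(body, `[`, character(1), 1L))
  cells <- vapply(body, function(f) f[-1L], character(n_col - 1L))
  cells <- t(matrix(cells, nrow = n_col - 1L))
  cells[trimws(cells) %in% c("", "NA", "NaN")] <- NA_character_
  values <- matrix(as.numeric(cells), nrow = length(row_ids))
  dimnames(values) <- list(row_ids, col_ids)
  if (orientation == "samples_in_rows") values <- t(values)
  expr_mat(values, scale = scale)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression()]: header of sample ids, first column of
#' feature labels, missing entries written as empty cells. Values are
#' printed at full double precision so a read/write round trip is exact.
#'
#' @param mat An [expr_mat()].
#' @param path Output path (`.csv` selects comma, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  sep <- matrix_delim(path)
  v <- mat$values
  body <- apply(v, 1L, function(row) {
    out <- formatC(row, digits = 17, format = "g")
    out[is.na(row)] <- "NA" # explicit token: a trailing empty field would be lost
    out
  })
  body <- t(matrix(body, ncol = nrow(v)))
  lines <- c(
    paste(c("feature", colnames(v)), collapse = sep),
    vapply(seq_len(nrow(v)), function(i) {
      paste(c(rownames(v)[i], body[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

matrix_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a GMT gene-set file
#'
#' Standard GMT semantics: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Duplicate member symbols within a
#' line are collapsed with a warning; duplicate set names and short lines
#' are errors.
#'
#' @param path File path.
#' @return A named list of unique gene-symbol vectors, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(structure(list(), descriptions = character(0), class = "gene_sets"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf(
      "GMT line %d has %d field(s); need name, description and >= 1 member",
      which(short)[1L], lengths(fields)[which(short)[1L]]
    ), call. = FALSE)
  }
  names_ <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate gene set name(s): ",
      paste(unique(names_[duplicated(names_)]), collapse = ", "),
      call. = FALSE
    )
  }
  descriptions <- stats::setNames(vapply(fields, `[`, character(1), 2L), names_)
  sets <- lapply(fields, function(f) {
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning(sprintf(
        "set '%s': %d duplicate member(s) collapsed",
        f[1L], sum(duplicated(members))
      ), call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- names_
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    stop("empty gene set(s): ", paste(names_[empty], collapse = ", "), call. = FALSE)
  }
  structure(sets, descriptions = descriptions, class = "gene_sets")
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of gene-symbol vectors (optionally with a
#'   `descriptions` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated table with required columns `sample_id`, `donor_id`,
#' `sex`, `tissue`, `replicate`; extra columns pass through as covariates.
#'
#' @param path File path.
#' @return A validated metadata tibble (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = matrix_delim(path), stringsAsFactors = FALSE)
  sample_metadata(df)
}

#' Read a gene list (one symbol per line or BED-like table)
#'
#' Accepts either a plain one-column list of gene symbols, or a BED-like
#' tab-separated table (`chrom`, `start`, `end`, `gene`, 0-based half-open
#' coordinates) from which only the gene column is used — the form in which
#' differentially accessible regions are typically distributed.
#'
#' @param path File path.
#' @param gene_column Column index holding gene symbols when the file has
#'   4+ columns (default 4, the BED name field).
#' @return Character vector of unique gene symbols.
#' @export
read_gene_list <- function(path, gene_column = 4L) {
  lines <- readLines(path)
  lines <- trimws(lines[nzchar(trimws(lines))])
  if (length(lines) == 0L) return(character(0))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(fields, function(f) {
    if (length(f) >= gene_column) f[gene_column] else f[1L]
  }, character(1))
  unique(trimws(genes))
}
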