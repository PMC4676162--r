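#' Read an expression matrix
#'
#' Supports a dense delimited layout (header row of gene ids, first column of
#' cell ids, tab or comma separated) and MatrixMarket triplet files with
#' plain-text row/column id sidecars. Returns the matrix in cells x genes
#' orientation regardless of on-disk layout: set `transpose = TRUE` when the
#' file stores genes as rows.
#'
#' @param path file path; `.mtx` extension selects MatrixMarket unless
#'   `format` says otherwise.
#' @param format `"auto"`, `"dense"` or `"mtx"`.
#' @param transpose set TRUE when the file is genes x cells.
#' @param row_file,col_file sidecar id files for MatrixMarket input (one id
#'   per line, in file row/column order); default `<path>.rows` and
#'   `<path>.cols`.
#' @param sep field separator for dense input; guessed from the first line
#'   when NULL.
#' @return Numeric cells x genes matrix with cell and gene dimnames.
#' @export
read_matrix <- function(path, format = c("auto", "dense", "mtx"),
                        transpose = FALSE, row_file = NULL, col_file = NULL,
                        sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "dense"
  if (format == "mtx") {
    if (is.null(row_file)) row_file <- paste0(path, ".rows")
    if (is.null(col_file)) col_file <- paste0(path, ".cols")
    if (!file.exists(row_file) || !file.exists(col_file))
      stop("MatrixMarket sidecar id files not found: ", row_file, " / ", col_file)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(row_file); cn <- readLines(col_file)
    if (length(rn) != nrow(m) || length(cn) != ncol(m))
      stop("sidecar id counts do not match matrix dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    if (is.null(sep)) {
      first <- readLines(path, n = 1L)
      sep <- if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
    }
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = NULL,
                            stringsAsFactors = FALSE)
    ids <- as.character(df[[1L]])
    gene_names <- colnames(df)[-1L]   # subsetting a data.frame mangles duplicates
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric entries in dense matrix file ", path)
    dimnames(m) <- list(ids, gene_names)
  }
  if (transpose) m <- t(m)
  if (anyDuplicated(rownames(m)))
    stop("duplicate cell ids in ", path)
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene ids in ", path)
  m
}

#' Write a dense delimited expression matrix
#'
#' Inverse of the dense layout of [read_matrix()]: header row of gene ids and
#' a leading `cell_id` column.
#'
#' @param m cells x genes matrix with dimnames.
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
write_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(cell_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-cell covariate table
#'
#' Delimited text with a header; the id column (default the first) keys the
#' rows. When `cell_ids` is given the table is checked against and reordered
#' to that cell order.
#'
#' @param path file path.
#' @param cell_ids optional cell ids to align to.
#' @param id_column name or index of the cell-id column.
#' @param sep separator, guessed when NULL.
#' @return data.frame with a `cell_id` column first.
#' @export
read_covariates <- function(path, cell_ids = NULL, id_column = 1L,
                            sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first) && !grepl("\t", first)) "," else "\t"
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  idc <- if (is.numeric(id_column)) names(df)[id_column] else id_column
  ids <- as.character(df[[idc]])
  if (anyDuplicated(ids)) stop("duplicate cell ids in covariate table")
  df[[idc]] <- NULL
  df <- data.frame(cell_id = ids, df, check.names = FALSE)
  if (!is.null(cell_ids)) {
    miss <- setdiff(cell_ids, ids)
    if (length(miss))
      stop("covariate table is missing cell(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
    df <- df[match(cell_ids, ids), , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member gene ids. Members
#' are de-duplicated; sets left empty are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()] (`gene_sets` object).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need name, description, members",
                   i, length(parts)))
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("GMT set '", parts[1L], "' is empty; dropped")
      next
    }
    sets[[parts[1L]]] <- members
  }
  gene_set_collection(sets)
}

#' Write gene sets in GMT format
#'
#' @param collection `gene_sets` or named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  sets <- if (inherits(collection, "gene_sets")) collection$sets else collection
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
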