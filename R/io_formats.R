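#' @importFrom stats plogis rnorm runif rlnorm kmeans dist quantile median setNames
#' @importFrom utils read.delim write.table head
NULL

# All delimited I/O in this package defaults to tab-separated with a header
# row; the expression matrix is stored internally in genes x cells
# orientation regardless of the on-disk layout, which the caller declares.

#' Construct a validated expression matrix
#'
#' The central data container: a nonnegative numeric matrix of `m` genes by
#' `n` cells/spots with unique, ordered gene and cell identifiers carried as
#' dimnames.
#'
#' @param values numeric matrix, genes in rows and cells/spots in columns.
#' @param gene_ids character vector of length `nrow(values)`; defaults to
#'   existing rownames.
#' @param cell_ids character vector of length `ncol(values)`; defaults to
#'   existing colnames.
#' @return a numeric matrix of class `expression_matrix` with dimnames set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix must have at least one gene and one cell")
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene and cell identifiers are required")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("dimension mismatch between matrix and ID lists")
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs")
  if (anyDuplicated(cell_ids)) stop("duplicate cell IDs")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0)) stop("negative expression values are not allowed")
  dimnames(values) <- list(gene_ids, cell_ids)
  class(values) <- c("expression_matrix", class(values))
  values
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d cells/spots\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Construct validated spatial coordinates
#'
#' @param xy numeric matrix/data.frame with two columns (x, y), one row per
#'   cell/spot. Units must be consistent with any distance threshold applied
#'   later (the platform's native units, typically micrometres).
#' @param cell_ids character vector of cell/spot identifiers.
#' @return an n x 2 numeric matrix of class `spatial_coords`, rownames set
#'   to the cell IDs.
#' @export
spatial_coords <- function(xy, cell_ids = rownames(xy)) {
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  if (ncol(xy) != 2L) stop("coordinates must have exactly two columns")
  if (is.null(cell_ids)) stop("cell IDs are required for coordinates")
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != nrow(xy))
    stop("one coordinate pair per cell ID is required")
  if (anyDuplicated(cell_ids)) stop("duplicate cell IDs in coordinates")
  if (anyNA(xy) || any(!is.finite(xy)))
    stop("non-finite coordinates")
  dimnames(xy) <- list(cell_ids, c("x", "y"))
  class(xy) <- c("spatial_coords", class(xy))
  xy
}

#' Construct validated cell-type labels
#'
#' @param labels character vector, one label per cell/spot.
#' @param cell_ids cell/spot identifiers (defaults to `names(labels)`).
#' @return a named character vector of class `cell_labels`.
#' @export
cell_labels <- function(labels, cell_ids = names(labels)) {
  labels <- as.character(labels)
  if (is.null(cell_ids)) stop("cell IDs are required for labels")
  cell_ids <- as.character(cell_ids)
  if (length(labels) != length(cell_ids))
    stop("every cell must have exactly one label")
  if (anyDuplicated(cell_ids)) stop("duplicate cell IDs in labels")
  if (anyNA(labels) || any(!nzchar(labels))) stop("empty cell-type label")
  names(labels) <- cell_ids
  class(labels) <- "cell_labels"
  labels
}

#' Construct a ligand-receptor interaction database
#'
#' Each record pairs one or more ligand subunits with one or more receptor
#' subunits (multimeric complexes are kept as subunit lists; expansion to
#' gene-level edges happens during gene-graph construction).
#'
#' @param ligand_subunits list of character vectors (>= 1 symbol each).
#' @param receptor_subunits list of character vectors (>= 1 symbol each).
#' @param annotation optional free-text annotation per record.
#' @return a data.frame of class `lr_database` with list columns
#'   `ligand_subunits`, `receptor_subunits` and character columns `ligand`,
#'   `receptor` (delimiter-joined for display) and `annotation`.
#' @export
lr_database <- function(ligand_subunits, receptor_subunits,
                        annotation = NULL) {
  ligand_subunits <- lapply(ligand_subunits, function(s) trimws(as.character(s)))
  receptor_subunits <- lapply(receptor_subunits, function(s) trimws(as.character(s)))
  if (length(ligand_subunits) != length(receptor_subunits))
    stop("ligand and receptor records must align")
  ok <- function(s) length(s) >= 1L && all(nzchar(s))
  if (!all(vapply(ligand_subunits, ok, logical(1))))
    stop("every record needs at least one non-empty ligand symbol")
  if (!all(vapply(receptor_subunits, ok, logical(1))))
    stop("every record needs at least one non-empty receptor symbol")
  n <- length(ligand_subunits)
  if (is.null(annotation)) annotation <- rep("", n)
  db <- data.frame(
    ligand = vapply(ligand_subunits, paste, character(1), collapse = "_"),
    receptor = vapply(receptor_subunits, paste, character(1), collapse = "_"),
    annotation = as.character(annotation),
    stringsAsFactors = FALSE
  )
  db$ligand_subunits <- ligand_subunits
  db$receptor_subunits <- receptor_subunits
  class(db) <- c("lr_database", class(db))
  db
}

#' Read an expression matrix from disk
#'
#' Supports dense delimited text (header row + leading ID column) and
#' Matrix Market sparse files with plain-text ID sidecar files. The on-disk
#' orientation is declared by the caller; the returned matrix is always
#' genes x cells.
#'
#' @param path path to the matrix file.
#' @param layout `"genes-in-rows"` (default) or `"cells-in-rows"`,
#'   describing the on-disk orientation.
#' @param format `"auto"` (by extension: `.mtx` is Matrix Market),
#'   `"delimited"` or `"matrix-market"`.
#' @param gene_id_file,cell_id_file for Matrix Market input: one ID per
#'   line, ordered as in the matrix.
#' @param sep field separator for delimited input (tab by default).
#' @return an [expression_matrix].
#' @export
read_expression <- function(path,
                            layout = c("genes-in-rows", "cells-in-rows"),
                            format = c("auto", "delimited", "matrix-market"),
                            gene_id_file = NULL, cell_id_file = NULL,
                            sep = "\t") {
  layout <- match.arg(layout)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "matrix-market" else "delimited"
  if (format == "matrix-market") {
    if (is.null(gene_id_file) || is.null(cell_id_file))
      stop("matrix-market input requires gene and cell ID sidecar files")
    if (!file.exists(gene_id_file)) stop("file not found: ", gene_id_file)
    if (!file.exists(cell_id_file)) stop("file not found: ", cell_id_file)
    vals <- as.matrix(Matrix::readMM(path))
    row_ids <- readLines(gene_id_file)
    col_ids <- readLines(cell_id_file)
    if (layout == "cells-in-rows") {
      vals <- t(vals)
    }
    if (nrow(vals) != length(row_ids) || ncol(vals) != length(col_ids))
      stop("dimension mismatch between matrix and ID lists")
    return(expression_matrix(vals, gene_ids = row_ids, cell_ids = col_ids))
  }
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, row.names = 1)
  vals <- as.matrix(tab)
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  if (layout == "cells-in-rows") vals <- t(vals)
  expression_matrix(vals)
}

#' Write an expression matrix to delimited text
#'
#' @param expr an [expression_matrix].
#' @param path output path.
#' @param layout on-disk orientation to write.
#' @param sep field separator.
#' @export
write_expression <- function(expr, path,
                             layout = c("genes-in-rows", "cells-in-rows"),
                             sep = "\t") {
  layout <- match.arg(layout)
  m <- unclass(expr)
  if (layout == "cells-in-rows") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- ""
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spatial coordinates
#'
#' Expects a delimited file with a header and columns cell ID, x, y.
#'
#' @param path input path.
#' @param cell_ids optional character vector; when supplied, every ID must
#'   be present in the file and rows are reordered to this order.
#' @param sep field separator.
#' @return a [spatial_coords] matrix.
#' @export
read_coordinates <- function(path, cell_ids = NULL, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("coordinate file needs cell, x, y columns")
  ids <- as.character(tab[[1]])
  xy <- as.matrix(tab[, 2:3])
  if (!is.numeric(xy)) stop("non-numeric coordinates in ", path)
  co <- spatial_coords(xy, cell_ids = ids)
  if (!is.null(cell_ids)) co <- reorder_coordinates(co, cell_ids)
  co
}

#' Reorder coordinates to a given cell-ID order
#'
#' @param coords a [spatial_coords] matrix.
#' @param cell_ids the requested order; all must be present.
#' @return [spatial_coords] with rows permuted to `cell_ids`.
#' @export
reorder_coordinates <- function(coords, cell_ids) {
  cell_ids <- as.character(cell_ids)
  missing <- setdiff(cell_ids, rownames(coords))
  if (length(missing))
    stop("coordinate missing for cell: ", paste(missing, collapse = ", "))
  spatial_coords(unclass(coords)[cell_ids, , drop = FALSE],
                 cell_ids = cell_ids)
}

#' Write spatial coordinates
#' @param coords a [spatial_coords] matrix.
#' @param path output path.
#' @param sep field separator.
#' @export
write_coordinates <- function(coords, path, sep = "\t") {
  df <- data.frame(cell = rownames(coords), x = coords[, 1], y = coords[, 2],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cell-type labels
#'
#' Delimited file with header and columns cell ID, label.
#' @param path input path.
#' @param sep field separator.
#' @return a [cell_labels] vector.
#' @export
read_cell_labels <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("label file needs cell and label columns")
  cell_labels(as.character(tab[[2]]), cell_ids = as.character(tab[[1]]))
}

#' Write cell-type labels
#' @param labels a [cell_labels] vector.
#' @param path output path.
#' @param sep field separator.
#' @export
write_cell_labels <- function(labels, path, sep = "\t") {
  df <- data.frame(cell = names(labels), label = as.character(unclass(labels)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a ligand-receptor interaction table
#'
#' Expects a delimited table with `ligand` and `receptor` columns (an
#' optional `annotation` column is carried through). Multimeric complexes
#' are encoded as delimiter-joined gene symbols (CellChatDB-style, e.g.
#' `"ITGA1_ITGB1"`) and retained here as subunit lists.
#'
#' @param path input path.
#' @param subunit_delimiter character splitting complex subunits; default
#'   `"_"`.
#' @param sep field separator.
#' @return an [lr_database].
#' @export
read_lr_database <- function(path, subunit_delimiter = "_", sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(tab))
  li <- match("ligand", nm); ri <- match("receptor", nm)
  if (is.na(li) || is.na(ri))
    stop("ligand-receptor table needs 'ligand' and 'receptor' columns")
  lig <- trimws(as.character(tab[[li]]))
  rec <- trimws(as.character(tab[[ri]]))
  if (any(is.na(lig) | !nzchar(lig))) stop("empty ligand field")
  if (any(is.na(rec) | !nzchar(rec))) stop("empty receptor field")
  ann <- if (!is.na(match("annotation", nm))) {
    as.character(tab[[match("annotation", nm)]])
  } else NULL
  lr_database(strsplit(lig, subunit_delimiter, fixed = TRUE),
              strsplit(rec, subunit_delimiter, fixed = TRUE),
              annotation = ann)
}

#' Write a ligand-receptor interaction table
#' @param db an [lr_database].
#' @param path output path.
#' @param sep field separator.
#' @export
write_lr_database <- function(db, path, sep = "\t") {
  df <- data.frame(ligand = db$ligand, receptor = db$receptor,
                   annotation = db$annotation, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a weighted directed edge list
#'
#' @param edges data.frame with columns `source`, `target`, `weight`.
#' @param path output path; a TSV with a header is written. An empty edge
#'   set produces a header-only file.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(edges)))
    stop("edge list needs source, target, weight columns")
  edges <- edges[, c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a weighted directed edge list written by [write_edge_list()]
#' @param path input path.
#' @return data.frame with columns `source`, `target`, `weight`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric"))
  names(tab) <- c("source", "target", "weight")
  tab
}
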