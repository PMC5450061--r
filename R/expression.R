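#' Construct an expression matrix
#'
#' The central container of the package: a genes x cells matrix of
#' non-negative abundances tagged with its unit (raw counts or CPM) and an
#' optional per-cell group label.
#'
#' @param values numeric matrix, genes in rows, cells in columns; rownames
#'   are gene ids and colnames are cell ids, both unique.
#' @param unit `"counts"` or `"CPM"`.
#' @param group optional character vector of per-cell labels, one per
#'   column (e.g. `"tumor"`, `"control"`).
#' @param zero_cells ids of cells whose columns were all zero when the
#'   matrix was normalized (kept all-zero, flagged here).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `unit`, `group`, `zero_cells`.
#' @export
expression_matrix <- function(values, unit = c("counts", "CPM"), group = NULL,
                              zero_cells = character()) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and cell colnames")
  if (anyDuplicated(rownames(values)))
    stop("gene ids are not unique")
  if (anyDuplicated(colnames(values)))
    stop("cell ids are not unique")
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (!is.null(group)) {
    if (length(group) != ncol(values))
      stop("group must have one label per cell")
    group <- stats::setNames(as.character(group), colnames(values))
  }
  structure(list(values = values, unit = unit, group = group,
                 zero_cells = zero_cells),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  if (!is.null(x$group))
    cat("groups:", paste(sprintf("%s=%d", names(table(x$group)),
                                 table(x$group)), collapse = ", "), "\n")
  if (length(x$zero_cells))
    cat("all-zero cells:", length(x$zero_cells), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from TSV or MatrixMarket files
#'
#' TSV layout: a header row of cell ids, then one row per gene with the
#' gene id in the first column.  An optional leading comment line
#' `#unit=CPM` declares the unit; otherwise values are taken as raw counts.
#' MTX layout: a MatrixMarket file plus one-id-per-line gene and cell name
#' files.  Duplicate gene rows are collapsed by summation and reported via
#' a message.
#'
#' @param path path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`.
#' @param genes_file,cells_file row/column name files (MTX only).
#' @param group optional per-cell group label (scalar or vector).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = c("tsv", "mtx"),
                            genes_file = NULL, cells_file = NULL,
                            group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    first <- readLines(path, n = 1L)
    unit <- if (grepl("^#\\s*unit\\s*=\\s*CPM", first, ignore.case = TRUE))
      "CPM" else "counts"
    nf <- utils::count.fields(path, sep = "\t", comment.char = "#")
    if (length(unique(nf)) > 1L) {
      bad <- which(nf != nf[1L])[1L]
      stop(sprintf("malformed expression TSV %s: line %d has %d fields, expected %d",
                   path, bad, nf[bad], nf[1L]))
    }
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             comment.char = "#")
    gene_ids <- as.character(tab[[1L]])
    values <- as.matrix(tab[, -1L, drop = FALSE])
    storage.mode(values) <- "double"
    if (anyDuplicated(gene_ids)) {
      ndup <- sum(duplicated(gene_ids))
      message(sprintf("collapsing %d duplicate gene row(s) by sum", ndup))
      values <- rowsum(values, gene_ids, reorder = FALSE)
      gene_ids <- rownames(values)
    }
    rownames(values) <- gene_ids
  } else {
    if (is.null(genes_file) || is.null(cells_file))
      stop("MTX input needs genes_file and cells_file")
    m <- Matrix::readMM(path)
    gene_ids <- readLines(genes_file)
    cell_ids <- readLines(cells_file)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(cell_ids))
      stop(sprintf("MTX dimensions %dx%d do not match name files (%d genes, %d cells)",
                   nrow(m), ncol(m), length(gene_ids), length(cell_ids)))
    values <- as.matrix(m)
    dimnames(values) <- list(gene_ids, cell_ids)
    if (anyDuplicated(gene_ids)) {
      message(sprintf("collapsing %d duplicate gene row(s) by sum",
                      sum(duplicated(gene_ids))))
      values <- rowsum(values, gene_ids, reorder = FALSE)
    }
    unit <- "counts"
  }
  if (!is.null(group) && length(group) == 1L)
    group <- rep(group, ncol(values))
  expression_matrix(values, unit = unit, group = group)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()] for the TSV layout; CPM matrices carry a
#' `#unit=CPM` comment line so the unit round-trips.  Values are written
#' with enough digits that reading the file back reproduces them exactly.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (m$unit == "CPM") writeLines("#unit=CPM", con)
  writeLines(paste(c("gene_id", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}

#' Normalize raw counts to counts per million
#'
#' Each cell column with nonzero total is scaled to sum to 1e6.  All-zero
#' columns are left untouched and recorded in the `zero_cells` field.
#' Calling on a matrix that is already CPM is a warning no-op.
#'
#' @param m an [expression_matrix()] with `unit = "counts"`.
#' @return the CPM-scaled [expression_matrix()].
#' @export
to_cpm <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit == "CPM") {
    warning("matrix is already CPM; returning unchanged")
    return(m)
  }
  totals <- colSums(m$values)
  zero <- totals == 0
  scale <- ifelse(zero, 1, 1e6 / totals)
  values <- sweep(m$values, 2L, scale, `*`)
  expression_matrix(values, unit = "CPM", group = unname(m$group),
                    zero_cells = colnames(m$values)[zero])
}

# internal: log2(CPM + 1) convenience used by clustering and markers
log2_cpm1 <- function(m) {
  stopifnot(m$unit == "CPM")
  log2(m$values + 1)
}
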