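#' Expression matrix container
#'
#' A genes x samples abundance matrix tagged with its unit. Values are
#' non-negative for `counts` and `fpkm`; `log2fpkm` values may be negative.
#' Gene and sample identifiers must be unique and are kept in order.
#'
#' @param values numeric matrix, genes as rows, samples as columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param unit one of `"counts"`, `"fpkm"`, `"log2fpkm"`.
#' @return an object of class `expr_matrix`: the matrix with a `unit`
#'   attribute.
#' @export
expression_matrix <- function(values, unit = c("fpkm", "counts", "log2fpkm")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("gene ids (rownames) are required", call. = FALSE)
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("sample ids (colnames) are required", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids", call. = FALSE)
  if (anyNA(values))
    stop("missing values are not allowed", call. = FALSE)
  if (unit != "log2fpkm" && nrow(values) > 0 && any(values < 0))
    stop(sprintf("negative values are invalid for unit '%s'", unit),
         call. = FALSE)
  structure(values, unit = unit, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, unit = %s\n",
              nrow(x), ncol(x), expr_unit(x)))
  if (nrow(x) > 0 && ncol(x) > 0) {
    show <- unclass(x)[seq_len(min(5L, nrow(x))), seq_len(min(5L, ncol(x))),
                       drop = FALSE]
    print(show, ...)
    if (nrow(x) > 5L || ncol(x) > 5L) cat("...\n")
  }
  invisible(x)
}

#' Unit tag of an expression matrix
#' @param x an `expr_matrix`
#' @return character scalar
#' @export
expr_unit <- function(x) attr(x, "unit", exact = TRUE)

# subsetting keeps class and unit; always a matrix (drop = FALSE semantics)
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  expression_matrix(out, unit = expr_unit(x))
}

#' Sample metadata sheet
#'
#' Per-sample metadata companion of an [expression_matrix()]: dataset id,
#' cell line, timepoint (or embryo stage) and replicate label.
#'
#' @param sample,dataset,cell_line,timepoint,replicate character vectors of
#'   equal length; `sample` must be unique.
#' @return data.frame of class `sample_sheet`
#' @export
sample_sheet <- function(sample, dataset, cell_line, timepoint, replicate) {
  df <- data.frame(sample = as.character(sample),
                   dataset = as.character(dataset),
                   cell_line = as.character(cell_line),
                   timepoint = as.character(timepoint),
                   replicate = as.character(replicate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids", call. = FALSE)
  class(df) <- c("sample_sheet", "data.frame")
  df
}

check_sheet_matches <- function(matrix, sheet) {
  if (!setequal(colnames(matrix), sheet$sample))
    stop("sample sheet does not match matrix columns", call. = FALSE)
  invisible(TRUE)
}

#' Read / write an expression matrix as TSV
#'
#' Tab-separated text, genes as rows; the first column holds gene ids, the
#' header holds sample ids. A read-after-write round trip reproduces ids
#' exactly and values to full precision.
#'
#' @param path file path
#' @param unit unit tag to attach on read
#' @return [read_expression()] returns an `expr_matrix`;
#'   [write_expression()] returns `path` invisibly.
#' @export
read_expression <- function(path, unit = c("fpkm", "counts", "log2fpkm")) {
  unit <- match.arg(unit)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 1) stop("malformed expression file", call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene ids in %s", path), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0 && !is.numeric(m))
    stop(sprintf("non-numeric or missing cells in %s", path), call. = FALSE)
  if (anyNA(m)) stop(sprintf("missing cells in %s", path), call. = FALSE)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  expression_matrix(m, unit = unit)
}

#' @rdname read_expression
#' @param matrix an `expr_matrix`
#' @export
write_expression <- function(matrix, path) {
  vals <- unclass(matrix)
  if (nrow(vals) == 0) {
    writeLines(paste(c("gene_id", colnames(vals)), collapse = "\t"), path)
    return(invisible(path))
  }
  # %.17g guarantees an exact double round trip through text
  txt <- matrix(sprintf("%.17g", vals), nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  df <- data.frame(gene_id = rownames(vals), txt,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", colnames(vals))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample sheet as TSV
#' @param path file path
#' @return a `sample_sheet` ([read_sample_sheet()]) or `path` invisibly.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("sample", "dataset", "cell_line", "timepoint", "replicate")
  if (!all(need %in% names(df)))
    stop(sprintf("sample sheet must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  sample_sheet(df$sample, df$dataset, df$cell_line, df$timepoint, df$replicate)
}

#' @rdname read_sample_sheet
#' @param sheet a `sample_sheet`
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Log2 transform of an FPKM matrix
#'
#' @param matrix an `expr_matrix` with unit `fpkm`
#' @param pseudocount positive real added before taking log2 (default 1)
#' @return an `expr_matrix` with unit `log2fpkm`
#' @export
to_log2 <- function(matrix, pseudocount = 1) {
  if (expr_unit(matrix) == "log2fpkm")
    stop("matrix is already log2-transformed", call. = FALSE)
  if (expr_unit(matrix) != "fpkm")
    stop("to_log2 expects unit 'fpkm'", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  out <- log2(unclass(matrix) + pseudocount)
  expression_matrix(out, unit = "log2fpkm")
}

#' Filter to expressed genes
#'
#' Keeps genes observed at or above `min_fpkm` in at least `min_samples`
#' samples, preserving row order. Idempotent.
#'
#' @param matrix an `expr_matrix` with unit `fpkm`
#' @param min_fpkm expression floor (default 1)
#' @param min_samples minimum number of samples at or above the floor
#'   (default 1)
#' @return filtered `expr_matrix`
#' @export
filter_expressed <- function(matrix, min_fpkm = 1, min_samples = 1L) {
  if (expr_unit(matrix) != "fpkm")
    stop("filter_expressed expects unit 'fpkm'", call. = FALSE)
  keep <- rowSums(unclass(matrix) >= min_fpkm) >= min_samples
  matrix[keep, , drop = FALSE]
}

#' Restrict two matrices to 1-to-1 orthologs
#'
#' Given expression matrices over two gene namespaces and a two-column
#' ortholog table (`gene_a`, `gene_b`), keeps only rows of the table that are
#' strictly one-to-one (a gene appearing more than once on either side drops
#' all of its rows) and whose genes are present in both matrices, and returns
#' the two matrices with rows aligned pairwise in identical order.
#'
#' @param matrix_a,matrix_b `expr_matrix` objects
#' @param ortholog_table data.frame with columns `gene_a`, `gene_b`
#' @return list with elements `a`, `b` (row-aligned `expr_matrix`) and
#'   `pairs` (the retained ortholog rows)
#' @export
harmonize_orthologs <- function(matrix_a, matrix_b, ortholog_table) {
  tab <- ortholog_table
  if (!all(c("gene_a", "gene_b") %in% names(tab)))
    stop("ortholog table needs columns gene_a, gene_b", call. = FALSE)
  tab$gene_a <- as.character(tab$gene_a)
  tab$gene_b <- as.character(tab$gene_b)
  one2one <- !(tab$gene_a %in% tab$gene_a[duplicated(tab$gene_a)]) &
             !(tab$gene_b %in% tab$gene_b[duplicated(tab$gene_b)])
  tab <- tab[one2one, , drop = FALSE]
  present <- tab$gene_a %in% rownames(matrix_a) &
             tab$gene_b %in% rownames(matrix_b)
  tab <- tab[present, , drop = FALSE]
  if (nrow(tab) == 0)
    stop(sprintf(paste0("no usable 1-to-1 ortholog pairs: %d table rows, ",
                        "%d genes in A, %d in B"),
                 nrow(ortholog_table), nrow(matrix_a), nrow(matrix_b)),
         call. = FALSE)
  list(a = matrix_a[tab$gene_a, , drop = FALSE],
       b = matrix_b[tab$gene_b, , drop = FALSE],
       pairs = tab)
}

#' Read / write gene sets in GMT format
#'
#' GMT is one set per line: name, description, then member genes, all
#' tab-separated.
#'
#' @param path file path
#' @return named list of character vectors; names are set names, the
#'   `description` attribute carries descriptions.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("malformed GMT line(s)", call. = FALSE)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors
#' @param descriptions optional character vector of set descriptions
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "description") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a two-column ortholog table as TSV
#' @param path file path
#' @return data.frame with columns `gene_a`, `gene_b`
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(df)))
    stop("ortholog table needs columns gene_a, gene_b", call. = FALSE)
  df[, c("gene_a", "gene_b")]
}

#' @rdname read_ortholog_table
#' @param table data.frame with columns `gene_a`, `gene_b`
#' @export
write_ortholog_table <- function(table, path) {
  utils::write.table(table[, c("gene_a", "gene_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
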