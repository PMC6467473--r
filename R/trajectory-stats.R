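#' Sample-sample Pearson correlation matrix
#'
#' Pairwise Pearson correlation between samples over the gene rows of a
#' log2-scale expression matrix. Zero-variance samples cannot be correlated;
#' their entries are set to NA and their ids reported in the
#' `flagged_samples` attribute.
#'
#' @param matrix `expr_matrix` with unit `log2fpkm`
#' @return symmetric correlation matrix (unit diagonal) of class
#'   `correlation_matrix`
#' @export
sample_correlation <- function(matrix) {
  if (expr_unit(matrix) != "log2fpkm")
    stop("sample_correlation expects unit 'log2fpkm'", call. = FALSE)
  if (ncol(matrix) < 2) stop("need >= 2 samples", call. = FALSE)
  x <- unclass(matrix)
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0
  r <- suppressWarnings(stats::cor(x))
  r[flat, ] <- NA_real_
  r[, flat] <- NA_real_
  diag(r) <- 1
  if (any(flat))
    warning(sprintf("%d zero-variance sample(s) flagged", sum(flat)),
            call. = FALSE)
  attr(r, "flagged_samples") <- colnames(x)[flat]
  class(r) <- c("correlation_matrix", "matrix", "array")
  r
}

#' Principal component analysis of samples
#'
#' Mean-centers each gene and computes sample scores by singular value
#' decomposition on log2-scale values of the chosen gene subset. Sign
#' convention: in every component the largest-magnitude gene loading is made
#' positive, so results are reproducible across platforms.
#'
#' @param matrix `expr_matrix` (`log2fpkm`, or `fpkm` which is
#'   log2(x+1)-transformed first)
#' @param gene_subset optional gene ids to restrict to (default all)
#' @param n_components number of components (default
#'   `min(genes, samples - 1)`)
#' @return object of class `pca_projection`: list with `scores`
#'   (samples x components), `loadings` (genes x components),
#'   `explained_variance` (fractions, non-increasing), `sdev`
#' @export
pca_project <- function(matrix, gene_subset = NULL, n_components = NULL) {
  x <- if (expr_unit(matrix) == "fpkm") unclass(to_log2(matrix))
       else unclass(matrix)
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) stop("empty gene subset", call. = FALSE)
    missing_g <- setdiff(gene_subset, rownames(x))
    if (length(missing_g))
      stop(sprintf("%d subset genes absent from matrix", length(missing_g)),
           call. = FALSE)
    x <- x[gene_subset, , drop = FALSE]
  }
  if (nrow(x) == 0) stop("empty gene subset", call. = FALSE)
  max_comp <- min(nrow(x), ncol(x) - 1L)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop("n_components exceeds min(genes, samples - 1)", call. = FALSE)

  xc <- x - rowMeans(x)
  sv <- svd(t(xc), nu = n_components, nv = n_components)
  total_var <- sum(sv$d^2)
  d <- sv$d[seq_len(n_components)]
  scores <- sv$u %*% diag(d, n_components)
  loadings <- sv$v
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  pcs <- paste0("PC", seq_len(n_components))
  dimnames(scores) <- list(colnames(x), pcs)
  dimnames(loadings) <- list(rownames(x), pcs)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = d^2 / total_var,
                 sdev = d / sqrt(max(1, ncol(x) - 1))),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("<pca_projection> %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = " "),
      "\n")
  invisible(x)
}

#' Joint PCA of a time course with a reference dataset
#'
#' Harmonizes the two matrices onto shared genes (through a 1-to-1 ortholog
#' table if given, by gene id intersection otherwise), concatenates the
#' samples and projects them together. The gene subset (e.g. time-course
#' variable genes, in A's namespace) is applied after harmonization.
#' Dataset of origin is carried in the `dataset` attribute of the scores.
#'
#' @param timecourse,reference `expr_matrix` objects (fpkm or log2fpkm, same
#'   unit)
#' @param ortholog_table optional data.frame with columns `gene_a` (time
#'   course) and `gene_b` (reference)
#' @param gene_subset optional gene ids (time-course namespace)
#' @param n_components number of components (default 3)
#' @return a `pca_projection`; `attr(scores, "dataset")` labels each sample
#'   `"timecourse"` or `"reference"`
#' @export
joint_projection <- function(timecourse, reference, ortholog_table = NULL,
                             gene_subset = NULL, n_components = 3) {
  if (expr_unit(timecourse) != expr_unit(reference))
    stop("units differ between datasets", call. = FALSE)
  if (!is.null(ortholog_table)) {
    h <- harmonize_orthologs(timecourse, reference, ortholog_table)
    a <- h$a; b <- h$b
    rownames(b) <- rownames(a)  # A namespace
  } else {
    shared <- intersect(rownames(timecourse), rownames(reference))
    if (length(shared) == 0) stop("no shared genes", call. = FALSE)
    a <- timecourse[shared, , drop = FALSE]
    b <- reference[shared, , drop = FALSE]
  }
  if (!is.null(gene_subset)) {
    gene_subset <- intersect(gene_subset, rownames(a))
    if (length(gene_subset) == 0)
      stop("gene subset does not intersect harmonized genes", call. = FALSE)
    a <- a[gene_subset, , drop = FALSE]
    b <- b[gene_subset, , drop = FALSE]
  }
  joint <- expression_matrix(cbind(unclass(a), unclass(b)),
                             unit = expr_unit(a))
  n_components <- min(n_components, nrow(joint), ncol(joint) - 1L)
  proj <- pca_project(joint, n_components = n_components)
  attr(proj$scores, "dataset") <- c(rep("timecourse", ncol(a)),
                                    rep("reference", ncol(b)))
  proj
}

#' Pairwise differential-expression counts between timepoints
#'
#' For every cell line and every pair of timepoints, counts the genes called
#' differentially expressed by [pairwise_de()] at the given thresholds.
#'
#' @param matrix `expr_matrix` (fpkm)
#' @param sheet companion `sample_sheet`
#' @param alpha,min_fc thresholds passed to [pairwise_de()]
#' @return named list (per cell line) of symmetric timepoint x timepoint
#'   count matrices with zero diagonal
#' @export
pairwise_variable_counts <- function(matrix, sheet, alpha = 0.01,
                                     min_fc = 2) {
  check_sheet_matches(matrix, sheet)
  out <- list()
  for (cl in unique(sheet$cell_line)) {
    sub <- sheet[sheet$cell_line == cl, , drop = FALSE]
    tps <- unique(sub$timepoint)
    counts <- matrix(0L, length(tps), length(tps),
                     dimnames = list(tps, tps))
    if (length(tps) >= 2) {
      for (i in seq_len(length(tps) - 1)) {
        for (j in seq.int(i + 1, length(tps))) {
          de <- pairwise_de(matrix, sheet,
                            sub$sample[sub$timepoint == tps[i]],
                            sub$sample[sub$timepoint == tps[j]],
                            alpha = alpha, min_fc = min_fc)
          counts[i, j] <- counts[j, i] <- nrow(de)
        }
      }
    }
    out[[cl]] <- counts
  }
  out
}
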