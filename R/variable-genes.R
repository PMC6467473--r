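#' Fit the CV-squared vs mean expression trend
#'
#' Computes, per gene, the linear-scale mean FPKM and squared coefficient of
#' variation across samples, then fits the standard mean-variability trend
#' for normalized expression,
#' \deqn{\log CV^2 = \log(a_1/\mu + a_0),}
#' by bounded nonlinear least squares over genes passing the expression floor.
#' The per-gene residual above the fitted curve (`excess`, natural-log scale)
#' quantifies variability beyond the technical trend.
#'
#' @param matrix an `expr_matrix` with unit `fpkm` and at least 3 samples
#' @param min_mean_fpkm floor on the per-gene mean for inclusion in the fit
#'   (default 0.1); all genes still receive fitted values and excess
#' @return object of class `cv2_fit`: list with coefficients `a0`, `a1` and a
#'   data.frame `table` (gene, mean_fpkm, mean_log2fpkm, cv2, log_cv2,
#'   fitted_log_cv2, excess)
#' @export
fit_cv2_trend <- function(matrix, min_mean_fpkm = 0.1) {
  if (expr_unit(matrix) != "fpkm")
    stop("fit_cv2_trend expects unit 'fpkm'", call. = FALSE)
  if (ncol(matrix) < 3)
    stop("need >= 3 samples to estimate CV", call. = FALSE)
  x <- unclass(matrix)
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  mu_f <- pmax(mu, 1e-6)  # floor before any log/ratio
  cv2 <- v / mu_f^2
  log_cv2 <- log(pmax(cv2, 1e-12))

  fit_idx <- which(mu >= min_mean_fpkm)
  if (length(fit_idx) < 10)
    stop("fewer than 10 genes pass the expression floor; cannot fit trend",
         call. = FALSE)
  df <- data.frame(mu = mu_f[fit_idx], y = log_cv2[fit_idx])
  a0_start <- stats::median(df$y)
  start <- list(a0 = exp(a0_start),
                a1 = max(stats::median(exp(df$y) * df$mu), 1e-8))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ log(a1 / mu + a0), data = df, start = start,
                      lower = c(a0 = 0, a1 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # coarse grid fallback on (log a0, log a1)
    grid <- expand.grid(a0 = exp(seq(-8, 3, length.out = 60)),
                        a1 = exp(seq(-8, 6, length.out = 60)))
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum((df$y - log(grid$a1[i] / df$mu + grid$a0[i]))^2)
    }, 0)
    co <- unlist(grid[which.min(sse), ])
  } else co <- stats::coef(fit)

  fitted_log_cv2 <- log(co[["a1"]] / mu_f + co[["a0"]])
  tab <- data.frame(gene = rownames(matrix),
                    mean_fpkm = mu,
                    mean_log2fpkm = log2(mu_f + 1),
                    cv2 = cv2,
                    log_cv2 = log_cv2,
                    fitted_log_cv2 = fitted_log_cv2,
                    excess = log_cv2 - fitted_log_cv2,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(a0 = co[["a0"]], a1 = co[["a1"]], table = tab,
                 n_fit = length(fit_idx)),
            class = "cv2_fit")
}

#' @export
print.cv2_fit <- function(x, ...) {
  cat(sprintf("<cv2_fit> log CV2 = log(%.4g/mu + %.4g), %d genes in fit\n",
              x$a1, x$a0, x$n_fit))
  invisible(x)
}

#' Select the most variable genes from a fitted CV-squared trend
#'
#' Applies thresholds along both axes of the CV2-vs-mean plot: a floor on
#' mean expression (x axis, log2 FPKM) and a floor on the residual above the
#' fitted trend (y axis, natural-log CV2 units). Ordered by descending
#' excess, ties broken by gene id.
#'
#' @param fit a `cv2_fit`
#' @param min_log2fpkm minimum per-gene mean log2(FPKM + 1) (default 1)
#' @param min_excess minimum log CV2 residual above the trend (default 1,
#'   i.e. CV2 at least e-fold above the fitted curve)
#' @return character vector of gene ids
#' @export
select_variable_genes <- function(fit, min_log2fpkm = 1, min_excess = 1) {
  tab <- fit$table
  keep <- tab$mean_log2fpkm >= min_log2fpkm & tab$excess >= min_excess
  sel <- tab[keep, , drop = FALSE]
  sel <- sel[order(-sel$excess, sel$gene), , drop = FALSE]
  sel$gene
}

# Welch t-test on a pair of numeric vectors with the degenerate-variance
# conventions: both variances zero and equal means -> p = 1; unequal means
# with zero pooled variance -> smallest positive double.
welch_p <- function(a, b) {
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else .Machine$double.xmin)
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df)
}

#' Pairwise differential expression between two sample groups
#'
#' Per-gene Welch t-test on log2(FPKM + 1) with Benjamini-Hochberg adjustment
#' across all tested genes. Fold change is computed on linear-scale group
#' means with a pseudocount of 1. Returns genes passing `padj < alpha` and
#' `|log2FC| > log2(min_fc)`. A hook (`p_values`) accepts externally computed
#' per-gene p-values (e.g. from a count-model engine) in place of the t-test.
#'
#' @param matrix an `expr_matrix` with unit `fpkm`
#' @param sheet companion `sample_sheet` (used only for validation; may be
#'   NULL)
#' @param group_a,group_b character vectors of sample ids, each with >= 2
#'   replicates
#' @param alpha adjusted-p cutoff (default 0.01)
#' @param min_fc minimum linear fold change (default 2)
#' @param p_values optional named numeric vector of per-gene p-values
#'   overriding the built-in test
#' @return object of class `de_gene_list`: data.frame (gene, log2fc, p, padj)
#'   restricted to significant genes, ordered by ascending p then gene id;
#'   the full table is in attribute `all_genes`
#' @export
pairwise_de <- function(matrix, sheet = NULL, group_a, group_b,
                        alpha = 0.01, min_fc = 2, p_values = NULL) {
  if (expr_unit(matrix) != "fpkm")
    stop("pairwise_de expects unit 'fpkm'", call. = FALSE)
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 replicates", call. = FALSE)
  missing <- setdiff(c(group_a, group_b), colnames(matrix))
  if (length(missing))
    stop(sprintf("unknown samples: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  xa <- unclass(matrix)[, group_a, drop = FALSE]
  xb <- unclass(matrix)[, group_b, drop = FALSE]
  la <- log2(xa + 1); lb <- log2(xb + 1)

  p <- if (!is.null(p_values)) {
    unname(p_values[rownames(matrix)])
  } else {
    vapply(seq_len(nrow(matrix)), function(g) welch_p(la[g, ], lb[g, ]), 0)
  }
  padj <- stats::p.adjust(p, method = "BH")
  log2fc <- log2((rowMeans(xa) + 1) / (rowMeans(xb) + 1))

  tab <- data.frame(gene = rownames(matrix), log2fc = log2fc, p = p,
                    padj = padj, stringsAsFactors = FALSE, row.names = NULL)
  sig <- tab[tab$padj < alpha & abs(tab$log2fc) > log2(min_fc), ,
             drop = FALSE]
  sig <- sig[order(sig$p, sig$gene), , drop = FALSE]
  attr(sig, "all_genes") <- tab
  class(sig) <- c("de_gene_list", "data.frame")
  sig
}

#' Union of time-course differential-expression gene lists
#'
#' Collects all genes differentially expressed between any two timepoints of
#' the time course in at least one cell line, at the stated thresholds
#' (default padj < 0.01, fold change > 2).
#'
#' @param matrix an `expr_matrix` with unit `fpkm`
#' @param sheet companion `sample_sheet`
#' @param alpha,min_fc thresholds passed to [pairwise_de()]
#' @return sorted character vector of gene ids (deduplicated union)
#' @export
timecourse_de_union <- function(matrix, sheet, alpha = 0.01, min_fc = 2) {
  check_sheet_matches(matrix, sheet)
  genes <- character(0)
  for (cl in unique(sheet$cell_line)) {
    sub <- sheet[sheet$cell_line == cl, , drop = FALSE]
    tps <- unique(sub$timepoint)
    if (length(tps) < 2) next
    for (i in seq_len(length(tps) - 1)) {
      for (j in seq.int(i + 1, length(tps))) {
        ga <- sub$sample[sub$timepoint == tps[i]]
        gb <- sub$sample[sub$timepoint == tps[j]]
        de <- pairwise_de(matrix, sheet, ga, gb, alpha = alpha,
                          min_fc = min_fc)
        genes <- c(genes, de$gene)
      }
    }
  }
  sort(unique(genes))
}
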