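#' Stage signature set
#'
#' Genes x stages matrix of per-stage mean expression (linear FPKM), the
#' basis for fractional-identity deconvolution.
#'
#' @param S numeric matrix, genes as rows, stages as columns, with dimnames
#' @return object of class `signature_set`
#' @export
signature_set <- function(S) {
  S <- as.matrix(S)
  if (is.null(colnames(S)) || anyDuplicated(colnames(S)))
    stop("stage labels must be present and unique", call. = FALSE)
  if (nrow(S) > 0 && any(rowSums(abs(S)) == 0))
    stop("signature matrix contains an all-zero gene row", call. = FALSE)
  structure(list(S = S, stages = colnames(S), genes = rownames(S)),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d genes x %d stages (%s)\n",
              nrow(x$S), ncol(x$S), paste(x$stages, collapse = ", ")))
  invisible(x)
}

#' Build per-stage expression signatures from a reference dataset
#'
#' The signature of a stage is the arithmetic mean expression over the
#' reference cells annotated to that stage (sheet `timepoint` column),
#' restricted to the requested genes. All-zero gene rows are dropped with a
#' message.
#'
#' @param reference `expr_matrix` (linear FPKM) of reference cells
#' @param sheet companion `sample_sheet`; the `timepoint` column holds stages
#' @param stages stages to include, in order
#' @param genes optional gene subset (default: all reference genes)
#' @return a [signature_set()]
#' @export
build_signatures <- function(reference, sheet, stages, genes = NULL) {
  check_sheet_matches(reference, sheet)
  if (is.null(genes)) genes <- rownames(reference)
  missing_g <- setdiff(genes, rownames(reference))
  if (length(missing_g))
    stop(sprintf("%d requested genes absent from reference",
                 length(missing_g)), call. = FALSE)
  x <- unclass(reference)[genes, , drop = FALSE]
  S <- vapply(stages, function(s) {
    cells <- sheet$sample[sheet$timepoint == s]
    if (length(cells) == 0)
      stop(sprintf("stage '%s' has no reference cells", s), call. = FALSE)
    rowMeans(x[, cells, drop = FALSE])
  }, numeric(length(genes)))
  if (length(genes) == 1) S <- matrix(S, 1, length(stages),
                                      dimnames = list(genes, stages))
  zero <- rowSums(abs(S)) == 0
  if (any(zero)) {
    message(sprintf("dropping %d all-zero signature rows", sum(zero)))
    S <- S[!zero, , drop = FALSE]
  }
  signature_set(S)
}

# Primal active-set solver for  min ||S f - x||^2  s.t.  sum(f) = 1, f >= 0.
# KKT-exact: on the working set the equality-constrained subproblem is
# solved exactly; constraints are added at blocking points and released by
# the most negative multiplier.
qp_simplex_ls <- function(S, x, tol = 1e-10, max_iter = NULL) {
  k <- ncol(S)
  Q <- crossprod(S)
  cvec <- -as.vector(crossprod(S, x))
  if (is.null(max_iter)) max_iter <- 50L * k + 50L
  f <- rep(1 / k, k)
  active <- rep(FALSE, k)
  nonunique <- FALSE
  scale_ref <- max(1, max(abs(Q)))

  solve_sub <- function(free) {
    nf <- length(free)
    K <- rbind(cbind(Q[free, free, drop = FALSE], rep(1, nf)),
               c(rep(1, nf), 0))
    rhs <- c(-cvec[free], 1)
    rc <- rcond(K)
    if (!is.finite(rc) || rc < 1e-12) {
      nonunique <<- TRUE
      K[seq_len(nf), seq_len(nf)] <-
        K[seq_len(nf), seq_len(nf)] + diag(1e-10 * scale_ref, nf)
    }
    solve(K, rhs)
  }

  lambda <- 0
  for (it in seq_len(max_iter)) {
    free <- which(!active)
    sol <- solve_sub(free)
    f_new <- rep(0, k)
    f_new[free] <- sol[seq_along(free)]
    lambda <- sol[length(free) + 1L]
    if (all(f_new[free] >= -tol)) {
      f <- pmax(f_new, 0)
      f <- f / sum(f)
      if (!any(active)) break
      mu <- (as.vector(Q %*% f) + cvec + lambda)[active]
      if (all(mu >= -tol * scale_ref)) break
      release <- which(active)[which.min(mu)]
      active[release] <- FALSE
    } else {
      d <- f_new - f
      ratio <- rep(Inf, k)
      shrink <- d < -1e-15
      ratio[shrink] <- f[shrink] / -d[shrink]
      alpha <- min(1, ratio)
      f <- f + alpha * d
      block <- which.min(ratio)
      active[block] <- TRUE
      f[block] <- 0
      f <- pmax(f, 0)
      f <- f / sum(f)
    }
  }
  resid <- as.vector(S %*% f - x)
  list(f = f, objective = sum(resid^2),
       residual_norm = sqrt(sum(resid^2)), nonunique = nonunique,
       iterations = it)
}

#' Fractional identity of one sample
#'
#' Decomposes an expression vector into stage fractions by
#' simplex-constrained least squares: minimizes \eqn{\|S f - x\|_2^2} subject
#' to \eqn{f \ge 0} and \eqn{\sum f = 1}, solved exactly by a primal
#' active-set quadratic program with the sum-to-one equality enforced (not
#' penalized). The solution is unique when the signatures are linearly
#' independent on the active set; rank deficiency is flagged, not fatal.
#'
#' @param S a [signature_set()] (or genes x stages matrix)
#' @param x named numeric vector of sample expression, aligned to (or
#'   alignable by name with) the signature genes
#' @return object of class `fraction_profile`: list with `fractions` (named,
#'   on the simplex), `residual_norm`, `objective`, `nonunique`
#' @export
solve_fractions <- function(S, x) {
  Sm <- if (inherits(S, "signature_set")) S$S else as.matrix(S)
  if (ncol(Sm) < 1) stop("need at least one stage", call. = FALSE)
  if (nrow(Sm) < ncol(Sm))
    stop("need at least as many genes as stages", call. = FALSE)
  if (!is.null(names(x)) && !is.null(rownames(Sm))) {
    if (!all(rownames(Sm) %in% names(x)))
      stop("sample vector does not cover the signature genes", call. = FALSE)
    x <- x[rownames(Sm)]
  }
  if (length(x) != nrow(Sm))
    stop("sample vector length does not match signature rows", call. = FALSE)
  sol <- qp_simplex_ls(Sm, as.numeric(x))
  structure(list(fractions = stats::setNames(sol$f, colnames(Sm)),
                 residual_norm = sol$residual_norm,
                 objective = sol$objective,
                 nonunique = sol$nonunique),
            class = "fraction_profile")
}

#' @export
print.fraction_profile <- function(x, ...) {
  cat("<fraction_profile>",
      paste(sprintf("%s=%.4f", names(x$fractions), x$fractions),
            collapse = " "),
      sprintf(" (residual %.4g)\n", x$residual_norm))
  invisible(x)
}

#' Stage fractions along a time course
#'
#' Solves [solve_fractions()] for every sample, then averages replicate
#' fractions per timepoint (with standard deviation). Deconvolution operates
#' on the genes shared between the time course and the signature set.
#'
#' @param timecourse `expr_matrix` (linear FPKM)
#' @param sheet companion `sample_sheet`
#' @param S a [signature_set()]
#' @param cell_line optional cell line to subset to
#' @return list with `per_sample` (data.frame sample, timepoint, one column
#'   per stage, residual) and `per_timepoint` (tidy data.frame timepoint,
#'   stage, mean_fraction, sd_fraction), timepoints in sheet order
#' @export
identity_timecourse <- function(timecourse, sheet, S, cell_line = NULL) {
  if (!is.null(cell_line))
    sheet <- sheet[sheet$cell_line == cell_line, , drop = FALSE]
  sheet <- sheet[sheet$sample %in% colnames(timecourse), , drop = FALSE]
  genes <- intersect(rownames(timecourse), S$genes)
  if (length(genes) < length(S$stages))
    stop("too few shared genes for deconvolution", call. = FALSE)
  Sm <- signature_set(S$S[genes, , drop = FALSE])
  x <- unclass(timecourse)[genes, , drop = FALSE]

  per_sample <- do.call(rbind, lapply(sheet$sample, function(sm) {
    fp <- solve_fractions(Sm, x[, sm])
    out <- data.frame(sample = sm,
                      timepoint = sheet$timepoint[sheet$sample == sm],
                      t(fp$fractions), residual = fp$residual_norm,
                      stringsAsFactors = FALSE, check.names = FALSE)
    out
  }))
  tps <- unique(sheet$timepoint)
  per_tp <- do.call(rbind, lapply(tps, function(tp) {
    sub <- per_sample[per_sample$timepoint == tp, S$stages, drop = FALSE]
    data.frame(timepoint = tp, stage = S$stages,
               mean_fraction = colMeans(sub),
               sd_fraction = apply(sub, 2, stats::sd),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  per_tp$timepoint <- factor(per_tp$timepoint, levels = tps)
  list(per_sample = per_sample, per_timepoint = per_tp)
}
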