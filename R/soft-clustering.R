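#' Standardize temporal expression profiles
#'
#' Collapses replicates to per-timepoint means (within one dataset/cell line;
#' subset the matrix or pass `cell_line`), then standardizes each gene's
#' profile to mean 0 and standard deviation 1 across timepoints. Genes with
#' zero variance across timepoints carry no dynamic information and are
#' dropped (their count is reported in a warning and in the `n_dropped`
#' attribute).
#'
#' @param matrix an `expr_matrix` (log2 scale recommended) or numeric matrix
#' @param sheet companion `sample_sheet`
#' @param cell_line optional cell-line label to subset to
#' @return numeric matrix genes x timepoints of standardized profiles, with
#'   attributes `timepoints` and `n_dropped`
#' @export
standardize_profiles <- function(matrix, sheet, cell_line = NULL) {
  if (!is.null(cell_line)) {
    keep <- sheet$cell_line == cell_line
    sheet <- sheet[keep, , drop = FALSE]
  }
  sheet <- sheet[sheet$sample %in% colnames(matrix), , drop = FALSE]
  tps <- unique(sheet$timepoint)
  if (length(tps) < 2) stop("need >= 2 timepoints", call. = FALSE)
  x <- unclass(matrix)[, sheet$sample, drop = FALSE]
  prof <- vapply(tps, function(tp) {
    rowMeans(x[, sheet$sample[sheet$timepoint == tp], drop = FALSE])
  }, numeric(nrow(x)))
  if (nrow(x) == 1) prof <- matrix(prof, 1, length(tps),
                                   dimnames = list(rownames(x), tps))
  colnames(prof) <- tps
  mu <- rowMeans(prof)
  sdv <- apply(prof, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat))
    warning(sprintf("%d zero-variance profile(s) dropped", sum(flat)),
            call. = FALSE)
  prof <- (prof - mu) / sdv
  out <- prof[!flat, , drop = FALSE]
  attr(out, "timepoints") <- tps
  attr(out, "n_dropped") <- sum(flat)
  out
}

# one fuzzy c-means run from a fixed initial centroid matrix;
# returns memberships consistent with the returned centroids
fcm_run <- function(x, centroids, m, tol, max_iter) {
  memb_from_centroids <- function(x, centroids, m) {
    d2 <- outer(rowSums(x^2), rep(1, nrow(centroids))) -
      2 * x %*% t(centroids) +
      outer(rep(1, nrow(x)), rowSums(centroids^2))
    d2 <- pmax(d2, 0)
    zero <- d2 < 1e-300
    # normalize by the per-gene minimum distance before the -1/(m-1) power:
    # the ratio keeps the largest weight at exactly 1, so small fuzzifiers
    # (m -> 1) underflow the far clusters instead of overflowing the near one
    dmin <- pmax(apply(d2, 1, min), 1e-300)
    w <- (d2 / dmin)^(-1 / (m - 1))
    u <- w / rowSums(w)
    hit <- rowSums(zero) > 0  # coincident with >=1 centroid: limit convention
    if (any(hit)) {
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    }
    list(u = u, d2 = d2)
  }
  j_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    md <- memb_from_centroids(x, centroids, m)
    j_trace <- c(j_trace, sum(md$u^m * md$d2))
    um <- md$u^m
    new_c <- (t(um) %*% x) / colSums(um)
    shift <- max(abs(new_c - centroids))
    centroids <- new_c
    if (shift < tol) break
  }
  md <- memb_from_centroids(x, centroids, m)
  j_final <- sum(md$u^m * md$d2)
  list(u = md$u, centroids = centroids, d2 = md$d2,
       objective = j_final, j_trace = c(j_trace, j_final),
       iterations = iter)
}

#' Fuzzy c-means soft clustering of standardized profiles
#'
#' The classic fuzzy c-means algorithm with Euclidean distance: memberships
#' \eqn{u_{gc} = (\sum_j (d_{gc}/d_{gj})^{2/(m-1)})^{-1}} and centroids
#' \eqn{c_c = \sum_g u_{gc}^m x_g / \sum_g u_{gc}^m} are alternated until the
#' largest centroid shift drops below `tol`. The objective
#' \eqn{J = \sum_{g,c} u_{gc}^m d_{gc}^2} is non-increasing across
#' iterations. Initialization samples `k` distinct genes as starting
#' centroids; with `n_starts > 1` the run with the lowest final objective
#' wins. A gene coinciding exactly with a centroid takes membership 1 there
#' (limit convention). Hard assignments are the membership argmax, ties
#' broken by lowest cluster index.
#'
#' @param profiles numeric matrix genes x timepoints (see
#'   [standardize_profiles()])
#' @param k number of clusters (2 <= k <= number of genes)
#' @param m fuzzifier, > 1 (default 1.25)
#' @param tol convergence tolerance on the centroid shift
#' @param max_iter iteration cap per start
#' @param seed integer seed for centroid initialization
#' @param n_starts number of random restarts (default 10)
#' @param init optional k x timepoints matrix of initial centroids; if given,
#'   a single run from exactly this initialization is performed
#' @return object of class `membership_matrix`: list with `membership`
#'   (genes x k), `centroids` (k x timepoints), `hard` (named integer
#'   vector), `objective`, `j_trace` (objective per iteration of the winning
#'   run), `k`, `m`, `labels` (NULL until [label_clusters()])
#' @export
fuzzy_cmeans <- function(profiles, k, m = 1.25, tol = 1e-9, max_iter = 500,
                         seed = 1, n_starts = 10, init = NULL) {
  x <- unclass(profiles)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(x)) stop("k exceeds the number of genes", call. = FALSE)
  if (m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)

  runs <- if (!is.null(init)) {
    stopifnot(nrow(init) == k, ncol(init) == ncol(x))
    list(fcm_run(x, as.matrix(init), m, tol, max_iter))
  } else {
    lapply(seq_len(n_starts), function(s) {
      idx <- with_seed(seed + s - 1L, sample(nrow(x), k))
      fcm_run(x, x[idx, , drop = FALSE], m, tol, max_iter)
    })
  }
  best <- runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]

  u <- best$u
  rownames(u) <- rownames(x)
  colnames(u) <- paste0("c", seq_len(k))
  hard <- apply(u, 1, which.max)  # which.max takes the lowest index on ties
  centroids <- best$centroids
  rownames(centroids) <- colnames(u)
  colnames(centroids) <- colnames(x)
  structure(list(membership = u, centroids = centroids,
                 hard = stats::setNames(as.integer(hard), rownames(x)),
                 objective = best$objective, j_trace = best$j_trace,
                 hard_wss = sum(best$d2[cbind(seq_len(nrow(u)), hard)]),
                 k = k, m = m, labels = NULL),
            class = "membership_matrix")
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat(sprintf("<membership_matrix> %d genes, k = %d, m = %.3g, J = %.6g\n",
              nrow(x$membership), x$k, x$m, x$objective))
  cat("cluster sizes (hard):",
      paste(tabulate(x$hard, x$k), collapse = " "), "\n")
  if (!is.null(x$labels))
    cat("labels:", paste(sprintf("%d=%s", seq_len(x$k), x$labels),
                         collapse = " "), "\n")
  invisible(x)
}

#' Choose the number of clusters by the elbow method
#'
#' For each k in `k_range`, runs multi-start fuzzy c-means and records the
#' hard within-cluster sum of squared distances J(k): the mean over starts
#' and the best single start. The selected k maximizes the second difference
#' of log J over the best-of-start curve,
#' log J(k-1) - 2 log J(k) + log J(k+1) — the sharpest *relative* flattening
#' of the decrease. (On the raw J scale the curvature of any steeply
#' decreasing convex curve peaks at the smallest k regardless of structure;
#' the log scale locates the elbow where the proportional gain collapses.)
#' When no clear elbow exists (max log-scale second difference < 0.25 —
#' structureless noise clouds sit an order of magnitude below this, planted
#' cluster structure an order of magnitude above) the result carries a
#' low-confidence flag.
#'
#' @param profiles standardized profile matrix
#' @param k_range integer vector of candidate k (>= 3 values)
#' @param m fuzzifier
#' @param seed integer seed
#' @param n_starts restarts per k
#' @param tol convergence tolerance passed to [fuzzy_cmeans()]
#' @return list with `k` (selected), `table` (k, j_mean, j_best),
#'   `low_confidence` (logical)
#' @export
elbow_select_k <- function(profiles, k_range = 2:9, m = 1.25, seed = 1,
                           n_starts = 10, tol = 1e-7) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3)
    stop("k_range needs at least 3 values (no interior point otherwise)",
         call. = FALSE)
  if (min(k_range) < 2 || max(k_range) > nrow(profiles) - 1)
    stop("k_range must lie within [2, genes - 1]", call. = FALSE)

  per_k <- lapply(k_range, function(k) {
    js <- vapply(seq_len(n_starts), function(s) {
      mm <- fuzzy_cmeans(profiles, k, m = m, seed = seed + (s - 1L) * 1000L,
                         n_starts = 1, tol = tol)
      mm$hard_wss
    }, 0)
    c(j_mean = mean(js), j_best = min(js))
  })
  tab <- data.frame(k = k_range,
                    j_mean = vapply(per_k, `[[`, 0, "j_mean"),
                    j_best = vapply(per_k, `[[`, 0, "j_best"))
  d2 <- diff(log(pmax(tab$j_best, 1e-300)), differences = 2)
  best_i <- which.max(d2)
  low_conf <- max(d2) < 0.25
  list(k = tab$k[best_i + 1L], table = tab, low_confidence = low_conf)
}

# time (in ordinal units) at which a profile first completes half of its
# net start-to-end change
half_change_time <- function(x) {
  total <- x[length(x)] - x[1]
  which(abs(x - x[1]) >= 0.5 * abs(total))[1]
}

#' Label the five temporal clusters semantically
#'
#' Assigns the archetype names of [archetype_labels()] to the k = 5 centroids
#' by their geometry: the centroid whose largest excursion from the midpoint
#' of its endpoints is interior, and whose net start-to-end change is less
#' than half its range, is the transient (`up_n_dn`) cluster; the remaining
#' four split by the sign of the net change into down- and up-regulated
#' pairs, and within each pair the centroid reaching half of its total change
#' earlier is `early`, the other `late`.
#'
#' @param mm a `membership_matrix` with k = 5
#' @return the `membership_matrix` with `labels` filled in (character vector
#'   indexed by cluster)
#' @export
label_clusters <- function(mm) {
  if (mm$k != 5)
    stop("semantic labelling is defined for k = 5", call. = FALSE)
  ce <- mm$centroids
  nt <- ncol(ce)
  delta <- ce[, nt] - ce[, 1]
  rng <- apply(ce, 1, function(x) max(x) - min(x))
  mid <- (ce[, 1] + ce[, nt]) / 2
  exc_idx <- vapply(seq_len(5), function(i)
    which.max(abs(ce[i, ] - mid[i])), 0L)
  candidate <- exc_idx > 1 & exc_idx < nt & abs(delta) < 0.5 * rng
  if (sum(candidate) == 0)
    stop("no transient (up_n_dn) candidate among the centroids",
         call. = FALSE)
  if (sum(candidate) > 1)
    stop(sprintf(
      "ambiguous geometry: clusters %s all qualify as up_n_dn",
      paste(which(candidate), collapse = ", ")), call. = FALSE)
  labels <- rep(NA_character_, 5)
  labels[candidate] <- "up_n_dn"
  rest <- which(!candidate)
  down <- rest[delta[rest] < 0]
  up <- rest[delta[rest] > 0]
  if (length(down) != 2 || length(up) != 2)
    stop(sprintf(
      "ambiguous geometry: %d down and %d up monotone centroids (need 2 + 2)",
      length(down), length(up)), call. = FALSE)
  t_half <- vapply(seq_len(5), function(i) half_change_time(ce[i, ]), 0L)
  labels[down[order(t_half[down])]] <- c("early_down", "late_down")
  labels[up[order(t_half[up])]] <- c("early_up", "late_up")
  mm$labels <- labels
  mm
}

#' Hypergeometric gene-set enrichment per cluster
#'
#' For every (hard cluster, gene set) pair, computes the one-sided
#' hypergeometric upper-tail probability of the observed overlap, restricted
#' to the given gene universe, with Benjamini-Hochberg adjustment across all
#' pairs.
#'
#' @param mm a `membership_matrix`
#' @param gene_sets named list of character vectors (see [read_gmt()])
#' @param universe character vector containing at least all clustered genes
#' @return data.frame (cluster, set, n_cluster, n_set, overlap, p, padj)
#' @export
cluster_set_enrichment <- function(mm, gene_sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  clustered <- names(mm$hard)
  if (!all(clustered %in% universe))
    stop("universe must contain all clustered genes", call. = FALSE)
  N <- length(universe)
  rows <- list()
  for (cl in seq_len(mm$k)) {
    members <- intersect(clustered[mm$hard == cl], universe)
    n <- length(members)
    for (s in names(gene_sets)) {
      set_u <- intersect(gene_sets[[s]], universe)
      K <- length(set_u)
      ov <- length(intersect(members, set_u))
      p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, set = s, n_cluster = n, n_set = K,
                   overlap = ov, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out
}
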