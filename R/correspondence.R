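#' Cluster grouping schemes for "similar" clusters
#'
#' A scheme groups cluster ids of two datasets into direction classes
#' (downregulated / upregulated). Two genes in different clusters still count
#' as "similar" when both clusters fall in the same group. Two presets are
#' shipped, matching the two published comparisons:
#' \describe{
#'   \item{`hpsc_vs_hpsc`}{within-hPSC comparison: downregulated = clusters
#'     {1, 2} on both sides; upregulated = clusters {4, 5} on both sides; the
#'     transient cluster 3 belongs to no group.}
#'   \item{`embryo_vs_hpsc`}{embryo (side A) vs hPSC (side B): downregulated
#'     = embryo {1, 2} and hPSC {1, 2}; upregulated = embryo {3, 4, 5} and
#'     hPSC {4, 5} (embryo cluster-3 genes stay above their starting level,
#'     so they group with the upregulated clusters; hPSC cluster 3 returns
#'     to baseline and belongs to no group).}
#' }
#'
#' @param name preset name, or a custom scheme via `groups`
#' @param groups named list; each element is `list(a = <cluster ids in A>,
#'   b = <cluster ids in B>)`
#' @return object of class `cluster_scheme`
#' @export
cluster_scheme <- function(name, groups = NULL) {
  if (is.null(groups)) {
    groups <- switch(name,
      hpsc_vs_hpsc = list(down = list(a = c(1, 2), b = c(1, 2)),
                          up = list(a = c(4, 5), b = c(4, 5))),
      embryo_vs_hpsc = list(down = list(a = c(1, 2), b = c(1, 2)),
                            up = list(a = c(3, 4, 5), b = c(4, 5))),
      stop(sprintf("unknown scheme preset '%s'", name), call. = FALSE))
  }
  for (side in c("a", "b")) {
    all_ids <- unlist(lapply(groups, `[[`, side))
    if (anyDuplicated(all_ids))
      stop("a cluster may appear in at most one group per dataset",
           call. = FALSE)
  }
  structure(list(name = name, groups = groups), class = "cluster_scheme")
}

# all permutations of 1..n (n <= 9 guarded by caller)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

#' Match cluster ids between two clusterings
#'
#' Finds the bijection between the cluster ids of two `membership_matrix`
#' objects (equal k) that maximizes the total Pearson correlation of matched
#' centroids — the assignment-problem optimum, found exactly by permutation
#' search (k <= 9). If the two datasets have different numbers of timepoints,
#' B's centroids are linearly interpolated onto A's normalized time axis.
#' When both objects carry semantic labels, label identity defines the
#' mapping and a warning is raised if it disagrees with the correlation
#' optimum.
#'
#' @param mm_a,mm_b `membership_matrix` objects with equal k
#' @return list with `map` (integer vector: `map[j]` is the A cluster
#'   matched to B cluster j), `mean_correlation` of matched centroid pairs,
#'   and `low_confidence` (TRUE when that mean correlation < 0.5)
#' @export
match_cluster_ids <- function(mm_a, mm_b) {
  if (mm_a$k != mm_b$k)
    stop("cluster counts differ between datasets", call. = FALSE)
  k <- mm_a$k
  if (k > 9) stop("exact matching supports k <= 9", call. = FALSE)
  ca <- mm_a$centroids
  cb <- mm_b$centroids
  if (ncol(cb) != ncol(ca)) {
    ta <- seq(0, 1, length.out = ncol(ca))
    tb <- seq(0, 1, length.out = ncol(cb))
    cb <- t(apply(cb, 1, function(y) stats::approx(tb, y, xout = ta)$y))
  }
  cors <- stats::cor(t(ca), t(cb))  # cors[i, j] = cor(A centroid i, B j)
  perms <- all_perms(k)
  scores <- apply(perms, 1, function(p) sum(cors[cbind(p, seq_len(k))]))
  best <- perms[which.max(scores), ]
  map <- as.integer(best)  # map[j] = A cluster for B cluster j
  mean_cor <- mean(cors[cbind(map, seq_len(k))])

  if (!is.null(mm_a$labels) && !is.null(mm_b$labels)) {
    label_map <- match(mm_b$labels, mm_a$labels)
    if (anyNA(label_map))
      stop("label sets differ between datasets", call. = FALSE)
    if (!identical(as.integer(label_map), map))
      warning("semantic-label mapping disagrees with centroid-correlation optimum; using labels",
              call. = FALSE)
    map <- as.integer(label_map)
    mean_cor <- mean(cors[cbind(map, seq_len(k))])
  }
  list(map = map, mean_correlation = mean_cor,
       low_confidence = mean_cor < 0.5)
}

#' Fractions of genes in the same and similar clusters
#'
#' For each shared gene, compares its cluster in dataset A with its cluster
#' in dataset B: `same` when the B cluster (translated through `mapping`)
#' equals the A cluster; otherwise `similar` when the A cluster and the
#' (untranslated) B cluster fall in the same scheme group; otherwise
#' `neither`. Fractions are taken over the genes present in both
#' assignments; genes missing from either side are excluded and tallied.
#'
#' @param assign_a,assign_b named vectors gene -> cluster id
#' @param scheme a [cluster_scheme()]
#' @param shared_genes genes to compare
#' @param mapping optional integer vector translating B cluster ids to A
#'   cluster ids (`map` from [match_cluster_ids()]); default identity
#' @return object of class `correspondence_result`: list with counts,
#'   fractions and a per-gene verdict data.frame
#' @export
correspondence_fractions <- function(assign_a, assign_b, scheme,
                                     shared_genes, mapping = NULL) {
  genes <- unique(shared_genes)
  present <- genes[genes %in% names(assign_a) & genes %in% names(assign_b)]
  n_dropped <- length(genes) - length(present)
  a <- as.integer(assign_a[present])
  b <- as.integer(assign_b[present])
  if (is.null(mapping)) mapping <- seq_len(max(c(a, b, 1)))
  b_in_a <- mapping[b]

  group_of <- function(ids, side) {
    out <- rep(NA_character_, length(ids))
    for (g in names(scheme$groups))
      out[ids %in% scheme$groups[[g]][[side]]] <- g
    out
  }
  same <- b_in_a == a
  ga <- group_of(a, "a")
  gb <- group_of(b, "b")
  similar <- !same & !is.na(ga) & !is.na(gb) & ga == gb
  verdict <- ifelse(same, "same", ifelse(similar, "similar", "neither"))

  n <- length(present)
  res <- list(
    n_compared = n,
    n_same = sum(same),
    n_similar = sum(similar),
    n_neither = sum(!same & !similar),
    n_dropped = n_dropped,
    frac_same = if (n > 0) sum(same) / n else NA_real_,
    frac_same_or_similar = if (n > 0) (sum(same) + sum(similar)) / n
                           else NA_real_,
    scheme = scheme$name,
    verdicts = data.frame(gene = present, cluster_a = a, cluster_b = b,
                          cluster_b_mapped = b_in_a, verdict = verdict,
                          stringsAsFactors = FALSE))
  class(res) <- "correspondence_result"
  res
}

#' @export
print.correspondence_result <- function(x, ...) {
  cat(sprintf("<correspondence_result> scheme = %s, n = %d\n",
              x$scheme, x$n_compared))
  if (x$n_compared > 0)
    cat(sprintf("  same: %d (%.1f%%)   same-or-similar: %d (%.1f%%)   neither: %d\n",
                x$n_same, 100 * x$frac_same, x$n_same + x$n_similar,
                100 * x$frac_same_or_similar, x$n_neither))
  else cat("  no genes compared (fractions undefined)\n")
  if (x$n_dropped > 0)
    cat(sprintf("  dropped (absent from an assignment): %d\n", x$n_dropped))
  invisible(x)
}

#' Renumber hard assignments into canonical semantic order
#'
#' The shipped grouping schemes refer to the published cluster numbering
#' (1 = early_down, 2 = late_down, 3 = up_n_dn, 4 = early_up, 5 = late_up).
#' This renumbers a labelled clustering's hard assignments so cluster id i
#' means the i-th archetype of [archetype_labels()].
#'
#' @param mm a `membership_matrix` with `labels` set (see [label_clusters()])
#' @return named integer vector gene -> canonical cluster id
#' @export
canonical_assignments <- function(mm) {
  if (is.null(mm$labels))
    stop("clustering carries no semantic labels; run label_clusters() first",
         call. = FALSE)
  canon <- match(mm$labels, archetype_labels())
  stats::setNames(canon[mm$hard], names(mm$hard))
}

#' Cross-species cluster correspondence through 1-to-1 orthologs
#'
#' Restricts the two clusterings to strictly 1-to-1 ortholog pairs, matches
#' cluster ids by centroid correlation (or semantic labels), and computes
#' same / same-or-similar fractions under the given scheme. The comparison
#' universe is the genes clustered in both species after ortholog filtering.
#'
#' @param mm_a,mm_b `membership_matrix` objects for species A and B
#' @param ortholog_table data.frame with columns `gene_a`, `gene_b`
#' @param scheme a [cluster_scheme()]
#' @return a `correspondence_result` (gene ids in A's namespace), with the
#'   cluster `mapping` attached
#' @export
cross_species_correspondence <- function(mm_a, mm_b, ortholog_table, scheme) {
  tab <- ortholog_table
  one2one <- !(tab$gene_a %in% tab$gene_a[duplicated(tab$gene_a)]) &
             !(tab$gene_b %in% tab$gene_b[duplicated(tab$gene_b)])
  tab <- tab[one2one, , drop = FALSE]
  tab <- tab[tab$gene_a %in% names(mm_a$hard) &
             tab$gene_b %in% names(mm_b$hard), , drop = FALSE]
  if (nrow(tab) == 0)
    stop("no 1-to-1 ortholog pairs clustered in both species", call. = FALSE)
  matching <- match_cluster_ids(mm_a, mm_b)
  if (!is.null(mm_a$labels) && !is.null(mm_b$labels)) {
    # semantic labels pin both sides to the published numbering, which is
    # also what the shipped schemes are written in
    assign_a <- canonical_assignments(mm_a)
    hb <- canonical_assignments(mm_b)
    mapping <- seq_len(mm_a$k)
  } else {
    assign_a <- mm_a$hard
    hb <- mm_b$hard
    mapping <- matching$map
  }
  # express B's assignment in A's gene namespace
  assign_b <- stats::setNames(as.integer(hb[tab$gene_b]), tab$gene_a)
  res <- correspondence_fractions(assign_a, assign_b, scheme,
                                  shared_genes = tab$gene_a,
                                  mapping = mapping)
  res$mapping <- matching
  res
}
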