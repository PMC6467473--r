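archetype_centroids <- function(nt = 6) {
  t_norm <- seq(0, 1, length.out = nt)
  t(sapply(archetype_labels(), function(a) {
    s <- capacitrack:::archetype_shape(a, t_norm)
    (s - mean(s)) / sd(s)
  }))
}

mk_mm <- function(centroids, hard = NULL, labels = NULL) {
  structure(list(membership = NULL, centroids = unname(centroids),
                 hard = hard, k = nrow(centroids), labels = labels),
            class = "membership_matrix")
}

test_that("cluster matching recovers identity and planted permutations", {
  ce <- archetype_centroids()
  mm_a <- mk_mm(ce)
  expect_equal(match_cluster_ids(mm_a, mm_a)$map, 1:5)

  perm <- c(3, 5, 1, 2, 4)  # B cluster j holds A's centroid perm[j]
  mm_b <- mk_mm(ce[perm, ])
  res <- match_cluster_ids(mm_a, mm_b)
  expect_equal(res$map, perm)
  expect_false(res$low_confidence)

  # differing timepoint axes: B on 11 points, interpolated
  mm_b11 <- mk_mm(archetype_centroids(11)[perm, ])
  expect_equal(match_cluster_ids(mm_a, mm_b11)$map, perm)

  # anti-correlated centroids: two rising shapes in A, their negations in B
  # (negating the full archetype set would map down- onto up-shapes instead)
  rise1 <- scale(as.numeric(1:6))[, 1]
  rise2 <- scale(sqrt(1:6))[, 1]
  mm_r <- mk_mm(rbind(rise1, rise2))
  res_anti <- match_cluster_ids(mm_r, mk_mm(rbind(-rise1, -rise2)))
  expect_true(res_anti$low_confidence)
  expect_length(res_anti$map, 2)

  mm4 <- mk_mm(ce[1:4, ])
  expect_error(match_cluster_ids(mm_a, mm4), "differ")
})

test_that("label identity overrides and warns when it disagrees with correlation", {
  ce <- archetype_centroids()
  mm_a <- mk_mm(ce, labels = archetype_labels())
  mm_b <- mk_mm(ce[c(2, 1, 3, 4, 5), ],
                labels = archetype_labels()[c(2, 1, 3, 4, 5)])
  expect_silent(res <- match_cluster_ids(mm_a, mm_b))
  expect_equal(res$map, c(2L, 1L, 3L, 4L, 5L))
  # deliberately wrong labels on b: correlation optimum disagrees
  mm_b_bad <- mk_mm(ce, labels = archetype_labels()[c(2, 1, 3, 4, 5)])
  expect_warning(res_bad <- match_cluster_ids(mm_a, mm_b_bad), "disagrees")
  expect_equal(res_bad$map, c(2L, 1L, 3L, 4L, 5L))  # labels win
})

test_that("correspondence fractions reproduce the hand-counted example", {
  assign_a <- stats::setNames(c(1L, 2L, 4L, 5L, 3L), paste0("g", 1:5))
  assign_b <- stats::setNames(c(1L, 4L, 5L, 5L, 3L), paste0("g", 1:5))
  res <- correspondence_fractions(assign_a, assign_b,
                                  cluster_scheme("hpsc_vs_hpsc"),
                                  paste0("g", 1:5))
  expect_equal(res$n_compared, 5L)
  expect_equal(res$n_same, 3L)
  expect_equal(res$frac_same, 0.6)
  expect_equal(res$frac_same_or_similar, 0.8)
  # gene2 (2 vs 4): different groups; gene3 (4 vs 5): both upregulated
  expect_equal(res$verdicts$verdict,
               c("same", "neither", "similar", "same", "same"))
  expect_equal(res$n_same + res$n_similar + res$n_neither, res$n_compared)
})

test_that("correspondence handles drops, empty input, and dataset swap", {
  assign_a <- stats::setNames(c(1L, 2L, 4L), paste0("g", 1:3))
  assign_b <- stats::setNames(c(1L, 4L), paste0("g", 1:2))
  sc <- cluster_scheme("hpsc_vs_hpsc")
  res <- correspondence_fractions(assign_a, assign_b, sc, paste0("g", 1:3))
  expect_equal(res$n_compared, 2L)
  expect_equal(res$n_dropped, 1L)

  empty <- correspondence_fractions(assign_a, assign_b, sc, character(0))
  expect_equal(empty$n_compared, 0L)
  expect_true(is.na(empty$frac_same))

  # identical assignments: 100% same
  full <- correspondence_fractions(assign_a, assign_a, sc, paste0("g", 1:3))
  expect_equal(full$frac_same, 1)

  # symmetry: swapping datasets (with identity mapping, mirrored scheme)
  a <- stats::setNames(sample(1:5, 50, replace = TRUE), paste0("g", 1:50))
  b <- stats::setNames(sample(1:5, 50, replace = TRUE), paste0("g", 1:50))
  r_ab <- correspondence_fractions(a, b, sc, names(a))
  r_ba <- correspondence_fractions(b, a, sc, names(a))
  expect_equal(r_ab$frac_same, r_ba$frac_same)
  expect_equal(r_ab$frac_same_or_similar, r_ba$frac_same_or_similar)
})

test_that("fractions are invariant under consistent cluster renumbering", {
  ce <- archetype_centroids()
  set.seed(7)
  genes <- paste0("g", 1:200)
  a_hard <- stats::setNames(sample(1:5, 200, replace = TRUE), genes)
  b_hard <- a_hard
  flip <- sample(200, 60)  # 30% of genes moved to a random other cluster
  b_hard[flip] <- ((b_hard[flip] + sample(1:4, 60, replace = TRUE) - 1) %% 5) + 1
  mm_a <- mk_mm(ce, hard = a_hard)
  base <- correspondence_fractions(a_hard, b_hard,
                                   cluster_scheme("hpsc_vs_hpsc"), genes)

  # renumber B's clusters by a permutation; matching absorbs it
  perm <- c(3, 5, 1, 2, 4)
  inv <- order(perm)
  b_renum <- stats::setNames(inv[b_hard], genes)
  mm_b_renum <- mk_mm(ce[perm, ], hard = b_renum)
  m <- match_cluster_ids(mm_a, mm_b_renum)
  # scheme groups expressed in B's new numbering
  sc_renum <- cluster_scheme("custom", groups = list(
    down = list(a = c(1, 2), b = inv[c(1, 2)]),
    up = list(a = c(4, 5), b = inv[c(4, 5)])))
  renum <- correspondence_fractions(a_hard, b_renum, sc_renum, genes,
                                    mapping = m$map)
  expect_equal(renum$frac_same, base$frac_same)
  expect_equal(renum$frac_same_or_similar, base$frac_same_or_similar)
})

test_that("cross-species correspondence composes harmonization, matching and counting", {
  # species B constructed as a relabeled ortholog copy of A
  tc <- generate_timecourse(300, 300, noise_cv = 0.15, seed = 31,
                            n_cell_lines = 1)
  prof <- standardize_profiles(to_log2(tc$matrix), tc$sheet)
  mm_a <- fuzzy_cmeans(prof, 5, seed = 1)
  genes_b <- paste0("X_", rownames(prof))
  prof_b <- prof
  rownames(prof_b) <- genes_b
  mm_b <- fuzzy_cmeans(prof_b, 5, seed = 5)
  orth <- data.frame(gene_a = rownames(prof), gene_b = genes_b)
  res <- cross_species_correspondence(mm_a, mm_b, orth,
                                      cluster_scheme("hpsc_vs_hpsc"))
  expect_gte(res$frac_same, 0.99)

  # many-to-one rows are excluded from the universe
  orth_decoy <- rbind(orth,
                      data.frame(gene_a = rownames(prof)[1],
                                 gene_b = "X_decoy"))
  res2 <- cross_species_correspondence(mm_a, mm_b, orth_decoy,
                                       cluster_scheme("hpsc_vs_hpsc"))
  expect_equal(res2$n_compared, res$n_compared - 1L)
})

test_that("scheme presets encode the two published groupings and validate", {
  sc1 <- cluster_scheme("hpsc_vs_hpsc")
  expect_equal(sc1$groups$down$a, c(1, 2))
  expect_equal(sc1$groups$up$b, c(4, 5))
  sc2 <- cluster_scheme("embryo_vs_hpsc")
  expect_equal(sc2$groups$up$a, c(3, 4, 5))
  expect_equal(sc2$groups$up$b, c(4, 5))
  expect_error(cluster_scheme("nope"), "unknown")
  expect_error(cluster_scheme("bad", groups = list(
    g1 = list(a = 1:2, b = 1), g2 = list(a = 2:3, b = 2))), "at most one")
})
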