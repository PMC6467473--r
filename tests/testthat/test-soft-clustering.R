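std_profiles <- function(seed = 3, n = 200, noise = 0.2) {
  tc <- generate_timecourse(n, n, noise_cv = noise, seed = seed,
                            n_cell_lines = 1)
  list(prof = standardize_profiles(to_log2(tc$matrix), tc$sheet),
       truth = tc$truth)
}

test_that("profile standardization centers, scales, and drops flat genes", {
  vals <- rbind(g1 = c(1, 1, 2, 2, 8, 8),   # replicates of 3 timepoints
                g2 = c(4, 4, 4, 4, 4, 4),   # flat -> dropped
                g3 = 3 * c(1, 1, 2, 2, 8, 8) + 11)  # affine copy of g1
  colnames(vals) <- paste0("s", 1:6)
  sheet <- sample_sheet(colnames(vals), "d", "line1",
                        rep(c("0", "1", "2"), each = 2),
                        rep(c("r1", "r2"), 3))
  expect_warning(prof <- standardize_profiles(vals, sheet), "1 zero-variance")
  expect_equal(rownames(prof), c("g1", "g3"))
  expect_equal(unname(rowMeans(prof)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(prof, 1, sd)), c(1, 1), tolerance = 1e-12)
  # affine invariance
  expect_equal(prof["g1", ], prof["g3", ], tolerance = 1e-12)
})

test_that("fuzzy c-means matches an independent oracle from a fixed init", {
  # 6 hand-placed points in 2 tight groups
  x <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1),
             c(3, 3), c(3.1, 3), c(3, 2.9))
  rownames(x) <- paste0("p", 1:6)
  init <- x[c(1, 4), ]
  mm <- fuzzy_cmeans(x, 2, m = 1.25, tol = 1e-12, max_iter = 500,
                     init = init)
  orc <- oracle_fcm(x, init, m = 1.25, tol = 1e-12, max_iter = 500)
  expect_lt(max(abs(mm$membership - orc$u)), 1e-8)
  expect_lt(max(abs(mm$centroids - orc$centroids)), 1e-8)
  # group structure recovered
  expect_equal(unname(mm$hard), c(1L, 1L, 1L, 2L, 2L, 2L))
})

test_that("fuzzy c-means memberships satisfy their invariants", {
  sp <- std_profiles()
  mm <- fuzzy_cmeans(sp$prof, 5, seed = 1)
  expect_true(all(abs(rowSums(mm$membership) - 1) < 1e-9))
  expect_true(all(mm$membership >= 0 & mm$membership <= 1))
  # objective non-increasing across iterations of the winning run
  expect_true(all(diff(mm$j_trace) <= 1e-8 * max(1, mm$j_trace[1])))
  # identical genes get identical membership rows
  x2 <- rbind(sp$prof[1:20, ], dup = sp$prof[1, ])
  mm2 <- fuzzy_cmeans(x2, 3, seed = 2)
  expect_equal(unname(mm2$membership["dup", ]),
               unname(mm2$membership[1, ]), tolerance = 1e-9)
  # a gene coinciding with a centroid takes membership 1 there
  y <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5), d = c(5, 5))
  mm3 <- fuzzy_cmeans(y, 2, init = rbind(c(0, 0), c(5, 5)))
  expect_equal(max(mm3$membership["a", ]), 1)
  expect_error(fuzzy_cmeans(sp$prof, nrow(sp$prof) + 1), "exceeds")
})

test_that("near-hard fuzzifier approaches k-means memberships", {
  sp <- std_profiles(seed = 6, n = 250)
  mm <- fuzzy_cmeans(sp$prof, 5, m = 1.01, seed = 1)
  expect_gte(mean(apply(mm$membership, 1, max) >= 0.99), 0.99)
})

test_that("implementation agrees with the e1071 reference on a fixed dataset", {
  skip_if_not_installed("e1071")
  sp <- std_profiles(seed = 10, n = 150, noise = 0.1)
  mm <- fuzzy_cmeans(sp$prof, 5, m = 1.25, seed = 4, n_starts = 10)
  cm <- e1071::cmeans(sp$prof, centers = 5, m = 1.25, iter.max = 500)
  # same partition up to cluster relabelling: compare co-clustering
  ours <- outer(mm$hard, mm$hard, "==")
  theirs <- outer(cm$cluster, cm$cluster, "==")
  expect_gte(mean(ours == theirs), 0.98)
})

test_that("semantic labels recover planted archetypes and their symmetries", {
  t_norm <- seq(0, 1, length.out = 6)
  centroids <- t(sapply(archetype_labels(), function(a) {
    s <- capacitrack:::archetype_shape(a, t_norm)
    (s - mean(s)) / sd(s)
  }))
  mk_mm <- function(ce) {
    structure(list(membership = NULL, centroids = ce, hard = NULL, k = 5,
                   labels = NULL), class = "membership_matrix")
  }
  shuf <- c(4, 1, 5, 2, 3)
  mm <- mk_mm(centroids[shuf, ])
  labs <- label_clusters(mm)$labels
  expect_identical(labs, archetype_labels()[shuf])
  # sign flip swaps up<->down and preserves timing
  labs_f <- label_clusters(mk_mm(-centroids))$labels
  expect_identical(labs_f, c("early_up", "late_up", "up_n_dn",
                             "early_down", "late_down"))
  # monotone-decreasing centroid completing its change by timepoint 2 of 6
  # is early_down (here: the flipped early_up archetype)
  expect_identical(labs_f[4], "early_down")
  expect_error(label_clusters(mk_mm(centroids[c(1, 2, 3, 3, 5), ])),
               "ambiguous|up_n_dn")
  mm4 <- mk_mm(centroids[1:4, ]); mm4$k <- 4
  expect_error(label_clusters(mm4), "k = 5")
})

test_that("full pipeline recovers planted clusters at the stated noise", {
  tc <- generate_timecourse(1000, 1000, noise_cv = 0.2, seed = 3,
                            n_cell_lines = 1)
  prof <- standardize_profiles(to_log2(tc$matrix), tc$sheet)
  mm <- label_clusters(fuzzy_cmeans(prof, 5, m = 1.25, seed = 1,
                                    n_starts = 10))
  agreement <- mean(mm$labels[mm$hard] ==
                    tc$truth$gene_archetype[names(mm$hard)])
  expect_gte(agreement, 0.95)
})

test_that("hypergeometric enrichment matches exact summation", {
  universe <- sprintf("u%02d", 1:20)
  mm <- structure(list(
    membership = NULL, k = 2,
    hard = stats::setNames(c(rep(1L, 4), rep(2L, 6)), universe[1:10]),
    labels = NULL), class = "membership_matrix")
  sets <- list(S1 = universe[c(1, 2, 3, 11, 12)],   # overlap 3 with cluster 1
               S2 = universe[15:18])                # disjoint from cluster 1
  enr <- cluster_set_enrichment(mm, sets, universe)
  r11 <- enr[enr$cluster == 1 & enr$set == "S1", ]
  expect_equal(r11$overlap, 3)
  expect_equal(r11$p, oracle_hyper_upper(3, 5, 20, 4), tolerance = 1e-12)
  expect_equal(r11$p, (choose(5, 3) * choose(15, 1) +
                       choose(5, 4) * choose(15, 0)) / choose(20, 4),
               tolerance = 1e-12)
  # disjoint set: P(X >= 0) = 1
  expect_equal(enr[enr$cluster == 1 & enr$set == "S2", "p"], 1)
  # cluster equal to the set: minimal p among same-size sets
  sets3 <- list(exact = universe[1:4], other = universe[5:8],
                mixed = universe[c(1, 5, 6, 7)])
  enr3 <- cluster_set_enrichment(mm, sets3, universe)
  p1 <- enr3[enr3$cluster == 1, ]
  expect_equal(p1$p[p1$set == "exact"], min(p1$p))
  expect_error(cluster_set_enrichment(mm, sets, character(0)), "universe")
})

test_that("elbow criterion needs an interior point and flags structureless data", {
  sp <- std_profiles(seed = 4, n = 60)
  expect_error(elbow_select_k(sp$prof, 2:3), "at least 3")
  one_arch <- sp$prof[names(which(sp$truth$gene_archetype == "early_up")), ]
  eb <- elbow_select_k(one_arch, 2:6, seed = 1, n_starts = 4)
  expect_true(eb$low_confidence)
  # J(k) best-of-starts is non-increasing
  expect_true(all(diff(eb$table$j_best) <= 1e-8))
})
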