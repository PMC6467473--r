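test_that("time-course generator books dimensions and archetypes correctly", {
  tc <- generate_timecourse(100, 50, n_replicates = 3, n_cell_lines = 2,
                            noise_cv = 0.1, seed = 1)
  expect_equal(dim(tc$matrix), c(100L, 36L))
  counts <- table(tc$truth$gene_archetype)
  expect_equal(unname(counts[archetype_labels()]), rep(10L, 5),
               ignore_attr = TRUE)
  expect_equal(unname(counts[["background"]]), 50L)
  expect_equal(nrow(tc$sheet), 36L)
  expect_setequal(tc$sheet$sample, colnames(tc$matrix))
})

test_that("zero noise reproduces archetype means exactly and seeds are pure", {
  tc0 <- generate_timecourse(60, 30, noise_cv = 0, seed = 5)
  m <- unclass(tc0$matrix)
  sheet <- tc0$sheet
  # all replicates of a (cell line, timepoint) identical
  for (tp in unique(sheet$timepoint)) {
    cols <- sheet$sample[sheet$timepoint == tp & sheet$cell_line == "line1"]
    expect_true(all(m[, cols] == m[, cols[1]]))
  }
  # and equal to 2^(planted log2 means)
  expect_equal(m[, sheet$sample[1]],
               2^tc0$truth$log2_means[, sheet$timepoint[1]],
               ignore_attr = TRUE)
  tc_a <- generate_timecourse(60, 30, noise_cv = 0.2, seed = 9)
  tc_b <- generate_timecourse(60, 30, noise_cv = 0.2, seed = 9)
  expect_identical(unclass(tc_a$matrix), unclass(tc_b$matrix))
  expect_error(generate_timecourse(0, 0), "positive")
  expect_error(generate_timecourse(10, 20), "exceed")
})

test_that("planted archetypes are mutually recoverable after standardization", {
  tc0 <- generate_timecourse(50, 50, noise_cv = 0, seed = 3,
                             n_cell_lines = 1)
  prof <- standardize_profiles(to_log2(tc0$matrix), tc0$sheet)
  t_norm <- seq(0, 1, length.out = 6)
  centroids <- t(sapply(archetype_labels(), function(a) {
    s <- capacitrack:::archetype_shape(a, t_norm)
    (s - mean(s)) / sd(s)
  }))
  for (g in rownames(prof)) {
    cors <- apply(centroids, 1, function(ce) cor(prof[g, ], ce))
    expect_equal(names(which.max(cors)),
                 unname(tc0$truth$gene_archetype[g]))
  }
})

test_that("stage reference plants signatures that noiseless means reproduce", {
  ref <- generate_stage_reference(120, stages = c("A", "B", "C", "D"),
                                  cells_per_stage = 20, noise_cv = 0,
                                  seed = 2)
  expect_equal(nrow(ref$sheet), 80L)
  expect_equal(unname(table(ref$sheet$timepoint)), rep(20L, 4),
               ignore_attr = TRUE)
  means <- sapply(c("A", "B", "C", "D"), function(st) {
    rowMeans(unclass(ref$matrix)[, ref$sheet$sample[ref$sheet$timepoint == st],
                                 drop = FALSE])
  })
  expect_equal(means, ref$signatures, ignore_attr = TRUE)
  # degenerate separation: all stage means identical
  ref0 <- generate_stage_reference(50, stages = c("A", "B"),
                                   cells_per_stage = 3, separation = 0,
                                   noise_cv = 0, seed = 2)
  expect_equal(ref0$signatures[, 1], ref0$signatures[, 2])
})

test_that("mixture generator reproduces exact mixtures and validates input", {
  ref <- generate_stage_reference(80, stages = c("S1", "S2", "S3"),
                                  cells_per_stage = 2, noise_cv = 0, seed = 4)
  S <- ref$signatures
  mix <- generate_mixtures(S, list(c(1, 0, 0), c(0.2, 0.3, 0.5)),
                           noise_cv = 0, seed = 1)
  expect_equal(unclass(mix$matrix)[, 1], S[, 1], ignore_attr = TRUE)
  expect_equal(unclass(mix$matrix)[, 2],
               as.vector(S %*% c(0.2, 0.3, 0.5)), ignore_attr = TRUE)
  # column-average symmetry for an equal two-stage mixture
  mix2 <- generate_mixtures(S[, 1:2], list(c(0.5, 0.5)), noise_cv = 0,
                            seed = 1)
  expect_equal(unclass(mix2$matrix)[, 1], rowMeans(S[, 1:2]),
               ignore_attr = TRUE)
  expect_error(generate_mixtures(S, list(c(0.5, 0.2, 0.2))), "simplex")
  expect_error(generate_mixtures(S, list(c(-0.1, 0.6, 0.5))), "simplex")
})

test_that("ortholog map plants a recoverable bijective fraction", {
  ga <- sprintf("ha%03d", 1:100)
  gb <- sprintf("mb%03d", 1:100)
  full <- generate_ortholog_map(ga, gb, frac_one_to_one = 1, seed = 1)
  expect_equal(nrow(full), 100L)
  expect_false(anyDuplicated(full$gene_a) > 0)
  expect_false(anyDuplicated(full$gene_b) > 0)

  part <- generate_ortholog_map(ga, gb, frac_one_to_one = 0.8, seed = 2)
  keep <- !(part$gene_a %in% part$gene_a[duplicated(part$gene_a)]) &
          !(part$gene_b %in% part$gene_b[duplicated(part$gene_b)])
  expect_equal(sum(keep), 80L)

  empty <- generate_ortholog_map(character(0), character(0), 0.5, seed = 1)
  expect_equal(nrow(empty), 0L)
})

test_that("gene-set generator writes GMT and plants detectable enrichment", {
  tc <- generate_timecourse(200, 100, noise_cv = 0.1, seed = 6,
                            n_cell_lines = 1)
  genes <- rownames(tc$matrix)
  sets <- generate_gene_sets(genes, n_sets = 3, set_size = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_length(readLines(path), 3L)
  back <- read_gmt(path)
  expect_identical(lapply(back, identity), lapply(sets, identity),
                   ignore_attr = TRUE)
  expect_true(all(lengths(back) == 10))
  # determinism
  sets2 <- generate_gene_sets(genes, n_sets = 3, set_size = 10, seed = 1)
  expect_identical(sets[[2]], sets2[[2]])

  # the enriched set's hypergeometric p against its archetype beats uniform
  enr <- generate_gene_sets(genes, n_sets = 4, set_size = 15,
                            enriched_cluster = "early_up",
                            gene_archetype = tc$truth$gene_archetype,
                            seed = 3)
  arch_genes <- names(which(tc$truth$gene_archetype == "early_up"))
  p_of <- function(set) {
    ov <- length(intersect(set, arch_genes))
    oracle_hyper_upper(ov, length(arch_genes), length(genes), length(set))
  }
  p_enriched <- p_of(enr[[1]])
  p_uniform <- sapply(enr[-1], p_of)
  expect_true(all(p_enriched < p_uniform))
  expect_gte(length(intersect(enr[[1]], arch_genes)) / 15, 0.8)
})
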