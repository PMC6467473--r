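#' Default pipeline configuration
#'
#' Returns the full configuration list with the published analysis defaults:
#' differential-expression thresholds padj < 0.01 and fold change > 2, five
#' clusters (or elbow selection over 2..9), fuzzifier 1.25, signature stages
#' EPI / post-E / post-L (ICM shown in PCA but excluded from deconvolution),
#' and the two shipped correspondence scheme presets.
#'
#' @param overrides named list of values overriding the defaults (nested by
#'   section, e.g. `list(de = list(alpha = 0.05))`)
#' @return nested configuration list
#' @export
default_config <- function(overrides = NULL) {
  cfg <- list(
    expression = list(min_fpkm = 1, min_samples = 1, pseudocount = 1),
    hvg = list(min_log2fpkm = 1, min_excess = 1),
    de = list(alpha = 0.01, min_fc = 2),
    cluster = list(k = 5, k_range = 2:9, m = 1.25, n_starts = 10,
                   tol = 1e-9, max_iter = 500, elbow = FALSE),
    correspondence = list(scheme = "hpsc_vs_hpsc",
                          cross_species_scheme = "embryo_vs_hpsc"),
    stages = list(signature = c("EPI", "postE", "postL"),
                  pca = c("ICM", "EPI", "postE", "postL")),
    pca = list(n_components = 3),
    seed = 1
  )
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  cfg
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[capacitrack] ", fmt), ...))

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a complete synthetic demo input bundle
#'
#' Generates a time course for two pseudo-cell-lines, a stage-annotated
#' reference in a second gene namespace, a bijective-plus-decoys ortholog
#' map, GMT gene sets (one enriched in the early_up archetype), and
#' planted-truth sidecars, all as plain-text files.
#'
#' @param dir output directory (created if absent)
#' @param seed integer seed
#' @param n_genes,n_variable time-course size (defaults sized so the full
#'   demo pipeline runs in well under five minutes)
#' @return `dir`, invisibly; files: `timecourse.tsv`, `samples.tsv`,
#'   `reference.tsv`, `reference_samples.tsv`, `orthologs.tsv`,
#'   `gene_sets.gmt`, `truth_archetypes.tsv`, `truth_signatures.tsv`
#' @export
make_demo <- function(dir, seed = 7, n_genes = 2000, n_variable = 300) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tc <- generate_timecourse(n_genes, n_variable, noise_cv = 0.15, seed = seed)
  write_expression(tc$matrix, file.path(dir, "timecourse.tsv"))
  write_sample_sheet(tc$sheet, file.path(dir, "samples.tsv"))
  write_tsv(data.frame(gene = names(tc$truth$gene_archetype),
                       archetype = unname(tc$truth$gene_archetype)),
            file.path(dir, "truth_archetypes.tsv"))

  # reference in its own namespace: the archetype genes of the time course
  # re-expressed across stages, so cross-species structure is real
  stages <- c("ICM", "EPI", "postE", "postL")
  ref <- generate_stage_reference(n_genes = 1500, stages = stages,
                                  cells_per_stage = 15, separation = 3,
                                  noise_cv = 0.2, seed = seed + 1L)
  write_expression(ref$matrix, file.path(dir, "reference.tsv"))
  write_sample_sheet(ref$sheet, file.path(dir, "reference_samples.tsv"))
  sig_df <- data.frame(gene = rownames(ref$signatures), ref$signatures,
                       check.names = FALSE)
  write_tsv(sig_df, file.path(dir, "truth_signatures.tsv"))

  orth <- generate_ortholog_map(rownames(tc$matrix), rownames(ref$matrix),
                                frac_one_to_one = 0.9, seed = seed + 2L)
  write_ortholog_table(orth, file.path(dir, "orthologs.tsv"))

  sets <- generate_gene_sets(rownames(tc$matrix), n_sets = 5, set_size = 40,
                             enriched_cluster = "early_up",
                             gene_archetype = tc$truth$gene_archetype,
                             seed = seed + 3L)
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}

#' Run the full analysis pipeline
#'
#' Executes the end-to-end analysis on a demo-style input bundle:
#' expressed-gene filtering, CV2-trend variable-gene selection and
#' time-course DE union, per-cell-line profile standardization, fuzzy
#' c-means clustering (fixed k or elbow-selected), semantic cluster
#' labelling, between-cell-line correspondence, per-cluster gene-set
#' enrichment, stage-signature construction and fractional-identity
#' deconvolution, sample correlation, PCA and joint PCA with the reference.
#' Every intermediate is written as TSV together with a JSON run manifest
#' (configuration, seed, gene/sample counts after every filter, package
#' version).
#'
#' @param input_dir directory produced by [make_demo()] (or with the same
#'   file layout)
#' @param out_dir output directory (created if absent)
#' @param config configuration list from [default_config()], or a path to a
#'   YAML file with the same structure
#' @return list of in-memory results (invisibly); side effect: TSVs and
#'   `manifest.json` in `out_dir`
#' @export
run_pipeline <- function(input_dir, out_dir, config = default_config()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- c("timecourse.tsv", "samples.tsv", "reference.tsv",
            "reference_samples.tsv", "orthologs.tsv", "gene_sets.gmt")
  for (f in need)
    if (!file.exists(file.path(input_dir, f)))
      stop(sprintf("missing input: %s", f), call. = FALSE)
  manifest <- list(config = config, inputs = file.path(input_dir, need),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   package_version = as.character(utils::packageVersion("capacitrack")),
                   counts = list())
  finish <- function(stage, err) {
    manifest$failed_stage <- stage
    manifest$error <- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(err)), call. = FALSE)
  }
  stage <- "load"
  res <- tryCatch({
    tc <- read_expression(file.path(input_dir, "timecourse.tsv"), "fpkm")
    sheet <- read_sample_sheet(file.path(input_dir, "samples.tsv"))
    ref <- read_expression(file.path(input_dir, "reference.tsv"), "fpkm")
    ref_sheet <- read_sample_sheet(file.path(input_dir,
                                             "reference_samples.tsv"))
    orth <- read_ortholog_table(file.path(input_dir, "orthologs.tsv"))
    sets <- read_gmt(file.path(input_dir, "gene_sets.gmt"))
    manifest$counts$genes_input <- nrow(tc)
    manifest$counts$samples_input <- ncol(tc)
    log_stage("loaded %d genes x %d samples", nrow(tc), ncol(tc))

    stage <- "filter_expressed"
    tc_f <- filter_expressed(tc, config$expression$min_fpkm,
                             config$expression$min_samples)
    manifest$counts$genes_expressed <- nrow(tc_f)
    log_stage("expressed genes: %d", nrow(tc_f))

    stage <- "variable_genes"
    fit <- fit_cv2_trend(tc_f)
    hvg <- select_variable_genes(fit, config$hvg$min_log2fpkm,
                                 config$hvg$min_excess)
    de_union <- timecourse_de_union(tc_f, sheet, config$de$alpha,
                                    config$de$min_fc)
    manifest$counts$hvg <- length(hvg)
    manifest$counts$de_union <- length(de_union)
    write_tsv(fit$table, file.path(out_dir, "cv2_fit.tsv"))
    write_tsv(data.frame(gene = hvg), file.path(out_dir, "hvg.tsv"))
    write_tsv(data.frame(gene = de_union), file.path(out_dir, "de_union.tsv"))
    log_stage("variable genes: %d (CV2 trend), %d (DE union)",
              length(hvg), length(de_union))
    cluster_genes <- intersect(hvg, de_union)
    if (length(cluster_genes) < 50) cluster_genes <- hvg
    manifest$counts$cluster_genes <- length(cluster_genes)

    stage <- "clustering"
    tc_log <- to_log2(tc_f, config$expression$pseudocount)
    mms <- list()
    for (cl in unique(sheet$cell_line)) {
      prof <- standardize_profiles(tc_log[cluster_genes, ], sheet,
                                   cell_line = cl)
      k <- config$cluster$k
      if (isTRUE(config$cluster$elbow)) {
        eb <- elbow_select_k(prof, config$cluster$k_range,
                             m = config$cluster$m, seed = config$seed,
                             n_starts = config$cluster$n_starts)
        write_tsv(eb$table, file.path(out_dir, sprintf("elbow_%s.tsv", cl)))
        k <- eb$k
      }
      mm <- fuzzy_cmeans(prof, k, m = config$cluster$m,
                         tol = config$cluster$tol,
                         max_iter = config$cluster$max_iter,
                         seed = config$seed,
                         n_starts = config$cluster$n_starts)
      if (k == 5) mm <- label_clusters(mm)
      mms[[cl]] <- mm
      memb <- data.frame(gene = rownames(mm$membership), mm$membership,
                         cluster = mm$hard,
                         label = if (is.null(mm$labels)) NA_character_
                                 else mm$labels[mm$hard],
                         check.names = FALSE)
      write_tsv(memb, file.path(out_dir, sprintf("membership_%s.tsv", cl)))
      write_tsv(data.frame(cluster = rownames(mm$centroids), mm$centroids,
                           check.names = FALSE),
                file.path(out_dir, sprintf("centroids_%s.tsv", cl)))
      log_stage("clustered %s: k = %d, J = %.4g", cl, mm$k, mm$objective)
    }

    stage <- "correspondence"
    corr <- NULL
    if (length(mms) >= 2) {
      ml <- match_cluster_ids(mms[[1]], mms[[2]])
      labelled <- !is.null(mms[[1]]$labels) && !is.null(mms[[2]]$labels)
      assign_a <- if (labelled) canonical_assignments(mms[[1]])
                  else mms[[1]]$hard
      assign_b <- if (labelled) canonical_assignments(mms[[2]])
                  else mms[[2]]$hard
      corr <- correspondence_fractions(
        assign_a, assign_b,
        cluster_scheme(config$correspondence$scheme),
        shared_genes = intersect(names(assign_a), names(assign_b)),
        mapping = if (labelled) seq_len(mms[[1]]$k) else ml$map)
      write_tsv(corr$verdicts, file.path(out_dir, "correspondence_genes.tsv"))
      write_tsv(data.frame(n_compared = corr$n_compared,
                           n_same = corr$n_same, n_similar = corr$n_similar,
                           frac_same = corr$frac_same,
                           frac_same_or_similar = corr$frac_same_or_similar),
                file.path(out_dir, "correspondence_summary.tsv"))
      log_stage("cell-line correspondence: %.1f%% same, %.1f%% same-or-similar",
                100 * corr$frac_same, 100 * corr$frac_same_or_similar)
    }

    stage <- "enrichment"
    enr <- cluster_set_enrichment(mms[[1]], sets, universe = rownames(tc_f))
    write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

    stage <- "signatures"
    sig_stages <- config$stages$signature
    harm <- harmonize_orthologs(tc_f, ref, orth)
    manifest$counts$ortholog_pairs <- nrow(harm$pairs)
    sig <- build_signatures(harm$b, ref_sheet, sig_stages)
    log_stage("signatures: %d genes x %d stages", length(sig$genes),
              length(sig$stages))

    stage <- "fractions"
    tc_ref_space <- harm$a
    rownames(tc_ref_space) <- harm$pairs$gene_b  # reference namespace
    idt <- identity_timecourse(tc_ref_space, sheet, sig)
    write_tsv(idt$per_sample, file.path(out_dir, "fractions_per_sample.tsv"))
    write_tsv(idt$per_timepoint,
              file.path(out_dir, "fractions_per_timepoint.tsv"))
    log_stage("fractions solved for %d samples", nrow(idt$per_sample))

    stage <- "trajectory"
    cors <- sample_correlation(tc_log)
    write_tsv(data.frame(sample = rownames(cors), unclass(cors),
                         check.names = FALSE),
              file.path(out_dir, "sample_correlation.tsv"))
    pca <- pca_project(tc_log, gene_subset = intersect(cluster_genes,
                                                       rownames(tc_log)),
                       n_components = config$pca$n_components)
    write_tsv(data.frame(sample = rownames(pca$scores), pca$scores,
                         check.names = FALSE),
              file.path(out_dir, "pca_scores.tsv"))
    jp <- joint_projection(tc_f, ref, orth,
                           gene_subset = cluster_genes,
                           n_components = config$pca$n_components)
    write_tsv(data.frame(sample = rownames(jp$scores),
                         dataset = attr(jp$scores, "dataset"), jp$scores,
                         check.names = FALSE),
              file.path(out_dir, "joint_pca_scores.tsv"))
    counts_tab <- pairwise_variable_counts(tc_f, sheet, config$de$alpha,
                                           config$de$min_fc)
    for (cl in names(counts_tab))
      write_tsv(data.frame(timepoint = rownames(counts_tab[[cl]]),
                           counts_tab[[cl]], check.names = FALSE),
                file.path(out_dir, sprintf("pairwise_counts_%s.tsv", cl)))

    list(hvg = hvg, de_union = de_union, memberships = mms,
         correspondence = corr, enrichment = enr, signatures = sig,
         fractions = idt, pca = pca, joint_pca = jp,
         pairwise_counts = counts_tab, correlation = cors)
  }, error = function(e) finish(stage, e))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  manifest$seed <- config$seed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  log_stage("done; manifest written")
  invisible(res)
}
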