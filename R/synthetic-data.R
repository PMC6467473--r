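#' @keywords internal
#' Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Temporal archetype labels
#'
#' The five planted dynamic archetypes used throughout: monotone decrease
#' completing early (`early_down`), monotone decrease completing late
#' (`late_down`), transient rise-then-fall (`up_n_dn`), monotone increase
#' completing early (`early_up`), monotone increase completing late
#' (`late_up`). `background` marks non-variable genes.
#' @return character vector of the five archetype names, in canonical order
#' @export
archetype_labels <- function() {
  c("early_down", "late_down", "up_n_dn", "early_up", "late_up")
}

# Canonical shape f(t) in [0,1] on normalized ordinal time t = (i-1)/(T-1).
# "early" completes >=90% of its change by the 2nd of 6 timepoints (t = 0.2);
# "late" completes <=10% before the 4th (t = 0.6).
archetype_shape <- function(archetype, t,
                            t_early = 0.2, t_late = 0.6) {
  switch(archetype,
    early_down = 1 - pmin(t / t_early, 1),
    late_down  = 1 - pmax(0, (t - t_late) / (1 - t_late)),
    up_n_dn    = 1 - abs(t - 0.5) / 0.5,
    early_up   = pmin(t / t_early, 1),
    late_up    = pmax(0, (t - t_late) / (1 - t_late)),
    background = rep(0, length(t)),
    stop(sprintf("unknown archetype '%s'", archetype), call. = FALSE)
  )
}

#' Planted ground truth container
#'
#' Records what a synthetic dataset was built from: each gene's temporal
#' archetype, which genes are highly variable, per-sample stage mixing
#' fractions (for mixture data), ortholog pairs and the seed used.
#'
#' @param gene_archetype named character vector, gene id -> archetype label
#'   (one of [archetype_labels()] or `"background"`)
#' @param hvg_flags named logical vector, gene id -> is highly variable
#' @param stage_fractions numeric matrix samples x stages, rows on the
#'   probability simplex, or NULL
#' @param ortholog_pairs data.frame with columns `gene_a`, `gene_b`, or NULL
#' @param seed integer seed the data were generated from
#' @return object of class `planted_truth`
#' @export
planted_truth <- function(gene_archetype = NULL, hvg_flags = NULL,
                          stage_fractions = NULL, ortholog_pairs = NULL,
                          seed = NULL) {
  if (!is.null(gene_archetype)) {
    ok <- gene_archetype %in% c(archetype_labels(), "background")
    if (!all(ok)) stop("unknown archetype label in truth", call. = FALSE)
  }
  if (!is.null(stage_fractions)) {
    if (any(stage_fractions < 0) ||
        any(abs(rowSums(stage_fractions) - 1) > 1e-12))
      stop("stage_fractions rows must lie on the simplex", call. = FALSE)
  }
  if (!is.null(ortholog_pairs)) {
    if (anyDuplicated(ortholog_pairs$gene_a) ||
        anyDuplicated(ortholog_pairs$gene_b))
      stop("ortholog_pairs must be 1-to-1", call. = FALSE)
  }
  structure(list(gene_archetype = gene_archetype, hvg_flags = hvg_flags,
                 stage_fractions = stage_fractions,
                 ortholog_pairs = ortholog_pairs, seed = seed),
            class = "planted_truth")
}

# multiplicative log-normal noise with exact target coefficient of variation;
# cv = 0 returns the means untouched
lognormal_noise <- function(means, cv) {
  if (cv == 0) return(means)
  sdlog <- sqrt(log(1 + cv^2))
  means * exp(stats::rnorm(length(means), -sdlog^2 / 2, sdlog))
}

#' Generate a synthetic capacitation time course
#'
#' Simulates a bulk expression time course in which `n_variable` genes follow
#' one of five archetypal log-scale trajectories (equal-sized groups up to
#' rounding, in the order of [archetype_labels()]) and the remaining genes are
#' flat background. Observed FPKM is the archetype mean times multiplicative
#' log-normal noise with coefficient of variation `noise_cv`. The default
#' design mirrors a capacitation experiment: six timepoints (days 0-10),
#' biological triplicates, two cell lines sharing gene archetypes.
#'
#' @param n_genes total number of genes
#' @param n_variable number of archetype (variable) genes, `<= n_genes`
#' @param timepoints ordered character vector of timepoint labels
#' @param n_replicates replicates per timepoint per cell line
#' @param n_cell_lines number of cell lines
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed integer seed
#' @param variable_noise_cv optional distinct noise CV for the variable genes
#'   (defaults to `noise_cv`)
#' @param dist `"lognormal"` for FPKM-scale log-normal noise (default) or
#'   `"nb"` for a negative-binomial count mode
#' @param baseline_log2_range,amplitude_log2_range ranges the per-gene
#'   baseline and swing (log2 units) are drawn from
#' @return list with `matrix` (`expr_matrix`), `sheet` (`sample_sheet`) and
#'   `truth` (`planted_truth`)
#' @export
generate_timecourse <- function(n_genes, n_variable,
                                timepoints = c("0", "1", "2", "3", "7", "10"),
                                n_replicates = 3, n_cell_lines = 2,
                                noise_cv = 0.1, seed = 1,
                                variable_noise_cv = noise_cv,
                                dist = c("lognormal", "nb"),
                                baseline_log2_range = c(3, 7),
                                amplitude_log2_range = c(2, 4)) {
  dist <- match.arg(dist)
  if (n_genes < 1 || n_replicates < 1 || n_cell_lines < 1)
    stop("sizes must be positive", call. = FALSE)
  if (n_variable > n_genes)
    stop("n_variable must not exceed n_genes", call. = FALSE)
  if (length(timepoints) < 2) stop("need >= 2 timepoints", call. = FALSE)
  if (noise_cv < 0 || variable_noise_cv < 0)
    stop("noise_cv must be non-negative", call. = FALSE)

  with_seed(seed, {
    nt <- length(timepoints)
    t_norm <- (seq_len(nt) - 1) / (nt - 1)
    genes <- sprintf("g%05d", seq_len(n_genes))
    arche <- rep("background", n_genes)
    if (n_variable > 0)
      arche[seq_len(n_variable)] <- rep_len(archetype_labels(), n_variable)
    names(arche) <- genes

    baseline <- stats::runif(n_genes, baseline_log2_range[1],
                             baseline_log2_range[2])
    amplitude <- stats::runif(n_genes, amplitude_log2_range[1],
                              amplitude_log2_range[2])
    # log2-scale mean trajectory per gene; background is flat at baseline
    log2_means <- t(vapply(seq_len(n_genes), function(g) {
      baseline[g] + amplitude[g] * archetype_shape(arche[g], t_norm)
    }, numeric(nt)))
    mean_fpkm <- 2^log2_means  # genes x timepoints

    lines <- sprintf("line%d", seq_len(n_cell_lines))
    grid <- expand.grid(replicate = sprintf("r%d", seq_len(n_replicates)),
                        timepoint = timepoints, cell_line = lines,
                        stringsAsFactors = FALSE)
    grid <- grid[, c("cell_line", "timepoint", "replicate")]
    sample_ids <- paste(grid$cell_line, paste0("d", grid$timepoint),
                        grid$replicate, sep = "_")

    cv_gene <- ifelse(arche == "background", noise_cv, variable_noise_cv)
    vals <- matrix(0, n_genes, nrow(grid),
                   dimnames = list(genes, sample_ids))
    for (j in seq_len(nrow(grid))) {
      mu <- mean_fpkm[, match(grid$timepoint[j], timepoints)]
      if (dist == "lognormal") {
        out <- mu
        for (cv in unique(cv_gene)) {
          idx <- cv_gene == cv
          out[idx] <- lognormal_noise(mu[idx], cv)
        }
        vals[, j] <- out
      } else {
        size <- ifelse(cv_gene > 0, 1 / cv_gene^2, Inf)
        vals[, j] <- ifelse(is.infinite(size), round(mu),
                            stats::rnbinom(n_genes, mu = mu, size = size))
      }
    }

    sheet <- sample_sheet(sample_ids, dataset = "timecourse",
                          cell_line = grid$cell_line,
                          timepoint = grid$timepoint,
                          replicate = grid$replicate)
    truth <- planted_truth(
      gene_archetype = arche,
      hvg_flags = stats::setNames(arche != "background", genes),
      seed = seed)
    truth$log2_means <- log2_means
    colnames(truth$log2_means) <- timepoints

    list(matrix = expression_matrix(vals,
                                    unit = if (dist == "nb") "counts" else "fpkm"),
         sheet = sheet, truth = truth)
  })
}

#' Generate a stage-annotated reference dataset
#'
#' Simulates single cells from ordered embryonic stages (for example ICM,
#' EPI, post-E, post-L). Each stage carries a block of marker genes whose
#' log2 mean is raised by `separation` relative to a shared baseline; per-cell
#' noise is multiplicative log-normal as in [generate_timecourse()].
#'
#' @param n_genes number of genes
#' @param stages ordered character vector of stage labels (>= 2)
#' @param cells_per_stage number of cells simulated per stage
#' @param separation log2-scale elevation of each stage's marker block
#' @param noise_cv per-cell multiplicative noise CV
#' @param seed integer seed
#' @return list with `matrix`, `sheet` and `signatures` (the planted
#'   genes x stages linear-FPKM mean matrix)
#' @export
generate_stage_reference <- function(n_genes,
                                     stages = c("ICM", "EPI", "postE", "postL"),
                                     cells_per_stage = 20, separation = 3,
                                     noise_cv = 0.2, seed = 1) {
  if (n_genes < 1 || cells_per_stage < 1)
    stop("sizes must be positive", call. = FALSE)
  if (length(stages) < 2) stop("need >= 2 stages", call. = FALSE)
  if (separation < 0) stop("separation must be non-negative", call. = FALSE)

  with_seed(seed, {
    genes <- sprintf("r%05d", seq_len(n_genes))
    ns <- length(stages)
    baseline <- stats::runif(n_genes, 2, 6)
    # consecutive marker blocks, one per stage; leftover genes are shared
    block <- rep(NA_integer_, n_genes)
    block_size <- n_genes %/% (ns + 1)
    if (block_size > 0)
      block[seq_len(block_size * ns)] <- rep(seq_len(ns), each = block_size)
    log2_sig <- matrix(baseline, n_genes, ns,
                       dimnames = list(genes, stages))
    for (s in seq_len(ns)) {
      idx <- which(block == s)
      log2_sig[idx, s] <- log2_sig[idx, s] + separation
    }
    signatures <- 2^log2_sig

    ids <- as.vector(t(outer(stages, seq_len(cells_per_stage),
                             function(s, i) paste0(s, "_c", i))))
    stage_of <- rep(stages, each = cells_per_stage)
    vals <- matrix(0, n_genes, length(ids), dimnames = list(genes, ids))
    for (j in seq_along(ids))
      vals[, j] <- lognormal_noise(signatures[, stage_of[j]], noise_cv)

    sheet <- sample_sheet(ids, dataset = "reference", cell_line = "embryo",
                          timepoint = stage_of,
                          replicate = rep(seq_len(cells_per_stage),
                                          times = ns))
    list(matrix = expression_matrix(vals, unit = "fpkm"), sheet = sheet,
         signatures = signatures)
  })
}

#' Generate known mixtures of stage signatures
#'
#' Each sample's mean expression is the signature matrix times a known
#' stage-fraction vector on the probability simplex, observed with
#' multiplicative log-normal noise.
#'
#' @param signatures genes x stages numeric matrix (or `signature_set`)
#' @param fractions list of numeric simplex vectors (or a samples x stages
#'   matrix), one per sample; each must be non-negative and sum to 1 within
#'   1e-9
#' @param noise_cv non-negative noise CV (0 gives exact mixtures)
#' @param seed integer seed
#' @return list with `matrix` (`expr_matrix`) and `truth` (`planted_truth`
#'   holding `stage_fractions`)
#' @export
generate_mixtures <- function(signatures, fractions, noise_cv = 0, seed = 1) {
  S <- if (inherits(signatures, "signature_set")) signatures$S
       else as.matrix(signatures)
  if (is.list(fractions) && !is.data.frame(fractions))
    fractions <- do.call(rbind, fractions)
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != ncol(S))
    stop("fraction vectors must have one entry per stage", call. = FALSE)
  if (any(fractions < -1e-9) || any(abs(rowSums(fractions) - 1) > 1e-9))
    stop("fraction vectors must lie on the probability simplex",
         call. = FALSE)
  fractions <- pmax(fractions, 0)
  fractions <- fractions / rowSums(fractions)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)

  with_seed(seed, {
    means <- S %*% t(fractions)  # genes x samples
    ids <- sprintf("mix%03d", seq_len(ncol(means)))
    colnames(means) <- ids
    rownames(fractions) <- ids
    colnames(fractions) <- colnames(S)
    vals <- means
    if (noise_cv > 0)
      for (j in seq_len(ncol(vals)))
        vals[, j] <- lognormal_noise(means[, j], noise_cv)
    list(matrix = expression_matrix(vals, unit = "fpkm"),
         truth = planted_truth(stage_fractions = fractions, seed = seed))
  })
}

#' Generate an ortholog mapping table with decoys
#'
#' Emits a two-column table in which a fraction `frac_one_to_one` of the
#' gene pairs form a strict bijection; the remaining rows are many-to-one
#' decoys (duplicated on one side) that 1-to-1 filtering must drop entirely.
#'
#' @param genes_a,genes_b gene id vectors for the two namespaces
#' @param frac_one_to_one fraction in `[0, 1]` of pairable genes given a
#'   unique reciprocal partner
#' @param seed integer seed
#' @return data.frame with columns `gene_a`, `gene_b`
#' @export
generate_ortholog_map <- function(genes_a, genes_b, frac_one_to_one = 1,
                                  seed = 1) {
  if (frac_one_to_one < 0 || frac_one_to_one > 1)
    stop("frac_one_to_one must be in [0, 1]", call. = FALSE)
  n <- min(length(genes_a), length(genes_b))
  if (n == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    a <- sample(genes_a, n)
    b <- sample(genes_b, n)
    n11 <- round(frac_one_to_one * n)
    tab <- data.frame(gene_a = a[seq_len(n11)], gene_b = b[seq_len(n11)],
                      stringsAsFactors = FALSE)
    r <- n - n11
    if (r > 0) {
      ra <- a[n11 + seq_len(r)]
      rb <- b[n11 + seq_len(r)]
      if (r == 1) {
        # single leftover gene: duplicate it on the A side
        decoy <- data.frame(gene_a = ra[c(1, 1)],
                            gene_b = rb[c(1, 1)],
                            stringsAsFactors = FALSE)
      } else {
        # pair leftover A genes two-to-one onto B genes so every decoy row
        # carries a duplicated B gene
        targets <- rb[rep(seq_len(ceiling(r / 2)), each = 2)[seq_len(r)]]
        if (r %% 2 == 1) targets[r] <- targets[r - 1]
        decoy <- data.frame(gene_a = ra, gene_b = targets,
                            stringsAsFactors = FALSE)
      }
      tab <- rbind(tab, decoy)
    }
    tab[sample(nrow(tab)), , drop = FALSE]
  })
}

#' Generate synthetic gene sets (GMT-style)
#'
#' Draws `n_sets` gene sets of `set_size` members. When `enriched_cluster`
#' names an archetype, the first set draws at least 80% of its members from
#' genes of that archetype (per `gene_archetype`); all other sets are drawn
#' uniformly from `genes`.
#'
#' @param genes universe of gene ids
#' @param n_sets number of sets
#' @param set_size members per set (`<= length(genes)`)
#' @param enriched_cluster optional archetype label to enrich the first set in
#' @param gene_archetype named character vector gene -> archetype; required
#'   when `enriched_cluster` is given
#' @param seed integer seed
#' @return named list of character vectors (writable with [write_gmt()])
#' @export
generate_gene_sets <- function(genes, n_sets, set_size,
                               enriched_cluster = NULL,
                               gene_archetype = NULL, seed = 1) {
  if (set_size > length(genes))
    stop("set_size must not exceed the number of genes", call. = FALSE)
  if (n_sets < 1 || set_size < 1) stop("sizes must be positive", call. = FALSE)
  with_seed(seed, {
    sets <- vector("list", n_sets)
    names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
    start <- 1L
    if (!is.null(enriched_cluster)) {
      if (is.null(gene_archetype))
        stop("gene_archetype is required with enriched_cluster", call. = FALSE)
      pool <- intersect(genes, names(gene_archetype)[
        gene_archetype == enriched_cluster])
      n_in <- min(length(pool), ceiling(0.8 * set_size))
      if (n_in == 0)
        stop(sprintf("no genes of archetype '%s' in the universe",
                     enriched_cluster), call. = FALSE)
      members <- sample(pool, n_in)
      rest <- sample(setdiff(genes, members), set_size - n_in)
      sets[[1]] <- c(members, rest)
      names(sets)[1] <- paste0("SET_ENRICHED_", enriched_cluster)
      start <- 2L
    }
    for (i in seq.int(start, length.out = n_sets - start + 1L))
      sets[[i]] <- sample(genes, set_size)
    attr(sets, "description") <- rep("synthetic", n_sets)
    sets
  })
}

#' Generate a planted cross-dataset correspondence pair
#'
#' Builds two expression time courses (e.g. two species) over the same genes
#' in which each gene's archetype in dataset B is planted relative to its
#' archetype in dataset A: with probability `frac_same` the same archetype,
#' with probability `frac_similar` the same-direction archetype with the
#' other timing (early_down <-> late_down, early_up <-> late_up), and
#' otherwise the direction-flipped archetype. Genes destined for the
#' `similar` or `opposite` verdicts are drawn from the four monotone
#' archetypes (the transient archetype has no same-direction partner under
#' the within-hPSC grouping scheme); `same` genes may take any archetype.
#' B's genes are renamed and linked to A's by a bijective ortholog table.
#'
#' @param n_genes number of (all variable) genes
#' @param frac_same,frac_similar expected fractions of same- and
#'   similar-cluster genes; the remainder is opposite
#' @param timepoints,n_replicates,noise_cv as in [generate_timecourse()]
#' @param seed integer seed
#' @return list with `a`, `b` (each `matrix` + `sheet`), `orthologs`
#'   (bijective table) and `truth` (data.frame gene_a, gene_b, arch_a,
#'   arch_b, verdict)
#' @export
generate_correspondence_pair <- function(n_genes = 500, frac_same = 0.6,
                                         frac_similar = 0.25,
                                         timepoints = c("0", "1", "2", "3", "7", "10"),
                                         n_replicates = 3, noise_cv = 0.2,
                                         seed = 1) {
  if (frac_same + frac_similar > 1)
    stop("frac_same + frac_similar must not exceed 1", call. = FALSE)
  partner_similar <- c(early_down = "late_down", late_down = "early_down",
                       early_up = "late_up", late_up = "early_up")
  partner_opposite <- c(early_down = "early_up", late_down = "late_up",
                        early_up = "early_down", late_up = "late_down")
  monotone <- names(partner_similar)

  with_seed(seed, {
    verdict <- sample(c("same", "similar", "opposite"), n_genes,
                      replace = TRUE,
                      prob = c(frac_same, frac_similar,
                               1 - frac_same - frac_similar))
    arch_a <- ifelse(verdict == "same",
                     sample(archetype_labels(), n_genes, replace = TRUE),
                     sample(monotone, n_genes, replace = TRUE))
    arch_b <- ifelse(verdict == "same", arch_a,
                     ifelse(verdict == "similar",
                            partner_similar[arch_a],
                            partner_opposite[arch_a]))
    genes_a <- sprintf("a%05d", seq_len(n_genes))
    genes_b <- sprintf("b%05d", seq_len(n_genes))

    simulate_side <- function(arche, genes, side_seed) {
      nt <- length(timepoints)
      t_norm <- (seq_len(nt) - 1) / (nt - 1)
      with_seed(side_seed, {
        baseline <- stats::runif(n_genes, 3, 7)
        amplitude <- stats::runif(n_genes, 2, 4)
        mean_fpkm <- t(vapply(seq_len(n_genes), function(g) {
          2^(baseline[g] + amplitude[g] * archetype_shape(arche[g], t_norm))
        }, numeric(nt)))
        grid <- expand.grid(replicate = sprintf("r%d", seq_len(n_replicates)),
                            timepoint = timepoints,
                            stringsAsFactors = FALSE)
        ids <- paste0("d", grid$timepoint, "_", grid$replicate)
        vals <- matrix(0, n_genes, nrow(grid), dimnames = list(genes, ids))
        for (j in seq_len(nrow(grid)))
          vals[, j] <- lognormal_noise(
            mean_fpkm[, match(grid$timepoint[j], timepoints)], noise_cv)
        sheet <- sample_sheet(ids, dataset = "timecourse",
                              cell_line = "line1",
                              timepoint = grid$timepoint,
                              replicate = grid$replicate)
        list(matrix = expression_matrix(vals, unit = "fpkm"), sheet = sheet)
      })
    }
    a <- simulate_side(arch_a, genes_a, seed + 101L)
    b <- simulate_side(arch_b, genes_b, seed + 202L)
    list(a = a, b = b,
         orthologs = data.frame(gene_a = genes_a, gene_b = genes_b,
                                stringsAsFactors = FALSE),
         truth = data.frame(gene_a = genes_a, gene_b = genes_b,
                            arch_a = unname(arch_a), arch_b = unname(arch_b),
                            verdict = verdict, stringsAsFactors = FALSE))
  })
}
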