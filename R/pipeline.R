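## End-to-end orchestration: simulate -> qc/normalize -> type -> archetypes
## -> fitness -> dynamics -> imaging -> cross-species, with a run manifest
## tracing every stage output to its inputs by digest.

#' Default pipeline configuration
#'
#' A desk-scale synthetic study: four timepoints, a cancer type carrying a
#' 4-archetype simplex continuum and an IFN-like signature gradient toward
#' archetype 1, a T-cell type with a 1D trajectory and a wave-like temporal
#' pattern, and a progressively increasing myeloid type. Every
#' study constant is a named entry here — SNR cutoff 0.25, k = 20
#' neighbors, resolution schedule 0.02/0.03/0.07/0.1, 12.5% mitochondrial
#' cutoff, 25%/20% archetype discretization, 5% fitness comparison, 1000
#' t-ratio shuffles — never hard-coded in the stages.
#'
#' @param seed master seed; each stage derives its own child seed.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_genes = 400, n_timepoints = 4,
                    cells_per_timepoint = 300, depth = 6000,
                    size_factor_sd = 0.3, mito_frac = 0.02,
                    n_archetypes = 4, archetype_scale = 2,
                    n_signature = 40, signature_effect = 2),
    qc = list(min_cells_per_gene = 5, min_genes_per_cell = 100,
              mito_frac_max = 0.125),
    normalize = list(pseudocount_prior = 0.5),
    typing = list(snr_threshold = 0.25, k_neighbors = 20,
                  resolution_schedule = c(0.02, 0.03, 0.07, 0.1),
                  min_cells = 50, isolation_quantile = 0.95),
    archetypes = list(n_archetypes = 4, n_shuffles = 1000,
                      frac_closest = 0.25, frac_generalist = 0.20),
    fitness = list(frac = 0.05),
    hifi = list(n_cells = 3000, resolution = 1, n_pcs = 2,
                positive_cutoff = 0.5),
    crossspecies = list(n_human = 26, n_mouse = 8)
  )
}

## planted simplex type + trajectory type + background type
.pipeline_sim_config <- function(cfg) {
  sim <- cfg$simulate
  G <- sim$n_genes
  set.seed(derive_seed(cfg$seed, "design"))
  blocks <- split(seq_len(G), cut(seq_len(G), 8, labels = FALSE))
  arch_genes <- blocks[seq_len(sim$n_archetypes)]
  profiles <- matrix(0, sim$n_archetypes, G)
  ## archetype-program genes are expressed in every cancer cell (common
  ## baseline) with an archetype-specific gradient on top, so the simplex
  ## lives among well-measured genes
  profiles[, unlist(arch_genes)] <- 1.2
  for (a in seq_len(sim$n_archetypes))
    profiles[a, arch_genes[[a]]] <- 1.2 + sim$archetype_scale
  signature <- arch_genes[[1]][seq_len(min(sim$n_signature,
                                           length(arch_genes[[1]])))]
  traj_loading <- numeric(G)
  traj_loading[blocks[[5]]] <- 1
  types <- list(
    cell_type_spec("cancer", markers = blocks[[6]],
                   pattern = "stable_colonization",
                   simplex = list(profiles = profiles, concentration = 0.8)),
    cell_type_spec("tcell", markers = blocks[[7]], pattern = "wave_like",
                   trajectory = list(loading = traj_loading)),
    cell_type_spec("myeloid", markers = blocks[[8]],
                   pattern = "progressive_increase")
  )
  list(config = sim_config(n_genes = G, cell_types = types,
                           n_timepoints = sim$n_timepoints,
                           cells_per_timepoint = sim$cells_per_timepoint,
                           depth = sim$depth,
                           size_factor_sd = sim$size_factor_sd,
                           mito_frac = sim$mito_frac,
                           seed = derive_seed(cfg$seed, "simulate")),
       signature = signature)
}

#' Run the full pipeline on synthetic data
#'
#' Executes the declared stages in order and writes each stage's outputs
#' under \code{out_dir}, plus a run manifest (JSON) with the configuration
#' hash, per-stage seeds, input/output file digests and filter-removal
#' counts. A failure in any stage halts the run; the manifest written up to
#' that point names the failing stage, so a corrected run can be compared
#' stage by stage.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   YAML file path.
#' @param out_dir output directory.
#' @return the manifest, invisibly; also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  if (is.character(config)) {
    .assert(file.exists(config), "missing config file: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_yaml <- yaml::as.yaml(config)
  manifest <- list(config_hash = .digest_text(cfg_yaml),
                   seed = config$seed, stages = list())
  writeLines(cfg_yaml, file.path(out_dir, "config.yaml"))

  stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$stages <- lapply(manifest$stages, function(s) {
        s$data <- NULL; s
      })
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      .fail("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- res
    res
  }

  ## --- simulate -------------------------------------------------------
  sim <- stage("simulate", function() {
    ps <- .pipeline_sim_config(config)
    out <- simulate_counts(ps$config)
    d <- file.path(out_dir, "counts")
    write_mtx(out$counts, d)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    list(seed = ps$config$seed, n_genes = nrow(out$counts$counts),
         n_cells = ncol(out$counts$counts),
         outputs = .digests(c(file.path(d, "matrix.mtx"),
                              file.path(out_dir, "truth.csv"))),
         data = list(out = out, signature = ps$signature))
  })
  data_sim <- sim$data

  ## --- qc + normalize -------------------------------------------------
  qc <- stage("qc", function() {
    f <- do.call(qc_filter, c(list(cm = data_sim$out$counts), config$qc))
    rep <- attr(f, "qc_report")
    c(rep, list(data = f))
  })
  lmx <- stage("normalize", function() {
    lm <- estimate_ltq(qc$data, config$normalize$pseudocount_prior)
    write_ltq(lm, file.path(out_dir, "ltq.csv"),
              file.path(out_dir, "gene_error.csv"))
    list(outputs = .digests(file.path(out_dir, c("ltq.csv",
                                                 "gene_error.csv"))),
         data = lm)
  })$data

  ## --- typing ---------------------------------------------------------
  typing <- stage("typing", function() {
    markers <- .marker_table_from_truth(data_sim$out, qc$data)
    totals <- Matrix::colSums(qc$data$counts)
    tree <- recursive_typing(
      lmx, markers,
      resolution_schedule = config$typing$resolution_schedule,
      counts_totals = totals,
      snr_threshold = config$typing$snr_threshold,
      k_neighbors = config$typing$k_neighbors,
      min_cells = config$typing$min_cells,
      isolation_quantile = config$typing$isolation_quantile,
      seed = derive_seed(config$seed, "typing"))
    labels <- typing_leaves(tree)
    utils::write.csv(data.frame(cell_id = names(labels),
                                cell_type = unname(labels)),
                     file.path(out_dir, "cell_types.csv"),
                     row.names = FALSE)
    list(seed = derive_seed(config$seed, "typing"),
         n_leaves = length(unique(labels)),
         outputs = .digests(file.path(out_dir, "cell_types.csv")),
         data = list(tree = tree, labels = labels))
  })

  ## --- archetypes on the simplex-bearing type -------------------------
  arch <- stage("archetypes", function() {
    cells <- data_sim$out$truth$cell_id[
      data_sim$out$truth$cell_type == "cancer"]
    cells <- intersect(cells, colnames(lmx$ltq))
    sub <- ltq_matrix(lmx$ltq[, cells, drop = FALSE], lmx$gene_error)
    genes <- snr_genes(sub, config$typing$snr_threshold)
    pca <- run_pca(sub$ltq[genes, , drop = FALSE],
                   n_pcs_max = config$archetypes$n_archetypes - 1L)
    d <- config$archetypes$n_archetypes - 1L
    sc <- pca$scores[, seq_len(d), drop = FALSE]
    fit <- t_ratio_test(sc, config$archetypes$n_archetypes,
                        n_shuffles = config$archetypes$n_shuffles,
                        seed = derive_seed(config$seed, "archetypes"))
    utils::write.csv(data.frame(cell_id = cells, fit$weights),
                     file.path(out_dir, "archetype_weights.csv"),
                     row.names = FALSE)
    list(seed = derive_seed(config$seed, "archetypes"),
         t_ratio = fit$t_ratio, p_value = fit$p_value,
         outputs = .digests(file.path(out_dir, "archetype_weights.csv")),
         data = list(fit = fit, scores = sc, pca = pca, cells = cells,
                     genes = genes))
  })

  ## --- fitness --------------------------------------------------------
  fitn <- stage("fitness", function() {
    sig_ids <- rownames(data_sim$out$counts$counts)[data_sim$signature]
    nz <- simulate_normz(rownames(lmx$ltq),
                         signature_genes = intersect(sig_ids,
                                                     rownames(lmx$ltq)),
                         effect = config$simulate$signature_effect,
                         seed = derive_seed(config$seed, "normz"))
    fs <- fitness_scores(ltq_matrix(
      lmx$ltq[, arch$data$cells, drop = FALSE], lmx$gene_error), nz)
    ## target the fitted archetype whose nearest cells are enriched for
    ## the planted signature program (fitted labels are permutation-free)
    dists <- distance_to_archetype(arch$data$scores,
                                   arch$data$fit$archetypes)
    sig_in <- intersect(sig_ids, rownames(lmx$ltq))
    sig_expr <- colMeans(lmx$ltq[sig_in, arch$data$cells, drop = FALSE])
    m <- round(0.25 * nrow(dists))
    target <- which.max(vapply(seq_len(ncol(dists)), function(j)
      mean(sig_expr[order(dists[, j])[seq_len(m)]]), numeric(1)))
    ft <- archetype_fitness_test(fs, dists[, target],
                                 frac = config$fitness$frac)
    list(p_value = ft$p_value, direction = ft$direction,
         target_archetype = colnames(dists)[target],
         data = list(scores = fs, test = ft))
  })

  ## --- dynamics -------------------------------------------------------
  stage("dynamics", function() {
    lab <- discretize_archetypes(
      arch$data$scores, arch$data$fit$archetypes,
      frac_closest = config$archetypes$frac_closest,
      frac_generalist = config$archetypes$frac_generalist)
    meta <- data_sim$out$counts$cell_meta
    ph <- data.frame(cell_id = arch$data$cells, phenotype = unname(lab),
                     timepoint = meta$timepoint[
                       match(arch$data$cells, meta$cell_id)])
    totals <- table(meta$timepoint)
    prev <- prevalence_over_time(ph, totals)
    utils::write.csv(prev, file.path(out_dir, "prevalence.csv"),
                     row.names = FALSE)
    pats <- vapply(split(prev, prev$phenotype), function(df)
      classify_temporal_pattern(df$fraction[order(df$timepoint)]), "")
    list(outputs = .digests(file.path(out_dir, "prevalence.csv")),
         patterns = as.list(pats))
  })

  ## --- imaging (HIFI) -------------------------------------------------
  stage("hifi", function() {
    hifi_seed <- if (!is.null(config$hifi$seed)) config$hifi$seed else
      derive_seed(config$seed, "hifi")
    truth_comp <- prop.table(table(data_sim$out$truth$cell_type))
    panel <- list(cancer = "SOX9", tcell = c("CD45", "CD3"),
                  myeloid = c("CD45", "IBA1"))
    modes <- list(SOX9 = c(0.1, 1.5), CD45 = c(0.1, 1.4),
                  CD3 = c(0.1, 1.6), IBA1 = c(0.1, 1.3))
    h <- simulate_hifi_intensities(
      config$hifi$n_cells, composition = as.vector(truth_comp) |>
        stats::setNames(names(truth_comp)),
      panel = panel, mode_locations = modes, seed = hifi_seed)
    sc <- scale_markers(h$intensities,
                        gating = c(CD3 = "CD45", IBA1 = "CD45"),
                        positive_cutoff = config$hifi$positive_cutoff)
    cl <- cluster_hifi(sc$scaled, n_pcs = config$hifi$n_pcs,
                       resolution = config$hifi$resolution,
                       seed = derive_seed(config$seed, "hifi_cluster"),
                       positive_cutoff = config$hifi$positive_cutoff)
    rules <- list(cancer = list(necessary = "SOX9", possible = character()),
                  tcell = list(necessary = c("CD45", "CD3"),
                               possible = character()),
                  myeloid = list(necessary = c("CD45", "IBA1"),
                                 possible = character()))
    ann <- annotate_hifi(cl$labels, sc$scaled, rules,
                         positive_cutoff = config$hifi$positive_cutoff)
    hifi_comp <- prop.table(table(ann$cell_type[
      ann$cell_type != "undetermined"]))
    cmp <- compare_compositions(
      stats::setNames(as.vector(hifi_comp), names(hifi_comp)),
      stats::setNames(as.vector(truth_comp), names(truth_comp)))
    acc <- mean(ann$cell_type ==
                  h$true_type[match(names(cl$labels),
                                    h$intensities$cell_id)])
    list(seed = hifi_seed, k = cl$k,
         accuracy = acc, log_composition_r = cmp$r,
         modes = as.list(sc$modes))
  })

  ## --- cross-species composition --------------------------------------
  stage("crossspecies", function() {
    set.seed(derive_seed(config$seed, "crossspecies"))
    meta <- data_sim$out$counts$cell_meta
    ## mouse samples: timepoints; human: Dirichlet around a shifted profile
    mcomp <- prop.table(table(meta$timepoint, meta$true_type), 1)
    n_mouse <- config$crossspecies$n_mouse
    mouse <- mcomp[rep(seq_len(nrow(mcomp)),
                       length.out = n_mouse), , drop = FALSE]
    human <- .rdirichlet(config$crossspecies$n_human,
                         colMeans(mcomp) * 15 + 0.5)
    colnames(human) <- colnames(mouse)
    comp <- rbind(mouse, human)
    rownames(comp) <- c(paste0("mouse", seq_len(nrow(mouse))),
                        paste0("human", seq_len(nrow(human))))
    species <- rep(c("mouse", "human"), c(nrow(mouse), nrow(human)))
    lg <- log_center_by_species(comp, species)
    w <- species_weights(species)
    pca <- weighted_pca(lg, w)
    tpm <- pseudobulk_tpm(qc$data)
    utils::write.csv(data.frame(gene = rownames(tpm), tpm),
                     file.path(out_dir, "pseudobulk_tpm.csv"),
                     row.names = FALSE)
    list(weights = as.list(unique(stats::setNames(w, species))),
         variance_explained_pc1 = pca$variance_explained[1],
         outputs = .digests(file.path(out_dir, "pseudobulk_tpm.csv")))
  })

  ## strip in-memory data from the manifest before writing
  manifest$stages <- lapply(manifest$stages, function(s) {
    s$data <- NULL; s
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

## marker table for annotation, from the simulator's planted marker blocks
.marker_table_from_truth <- function(sim_out, cm) {
  truth <- sim_out$truth
  types <- unique(truth$cell_type)
  ltq_genes <- rownames(cm$counts)
  do.call(rbind, lapply(types, function(ty) {
    cells <- truth$cell_id[truth$cell_type == ty]
    cells <- intersect(cells, colnames(cm$counts))
    ## top genes by mean count specific to the type
    mu_in <- Matrix::rowMeans(cm$counts[, cells, drop = FALSE])
    mu_out <- Matrix::rowMeans(
      cm$counts[, setdiff(colnames(cm$counts), cells), drop = FALSE])
    sel <- order(log1p(mu_in) - log1p(mu_out), decreasing = TRUE)[1:10]
    data.frame(cell_type = ty, gene = ltq_genes[sel])
  }))
}

.digest_text <- function(txt) {
  f <- tempfile(); writeLines(txt, f)
  on.exit(unlink(f))
  unname(tools::md5sum(f))
}

.digests <- function(paths) {
  as.list(stats::setNames(unname(tools::md5sum(paths)), basename(paths)))
}
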