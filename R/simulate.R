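## Synthetic-data generator: multi-type UMI counts with Poisson sampling noise
## around cell-specific log rates, a simplex continuum inside one type, a 1D
## trajectory inside another, three temporal composition patterns, bimodal
## marker-intensity channels and signature-enriched CRISPR fitness tables.

#' Relative temporal abundance profile for one of three canonical patterns
#'
#' The three temporal patterns of microenvironment phenotypes: stable
#' colonization (rise from the first timepoint, then constant), wave-like
#' (an interior peak) and progressive increase (monotone growth).
#'
#' @param pattern one of \code{"stable_colonization"}, \code{"wave_like"},
#'   \code{"progressive_increase"}, or \code{"constant"}.
#' @param n_timepoints number of timepoints.
#' @param peak interior peak index for the wave-like pattern (default: middle).
#' @return numeric vector of relative (unnormalized) abundances per timepoint.
#' @export
temporal_profile <- function(pattern, n_timepoints,
                             peak = ceiling((n_timepoints + 1) / 2)) {
  .assert(n_timepoints >= 1, "need at least one timepoint")
  switch(match.arg(pattern, c("stable_colonization", "wave_like",
                              "progressive_increase", "constant")),
    stable_colonization = c(0.2, rep(1, n_timepoints - 1L)),
    wave_like = {
      .assert(n_timepoints >= 3 && peak > 1 && peak < n_timepoints,
              "wave_like needs an interior peak")
      up <- seq(0.2, 1, length.out = peak)
      down <- seq(1, 0.25, length.out = n_timepoints - peak + 1L)
      c(up, down[-1])
    },
    progressive_increase = 2^(seq_len(n_timepoints) - 1L) / 2^(n_timepoints - 1L),
    constant = rep(1, n_timepoints)
  )
}

#' Specify one simulated cell type
#'
#' @param name cell type name.
#' @param markers integer indices of this type's marker genes.
#' @param marker_strength natural-log fold change added to marker genes
#'   (default 2.5, i.e. ~12-fold).
#' @param pattern temporal pattern name (see [temporal_profile()]) or a
#'   numeric vector of relative abundances, one per timepoint.
#' @param parent_markers optional indices of super-type marker genes shared
#'   with sibling types (used to plant typing hierarchies).
#' @param simplex optional list(n_archetypes, profiles, concentration):
#'   \code{profiles} is an n_archetypes x n_genes matrix of log-rate offsets;
#'   cells of this type get lograte = base + w \%*\% profiles with Dirichlet
#'   weights w.
#' @param trajectory optional list(loading): a length-n_genes log-rate
#'   gradient; cells get lograte = base + position * loading with latent
#'   position ~ Uniform(-1, 1).
#' @return a \code{cell_type_spec} list.
#' @export
cell_type_spec <- function(name, markers = integer(), marker_strength = 2.5,
                           pattern = "constant", parent_markers = integer(),
                           simplex = NULL, trajectory = NULL) {
  structure(list(name = name, markers = as.integer(markers),
                 marker_strength = marker_strength, pattern = pattern,
                 parent_markers = as.integer(parent_markers),
                 simplex = simplex, trajectory = trajectory),
            class = "cell_type_spec")
}

#' Simulation configuration
#'
#' Defines the full synthetic study: genes, cell types with temporal
#' patterns, sequencing depth and noise. Per-timepoint type abundances are
#' normalized to sum to one; the configuration is validated on construction.
#'
#' @param n_genes number of genes (a \code{mito_frac} subset is given the
#'   reserved \code{mt-} prefix so mitochondrial QC is exercisable).
#' @param cell_types list of [cell_type_spec()] objects.
#' @param n_timepoints number of timepoints.
#' @param cells_per_timepoint total cells sequenced per timepoint (scalar or
#'   vector of length \code{n_timepoints}).
#' @param depth mean UMIs per cell.
#' @param size_factor_sd log-scale SD of the log-normal cell size factors
#'   (default 0.3).
#' @param mito_frac fraction of genes given the \code{mt-} prefix
#'   (default 0.02).
#' @param nb_size optional negative-binomial size parameter; \code{NULL}
#'   (default) keeps pure Poisson sampling noise.
#' @param seed master seed; all randomness flows from it.
#' @return a validated \code{sim_config} object.
#' @export
sim_config <- function(n_genes = 600, cell_types, n_timepoints = 4,
                       cells_per_timepoint = 500, depth = 2000,
                       size_factor_sd = 0.3, mito_frac = 0.02,
                       nb_size = NULL, seed = 1) {
  .assert(length(cell_types) >= 1, "need at least one cell type")
  .assert(all(vapply(cell_types, inherits, TRUE, "cell_type_spec")),
          "cell_types must be cell_type_spec objects")
  cells_per_timepoint <- rep_len(as.integer(cells_per_timepoint), n_timepoints)
  comp <- vapply(cell_types, function(ct) {
    w <- if (is.character(ct$pattern)) {
      temporal_profile(ct$pattern, n_timepoints)
    } else {
      .assert(length(ct$pattern) == n_timepoints,
              "numeric pattern must have one weight per timepoint")
      as.numeric(ct$pattern)
    }
    .assert(all(w >= 0) && any(w > 0), "pattern weights must be >= 0, not all 0")
    w
  }, numeric(n_timepoints))
  comp <- matrix(comp, nrow = n_timepoints)
  comp <- comp / rowSums(comp)  # fractions per timepoint sum to 1
  rownames(comp) <- paste0("t", seq_len(n_timepoints))
  colnames(comp) <- vapply(cell_types, `[[`, "", "name")
  .assert(!anyDuplicated(colnames(comp)), "cell type names must be unique")
  for (ct in cell_types) {
    .assert(all(ct$markers >= 1 & ct$markers <= n_genes),
            "marker indices out of range for type %s", ct$name)
    if (!is.null(ct$simplex)) .validate_simplex_spec(ct$simplex, n_genes)
    if (!is.null(ct$trajectory))
      .assert(length(ct$trajectory$loading) == n_genes,
              "trajectory loading must have one entry per gene")
  }
  structure(list(n_genes = n_genes, cell_types = cell_types,
                 n_timepoints = n_timepoints,
                 cells_per_timepoint = cells_per_timepoint,
                 composition = comp, depth = depth,
                 size_factor_sd = size_factor_sd, mito_frac = mito_frac,
                 nb_size = nb_size, seed = as.integer(seed)),
            class = "sim_config")
}

.validate_simplex_spec <- function(sp, n_genes) {
  .assert(is.matrix(sp$profiles) && ncol(sp$profiles) == n_genes,
          "simplex profiles must be n_archetypes x n_genes")
  k <- nrow(sp$profiles)
  .assert(k >= 2, "need at least 2 archetypes")
  ## affine independence: the k-1 difference vectors must have full rank
  d <- sweep(sp$profiles[-1, , drop = FALSE], 2, sp$profiles[1, ])
  .assert(qr(d)$rank == k - 1,
          "degenerate simplex: archetype profiles are affinely dependent")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d genes, %d timepoints, %s cells/timepoint, depth %g\n",
              x$n_genes, x$n_timepoints,
              paste(x$cells_per_timepoint, collapse = "/"), x$depth))
  cat("composition (rows sum to 1):\n")
  print(round(x$composition, 3))
  invisible(x)
}

#' Simulate a UMI count matrix with planted ground truth
#'
#' Counts are Poisson draws around cell-scaled exponentiated log rates:
#' \eqn{n_{gc} \sim Poisson(s_c \exp(\lambda_{gc}))} where the per-cell
#' rate vector \eqn{\exp(\lambda_{.c})} is normalized to sum to one and the
#' size factor \eqn{s_c} is log-normal with mean \code{depth}. Cells of a
#' simplex type mix archetype log-rate profiles with Dirichlet weights;
#' trajectory cells move along a 1D log-rate gradient.
#'
#' @param config a [sim_config()] object.
#' @return list with \code{counts} (a [count_matrix()]) and \code{truth}
#'   (data.frame cell_id / timepoint / cell_type plus, where applicable,
#'   archetype \code{weights} matrix and \code{trajectory_position}).
#' @export
simulate_counts <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(derive_seed(config$seed, "counts"))
  G <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(G))
  n_mito <- round(config$mito_frac * G)
  if (n_mito > 0) {
    idx <- sample.int(G, n_mito)
    gene_ids[idx] <- sprintf("mt-%05d", seq_along(idx))
  }
  base <- rep(0, G)  # flat baseline log rate; normalized per cell below

  cells <- list(); truths <- list(); wts <- list(); traj <- list()
  cell_no <- 0L
  for (t in seq_len(config$n_timepoints)) {
    n_t <- config$cells_per_timepoint[t]
    n_per_type <- .apportion(config$composition[t, ], n_t)
    for (j in seq_along(config$cell_types)) {
      ct <- config$cell_types[[j]]
      n <- n_per_type[j]
      if (n == 0) next
      lam <- matrix(base, nrow = n, ncol = G, byrow = TRUE)
      if (length(ct$parent_markers))
        lam[, ct$parent_markers] <- lam[, ct$parent_markers] + ct$marker_strength
      if (length(ct$markers))
        lam[, ct$markers] <- lam[, ct$markers] + ct$marker_strength
      w <- NULL; pos <- NULL
      if (!is.null(ct$simplex)) {
        conc <- if (is.null(ct$simplex$concentration)) 0.8 else
          ct$simplex$concentration
        k <- nrow(ct$simplex$profiles)
        w <- .rdirichlet(n, rep(conc, k))
        lam <- lam + w %*% ct$simplex$profiles
      }
      if (!is.null(ct$trajectory)) {
        pos <- stats::runif(n, -1, 1)
        lam <- lam + outer(pos, ct$trajectory$loading)
      }
      ids <- sprintf("cell%06d", cell_no + seq_len(n))
      cell_no <- cell_no + n
      rate <- exp(lam); rate <- rate / rowSums(rate)
      s <- config$depth * exp(stats::rnorm(n, -config$size_factor_sd^2 / 2,
                                           config$size_factor_sd))
      mu <- rate * s
      cnt <- if (is.null(config$nb_size)) {
        matrix(stats::rpois(n * G, as.vector(mu)), nrow = n)
      } else {
        matrix(stats::rnbinom(n * G, mu = as.vector(mu),
                              size = config$nb_size), nrow = n)
      }
      rownames(cnt) <- ids
      cells[[length(cells) + 1L]] <- cnt
      truths[[length(truths) + 1L]] <-
        data.frame(cell_id = ids, timepoint = t, cell_type = ct$name,
                   stringsAsFactors = FALSE)
      if (!is.null(w)) { rownames(w) <- ids; wts[[length(wts) + 1L]] <- w }
      if (!is.null(pos)) traj[[length(traj) + 1L]] <-
        stats::setNames(pos, ids)
    }
  }
  counts <- t(do.call(rbind, cells))  # genes x cells
  rownames(counts) <- gene_ids
  truth <- do.call(rbind, truths)
  meta <- data.frame(cell_id = truth$cell_id,
                     sample = paste0("s", truth$timepoint),
                     timepoint = truth$timepoint,
                     true_type = truth$cell_type, stringsAsFactors = FALSE)
  out <- list(counts = count_matrix(counts, meta), truth = truth)
  if (length(wts)) out$weights <- do.call(rbind, wts)
  if (length(traj)) out$trajectory_position <- unlist(traj)
  out
}

## largest-remainder apportionment of n cells to fractions f (sums to n)
.apportion <- function(f, n) {
  x <- f * n
  base <- floor(x)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(x - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  as.integer(base)
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate a noisy population inside a known simplex
#'
#' Each cell is a convex (Dirichlet-weighted) combination of archetype
#' profiles plus isotropic Gaussian noise, on the denoised log-expression
#' (LTQ) scale. Used to test archetype recovery directly.
#'
#' @param n_cells number of cells.
#' @param archetype_profiles n_archetypes x n_dims matrix of archetype
#'   coordinates.
#' @param noise_sd Gaussian noise SD added per coordinate.
#' @param concentration Dirichlet concentration for the weights (default 0.8,
#'   corner-enriched occupancy).
#' @param weights optional explicit n_cells x n_archetypes weight matrix
#'   (rows on the simplex); overrides the Dirichlet draw.
#' @param seed integer seed.
#' @return list(x = n_cells x n_dims matrix, weights = n_cells x n_archetypes).
#' @export
simulate_simplex_population <- function(n_cells, archetype_profiles,
                                        noise_sd = 0, concentration = 0.8,
                                        weights = NULL, seed = 1) {
  k <- nrow(archetype_profiles)
  .assert(k >= 2, "need at least 2 archetypes")
  set.seed(seed)
  if (is.null(weights)) {
    weights <- .rdirichlet(n_cells, rep(concentration, k))
  } else {
    .assert(nrow(weights) == n_cells && ncol(weights) == k,
            "weights must be n_cells x n_archetypes")
    .assert(all(weights >= 0) && all(abs(rowSums(weights) - 1) < 1e-9),
            "weights rows must lie on the simplex")
  }
  x <- weights %*% archetype_profiles
  if (noise_sd > 0)
    x <- x + matrix(stats::rnorm(length(x), 0, noise_sd), nrow = n_cells)
  list(x = x, weights = weights)
}

#' Simulate a CRISPR-screen NormZ table with a planted signature
#'
#' Signature genes receive NormZ ~ N(effect, 1); all other genes N(0, 1),
#' emulating a genome-wide knockout screen in which a gene signature confers
#' a survival (dis)advantage under cytotoxic-T-cell selection.
#'
#' @param gene_ids character vector of gene ids (or a count of genes).
#' @param signature_genes indices or ids of signature genes.
#' @param effect mean NormZ shift of the signature (default 0).
#' @param seed integer seed.
#' @return data.frame(gene, normz).
#' @export
simulate_normz <- function(gene_ids, signature_genes = integer(),
                           effect = 0, seed = 1) {
  if (is.numeric(gene_ids) && length(gene_ids) == 1L)
    gene_ids <- sprintf("gene%05d", seq_len(gene_ids))
  set.seed(seed)
  z <- stats::rnorm(length(gene_ids))
  if (length(signature_genes)) {
    idx <- if (is.character(signature_genes))
      match(signature_genes, gene_ids) else as.integer(signature_genes)
    .assert(!anyNA(idx) && all(idx >= 1 & idx <= length(gene_ids)),
            "signature genes not found in gene universe")
    z[idx] <- z[idx] + effect
  }
  data.frame(gene = gene_ids, normz = z, stringsAsFactors = FALSE)
}

#' Simulate per-cell multiplexed-imaging marker intensities
#'
#' Log-transformed fluorescence intensities are bimodal: cells whose true
#' type carries a marker draw from the marker's positive mode, all others
#' from the negative mode. Markers can be nested (a child marker is positive
#' only within parent-positive cells), mirroring gated staining panels.
#' Raw intensities are returned as \code{expm1} of the (non-negative,
#' truncated) log draws, so \code{log1p} recovers the simulated modes.
#'
#' @param n_cells number of cells.
#' @param composition named fractions per cell type (sums to 1).
#' @param panel named list: for each cell type, the character vector of
#'   markers that type expresses.
#' @param mode_locations named list: for each marker, \code{c(neg, pos)}
#'   log-intensity mode locations.
#' @param sd log-intensity SD around each mode (default 0.15).
#' @param seed integer seed.
#' @return list(intensities = cells x markers raw-intensity data.frame with
#'   cell_id and sample columns, true_type = character vector).
#' @export
simulate_hifi_intensities <- function(n_cells, composition, panel,
                                      mode_locations, sd = 0.15, seed = 1) {
  markers <- names(mode_locations)
  .assert(length(markers) > 0, "need at least one marker")
  .assert(abs(sum(composition) - 1) < 1e-6, "composition must sum to 1")
  if (n_cells == 0) {
    empty <- as.data.frame(matrix(numeric(), 0, length(markers),
                                  dimnames = list(NULL, markers)))
    return(list(intensities = cbind(data.frame(cell_id = character(),
                                               sample = character()), empty),
                true_type = character()))
  }
  set.seed(seed)
  types <- sample(names(composition), n_cells, replace = TRUE,
                  prob = composition)
  y <- matrix(0, n_cells, length(markers), dimnames = list(NULL, markers))
  for (m in markers) {
    pos_types <- names(panel)[vapply(panel, function(p) m %in% p, TRUE)]
    is_pos <- types %in% pos_types
    mu <- ifelse(is_pos, mode_locations[[m]][2], mode_locations[[m]][1])
    y[, m] <- pmax(stats::rnorm(n_cells, mu, sd), 0)
  }
  raw <- expm1(y)
  out <- cbind(data.frame(cell_id = sprintf("img%06d", seq_len(n_cells)),
                          sample = "s1", stringsAsFactors = FALSE),
               as.data.frame(raw))
  list(intensities = out, true_type = types)
}
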