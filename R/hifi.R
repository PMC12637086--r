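## Cell typing from multiplexed immunofluorescence intensity tables:
## high-mode marker scaling with gated mode search, PCA + Leiden
## clustering, necessary/possible-marker annotation, and the composition
## comparison against scRNA-seq.

#' Locate the high (rightmost) mode of a log-intensity distribution
#'
#' Kernel density estimate of the values; returns the location of the
#' highest-intensity (rightmost) local maximum whose prominence — height
#' relative to the tallest mode — exceeds \code{min_prominence}. If no
#' local maximum qualifies, falls back to the global maximum (flagged via
#' attribute \code{fallback}).
#'
#' @param values numeric log intensities.
#' @param bandwidth KDE bandwidth (default \code{stats::bw.nrd0}); rare
#'   positive populations can need a smaller value.
#' @param min_prominence minimum mode height as a fraction of the tallest
#'   mode (default 0.05): a rare positive population hiding below it is
#'   invisible to the ungated search — the reason the mode search is gated
#'   within parent-positive cells.
#' @return mode location (numeric scalar).
#' @export
find_high_mode <- function(values, bandwidth = NULL, min_prominence = 0.05) {
  values <- values[is.finite(values)]
  .assert(length(values) > 0, "cannot locate a mode of an empty sample")
  if (length(values) == 1) return(values)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  if (bandwidth <= 0) return(stats::median(values))
  d <- stats::density(values, bw = bandwidth, n = 512)
  y <- d$y
  ## interior local maxima
  loc <- which(diff(sign(diff(y))) == -2) + 1L
  loc <- loc[y[loc] >= min_prominence * max(y)]
  if (!length(loc)) {
    out <- d$x[which.max(y)]
    attr(out, "fallback") <- TRUE
    return(out)
  }
  d$x[max(loc)]  # rightmost qualifying mode
}

#' Scale marker intensities by their gated high mode
#'
#' Log-transforms raw intensities with \code{log1p} and divides each marker
#' by the location of the high (positive-population) mode of its
#' log-intensity distribution, so negative cells sit near 0 and positive
#' cells center around 1 regardless of the marker's brightness or dynamic
#' range. For markers whose positive population is rare (e.g. a T-cell
#' marker), the mode search is gated: it runs only among cells positive for
#' the marker's parent (scaled parent value > \code{positive_cutoff}),
#' mirroring hierarchical staining panels. Parents are scaled before
#' children (topological order).
#'
#' @param intensities data.frame with cell_id/sample columns plus one raw
#'   (>= 0) intensity column per marker.
#' @param gating named character vector: \code{gating[child] = parent};
#'   markers absent from it are ungated. Must be acyclic.
#' @param bandwidth per-marker KDE bandwidths (named list/vector or single
#'   value); default Silverman's rule per marker.
#' @param min_prominence passed to [find_high_mode()].
#' @param positive_cutoff scaled value above which a cell counts as
#'   positive (default 0.5, the midpoint of the two populations).
#' @param mode_floor smallest credible positive-mode location on the
#'   log1p scale (default 0.5). A channel whose detected high mode falls
#'   below it has no real positive population (only the negative mode was
#'   found); it is scaled by the floor instead — keeping its cells far
#'   below 1 — and flagged.
#' @return list: \code{scaled} (data.frame like the input, scaled values),
#'   \code{modes} (named vector of high-mode locations on the log1p scale),
#'   \code{fallback} (named logical: markers where no qualifying positive
#'   mode was found and the floor was used).
#' @export
scale_markers <- function(intensities, gating = NULL, bandwidth = NULL,
                          min_prominence = 0.05, positive_cutoff = 0.5,
                          mode_floor = 0.5) {
  meta_cols <- intersect(c("cell_id", "sample"), names(intensities))
  markers <- setdiff(names(intensities), meta_cols)
  .assert(length(markers) > 0, "no marker columns found")
  gating <- gating[names(gating) %in% markers]
  ## topological order: ungated markers first, then children
  ord <- character(0); remaining <- markers
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(m)
      is.null(gating) || !(m %in% names(gating)) ||
        gating[[m]] %in% ord, TRUE)]
    .assert(length(ready) > 0, "gating graph has a cycle")
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  scaled <- intensities
  modes <- stats::setNames(numeric(length(markers)), markers)
  fallback <- stats::setNames(logical(length(markers)), markers)
  for (m in ord) {
    v <- log1p(intensities[[m]])
    .assert(all(is.finite(v)) && all(intensities[[m]] >= 0),
            "intensities must be finite and >= 0 (marker %s)", m)
    gate <- rep(TRUE, length(v))
    if (!is.null(gating) && m %in% names(gating))
      gate <- scaled[[gating[[m]]]] > positive_cutoff
    bw <- if (is.null(bandwidth)) NULL
          else if (length(bandwidth) == 1 && is.null(names(bandwidth)))
            bandwidth else bandwidth[[m]]
    vals <- if (any(gate)) v[gate] else v
    md <- find_high_mode(vals, bandwidth = bw,
                         min_prominence = min_prominence)
    modes[m] <- as.numeric(md)
    fallback[m] <- isTRUE(attr(md, "fallback")) || modes[m] < mode_floor
    scaled[[m]] <- v / max(modes[m], mode_floor)
  }
  list(scaled = scaled, modes = modes, fallback = fallback)
}

#' Leiden clustering of marker-positive cells
#'
#' Clusters cells expressing at least one marker (scaled value above the
#' positivity cutoff) with Leiden on a kNN graph of the first
#' \code{n_pcs} PCs of the scaled signals; the neighborhood size follows
#' \eqn{k = \max(\mathrm{round}(n_\mathrm{cells} \times 10^{-3}), 10)}.
#'
#' @param scaled data.frame from [scale_markers()]\code{$scaled}.
#' @param n_pcs PCs used (default 2).
#' @param resolution Leiden resolution (default 1).
#' @param seed integer seed.
#' @param positive_cutoff positivity threshold on scaled values
#'   (default 0.5).
#' @return list: \code{labels} (integer per clustered cell, named by
#'   cell_id), \code{k} (neighborhood size used), \code{included}
#'   (logical per input cell).
#' @export
cluster_hifi <- function(scaled, n_pcs = 2, resolution = 1, seed = 1,
                         positive_cutoff = 0.5) {
  meta_cols <- intersect(c("cell_id", "sample"), names(scaled))
  markers <- setdiff(names(scaled), meta_cols)
  x <- as.matrix(scaled[, markers, drop = FALSE])
  included <- rowSums(x > positive_cutoff) >= 1
  xm <- x[included, , drop = FALSE]
  k <- hifi_k_neighbors(nrow(xm))
  pca <- run_pca(t(xm), n_pcs_max = max(n_pcs, 2))
  sc <- pca$scores[, seq_len(min(n_pcs, ncol(pca$scores))), drop = FALSE]
  labels <- cluster_graph(sc, k_neighbors = k, resolution = resolution,
                          seed = seed)
  ids <- if ("cell_id" %in% names(scaled)) scaled$cell_id[included] else
    which(included)
  list(labels = stats::setNames(labels, ids), k = k, included = included)
}

#' Neighborhood size rule for imaging data
#'
#' \eqn{k = \max(\mathrm{round}(n \times 10^{-3}), 10)}.
#'
#' @param n_cells number of cells being clustered.
#' @return integer k.
#' @export
hifi_k_neighbors <- function(n_cells) {
  as.integer(max(round(n_cells * 1e-3), 10))
}

#' Annotate imaging clusters by necessary/possible marker rules
#'
#' A cluster matches a cell type iff its median scaled value exceeds the
#' positivity cutoff for every necessary marker, and no marker outside the
#' type's necessary-or-possible set is positive. A cluster matching no
#' type — or more than one (never silently guessed) — is "undetermined".
#'
#' @param labels named integer cluster labels from [cluster_hifi()].
#' @param scaled data.frame from [scale_markers()]\code{$scaled}.
#' @param rules named list: for each cell type,
#'   \code{list(necessary = c(...), possible = c(...))}.
#' @param positive_cutoff positivity threshold (default 0.5).
#' @return list: \code{cluster_type} (character per cluster),
#'   \code{cell_type} (character per clustered cell, named by cell id).
#' @export
annotate_hifi <- function(labels, scaled, rules, positive_cutoff = 0.5) {
  meta_cols <- intersect(c("cell_id", "sample"), names(scaled))
  markers <- setdiff(names(scaled), meta_cols)
  ids <- if ("cell_id" %in% names(scaled)) scaled$cell_id else
    seq_len(nrow(scaled))
  x <- as.matrix(scaled[match(names(labels), ids), markers, drop = FALSE])
  cl <- sort(unique(labels))
  cluster_type <- stats::setNames(character(length(cl)), cl)
  for (c in cl) {
    med <- apply(x[labels == c, , drop = FALSE], 2, stats::median)
    pos <- names(med)[med > positive_cutoff]
    hits <- names(rules)[vapply(rules, function(r) {
      all(r$necessary %in% pos) &&
        all(pos %in% c(r$necessary, r$possible))
    }, TRUE)]
    if (length(hits) == 1) {
      cluster_type[as.character(c)] <- hits
    } else {
      if (length(hits) > 1)
        warning(sprintf("cluster %s matches multiple types (%s); undetermined",
                        c, paste(hits, collapse = ", ")))
      cluster_type[as.character(c)] <- "undetermined"
    }
  }
  list(cluster_type = cluster_type,
       cell_type = stats::setNames(cluster_type[as.character(labels)],
                                   names(labels)))
}

#' Compare imaging and scRNA-seq cell type compositions
#'
#' Log-transforms both modalities' cell type proportions and reports the
#' per-type log-fraction pairs with their Pearson correlation. Types absent
#' from one modality get a pseudo-fraction floor (half the minimum nonzero
#' fraction) and are flagged.
#'
#' @param hifi_fractions named fractions from imaging.
#' @param scrna_fractions named fractions from scRNA-seq.
#' @return list: \code{table} (data.frame type, log_hifi, log_scrna,
#'   floored), \code{r} (Pearson correlation of the log fractions).
#' @export
compare_compositions <- function(hifi_fractions, scrna_fractions) {
  types <- union(names(hifi_fractions), names(scrna_fractions))
  h <- stats::setNames(rep(0, length(types)), types)
  s <- h
  h[names(hifi_fractions)] <- hifi_fractions
  s[names(scrna_fractions)] <- scrna_fractions
  lh <- .log_with_floor(h); ls <- .log_with_floor(s)
  tab <- data.frame(type = types, log_hifi = lh$log, log_scrna = ls$log,
                    floored = lh$floored | ls$floored)
  list(table = tab, r = stats::cor(tab$log_hifi, tab$log_scrna))
}
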