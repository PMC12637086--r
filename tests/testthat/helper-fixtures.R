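## shared fixtures and oracles, built in code at test time

## all permutations of a small vector (brute-force matching oracle)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

## worst matched vertex distance under the best assignment (brute force)
match_archetype_error <- function(fitted, truth) {
  D <- as.matrix(stats::dist(rbind(fitted, truth)))
  D <- D[seq_len(nrow(fitted)), nrow(fitted) + seq_len(nrow(truth))]
  min(vapply(all_perms(seq_len(nrow(truth))),
             function(p) max(D[cbind(seq_along(p), p)]), numeric(1)))
}

## the study's geometry: 4 archetypes spanning a 3D simplex
tetra_archetypes <- function(scale = 4) {
  matrix(c(0, 0, 0, scale, 0, 0, 0, scale, 0, 0, 0, scale),
         4, 3, byrow = TRUE)
}

## small two-type study for QC/normalization tests
two_type_config <- function(n_genes = 200, cells = 150, depth = 3000,
                            seed = 11) {
  sim_config(
    n_genes = n_genes,
    cell_types = list(
      cell_type_spec("A", markers = 1:20, pattern = "constant"),
      cell_type_spec("B", markers = 21:40, pattern = "constant")),
    n_timepoints = 2, cells_per_timepoint = cells, depth = depth,
    seed = seed)
}

## six-type imaging panel mirroring a cancer/immune staining design
hifi_panel <- function() {
  list(cancer = "SOX9", stroma = character(0),
       myeloid = c("CD45", "IBA1"),
       macrophage = c("CD45", "IBA1", "F480"),
       thelper = c("CD45", "CD3"),
       tc = c("CD45", "CD3", "CD8"))
}

hifi_modes <- function() {
  list(SOX9 = c(0.1, 1.5), CD45 = c(0.1, 1.4), IBA1 = c(0.1, 1.3),
       F480 = c(0.1, 1.6), CD3 = c(0.1, 1.5), CD8 = c(0.1, 1.4))
}

hifi_rules <- function() {
  list(cancer = list(necessary = "SOX9", possible = character()),
       myeloid = list(necessary = c("CD45", "IBA1"), possible = character()),
       macrophage = list(necessary = c("CD45", "IBA1", "F480"),
                         possible = character()),
       thelper = list(necessary = c("CD45", "CD3"), possible = character()),
       tc = list(necessary = c("CD45", "CD3", "CD8"),
                 possible = character()))
}

hifi_composition <- function() {
  c(cancer = 0.45, stroma = 0.10, myeloid = 0.15, macrophage = 0.12,
    thelper = 0.10, tc = 0.08)
}

## planted nine-type hierarchy (4 super-groups) for typing recovery
nine_type_config <- function(cells_per_timepoint = 1000, n_timepoints = 3,
                             depth = 5000, seed = 21) {
  G <- 540
  blk <- function(i) ((i - 1) * 12 + 1):(i * 12)  # 12-gene marker blocks
  super <- list(myeloid = blk(40), cancer = blk(41), lymphoid = blk(42),
                stroma = blk(43))
  leaf <- list(macrophage = blk(1), dc = blk(2), cancer = blk(3),
               tc = blk(4), th = blk(5), treg = blk(6), b = blk(7),
               ilc = blk(8), stroma = blk(9))
  parent_of <- c(macrophage = "myeloid", dc = "myeloid", cancer = "cancer",
                 tc = "lymphoid", th = "lymphoid", treg = "lymphoid",
                 b = "lymphoid", ilc = "lymphoid", stroma = "stroma")
  fracs <- c(macrophage = 0.16, dc = 0.08, cancer = 0.30, tc = 0.10,
             th = 0.10, treg = 0.06, b = 0.06, ilc = 0.04, stroma = 0.10)
  types <- lapply(names(leaf), function(ty)
    cell_type_spec(ty, markers = leaf[[ty]],
                   parent_markers = super[[parent_of[[ty]]]],
                   pattern = rep(fracs[[ty]], n_timepoints)))
  list(config = sim_config(n_genes = G, cell_types = types,
                           n_timepoints = n_timepoints,
                           cells_per_timepoint = cells_per_timepoint,
                           depth = depth, seed = seed),
       leaf_markers = leaf)
}

## marker table (cell_type, gene) from planted marker blocks
marker_table <- function(leaf_markers, gene_ids) {
  do.call(rbind, lapply(names(leaf_markers), function(ty)
    data.frame(cell_type = ty, gene = gene_ids[leaf_markers[[ty]]],
               stringsAsFactors = FALSE)))
}
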