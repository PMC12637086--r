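test_that("run_pca is an exact centered unscaled PCA", {
  set.seed(41)
  ## pure rank-1 structure dominates the first component
  u <- rnorm(30); v <- rnorm(200)
  x <- outer(u, v)  # genes x cells
  dimnames(x) <- list(paste0("g", 1:30), paste0("c", 1:200))
  p <- run_pca(x)
  expect_gt(p$variance_explained[1] / sum(p$variance_explained), 0.999)

  ## loadings orthonormal, variance non-increasing, reconstruction exact
  set.seed(42)
  x2 <- matrix(rnorm(40 * 120), 40, 120,
               dimnames = list(paste0("g", 1:40), paste0("c", 1:120)))
  p2 <- run_pca(x2, n_pcs_max = 40)
  expect_equal(crossprod(p2$loadings), diag(ncol(p2$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(p2$variance_explained) <= 1e-12))
  centered <- t(x2) - rep(colMeans(t(x2)), each = nrow(t(x2)))
  expect_equal(p2$scores %*% t(p2$loadings), centered,
               tolerance = 1e-8, ignore_attr = TRUE)

  ## isotropic noise: the sorted shares stay inside the sampling band
  ## around equality ((1 +/- sqrt(p/n))^2 bounds on eigenvalue spread)
  ves <- t(replicate(10, {
    g <- matrix(rnorm(10 * 2000), 10, 2000)
    dimnames(g) <- list(paste0("g", 1:10), paste0("c", 1:2000))
    run_pca(g, n_pcs_max = 10)$variance_explained
  }))
  band <- 10 * (1 + c(-1, 1) * sqrt(10 / 2000))^2 + c(-1, 1)
  expect_true(all(ves > band[1] & ves < band[2]))
})

test_that("choose_n_pcs follows the second-difference elbow rule", {
  expect_identical(choose_n_pcs(c(50, 25, 3, 2.8, 2.7)), 2L)
  expect_identical(choose_n_pcs(c(40, 30, 20, 2, 1.9)), 3L)
  ## strictly geometric decay has no elbow: lower bound 2
  expect_identical(choose_n_pcs(60 * 0.5^(0:9)), 2L)
  expect_identical(choose_n_pcs(c(50, 25, 3, 2.8, 2.7), n_pcs_max = 2), 2L)
})

test_that("cluster_graph recovers planted blobs and is reproducible", {
  skip_if_not_installed("mclust")
  set.seed(43)
  blob <- function(center, n) sweep(matrix(rnorm(n * 2, 0, 1), n, 2), 2,
                                    center, "+")
  ## two blobs separated by 20 sigma
  x2 <- rbind(blob(c(0, 0), 150), blob(c(20, 0), 150))
  lab2 <- cluster_graph(x2, resolution = 0.02, seed = 7)
  truth2 <- rep(1:2, each = 150)
  expect_equal(mclust::adjustedRandIndex(lab2, truth2), 1)

  ## a single blob stays one community
  lab1 <- cluster_graph(blob(c(0, 0), 300), resolution = 0.02, seed = 7)
  expect_equal(length(unique(lab1)), 1L)

  ## four planted blobs at the study's top-level resolution 0.02
  x4 <- rbind(blob(c(0, 0), 120), blob(c(20, 0), 120),
              blob(c(0, 20), 120), blob(c(20, 20), 120))
  lab4 <- cluster_graph(x4, resolution = 0.02, seed = 7)
  expect_equal(length(unique(lab4)), 4L)
  expect_equal(mclust::adjustedRandIndex(lab4, rep(1:4, each = 120)), 1)

  ## fixed seed: bitwise reproducible
  expect_identical(lab4, cluster_graph(x4, resolution = 0.02, seed = 7))
})

test_that("isolation_filter computes n*d^3 and flags isolated cells", {
  ## two cells at distance 1 with k=1: d=1 each, n*d^3 = 2
  two <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  iso <- isolation_filter(two, k_neighbors = 1, cutoff_nd3 = 10)
  expect_equal(iso$nd3, c(2, 2))

  ## the d^3 ~ 1/n scaling: the same region at 10x the cell count keeps
  ## the n*d^3 distribution unchanged (interior cells, to dodge
  ## box-boundary edge effects)
  set.seed(101)
  small <- matrix(runif(1000 * 3), ncol = 3)
  big <- matrix(runif(10000 * 3), ncol = 3)
  nd_small <- isolation_filter(small, k_neighbors = 5, cutoff_nd3 = Inf)$nd3
  nd_big <- isolation_filter(big, k_neighbors = 5, cutoff_nd3 = Inf)$nd3
  interior <- function(x) apply(x > 0.2 & x < 0.8, 1, all)
  ks <- stats::ks.test(nd_small[interior(small)], nd_big[interior(big)])
  expect_gt(ks$p.value, 0.01)

  ## an extreme outlier has the maximum n*d^3 and is excluded
  set.seed(45)
  cloud <- matrix(rnorm(500 * 3, 0, 0.5), ncol = 3)
  cloud <- rbind(cloud, c(50, 50, 50))
  iso2 <- isolation_filter(cloud, k_neighbors = 10)
  expect_equal(which.max(iso2$nd3), 501L)
  expect_false(iso2$keep[501])
})

test_that("annotate_clusters assigns markers with a margin and never guesses ties", {
  set.seed(46)
  G <- 40
  ids <- paste0("g", 1:G)
  markers <- data.frame(cell_type = rep(c("A", "B"), each = 5),
                        gene = ids[c(1:5, 6:10)])
  ## two clusters, each expressing its own marker block
  ltq <- matrix(rnorm(G * 200, -8, 0.1), G, 200,
                dimnames = list(ids, paste0("c", 1:200)))
  labels <- rep(1:2, each = 100)
  ltq[1:5, labels == 1] <- ltq[1:5, labels == 1] + 2
  ltq[6:10, labels == 2] <- ltq[6:10, labels == 2] + 2
  ann <- annotate_clusters(labels, ltq, markers)
  expect_identical(unname(ann), c("A", "B"))

  ## exactly tied marker scores stay unresolved (deterministic profile:
  ## both marker blocks follow the same cluster pattern)
  ltq2 <- matrix(-8, G, 300, dimnames = list(ids, paste0("c", 1:300)))
  lab3 <- rep(1:3, each = 100)
  ltq2[1:10, lab3 == 1] <- -6   # A and B markers rise together
  ann2 <- annotate_clusters(lab3, ltq2, markers)
  expect_true(all(ann2 == "unresolved"))

  ## unknown marker ids warn and are dropped
  markers3 <- rbind(markers, data.frame(cell_type = "A", gene = "nope"))
  expect_warning(annotate_clusters(labels, ltq, markers3), "not in matrix")
})

test_that("recursive typing resolves a planted two-level hierarchy", {
  skip_if_not_installed("mclust")
  ## two super-types, each split into two subtypes
  G <- 160
  types <- list(
    cell_type_spec("A1", markers = 1:12, parent_markers = 101:115),
    cell_type_spec("A2", markers = 21:32, parent_markers = 101:115),
    cell_type_spec("B1", markers = 41:52, parent_markers = 121:135),
    cell_type_spec("B2", markers = 61:72, parent_markers = 121:135))
  cfg <- sim_config(n_genes = G, cell_types = types, n_timepoints = 2,
                    cells_per_timepoint = 400, depth = 5000, seed = 47)
  out <- simulate_counts(cfg)
  cm <- qc_filter(out$counts)
  lm <- estimate_ltq(cm)
  mk <- do.call(rbind, lapply(list(A1 = 1:12, A2 = 21:32, B1 = 41:52,
                                   B2 = 61:72), function(ix)
    data.frame(gene = rownames(out$counts$counts)[ix])))
  mk$cell_type <- rep(c("A1", "A2", "B1", "B2"), each = 12)
  tree <- recursive_typing(lm, mk,
                           counts_totals = Matrix::colSums(cm$counts),
                           min_cells = 40, seed = 48)
  leaves <- typing_leaves(tree)
  truth <- out$truth$cell_type[match(names(leaves), out$truth$cell_id)]
  expect_gte(mclust::adjustedRandIndex(leaves, truth), 0.9)
  expect_setequal(unique(leaves), c("A1", "A2", "B1", "B2"))
  ## every typed cell appears in exactly one leaf
  expect_false(anyDuplicated(names(leaves)) > 0)

  ## a homogeneous population yields a single leaf (continuum at the root)
  cfg1 <- sim_config(n_genes = 160,
                     cell_types = list(cell_type_spec("only",
                                                      markers = 1:10)),
                     n_timepoints = 1, cells_per_timepoint = 300,
                     depth = 3000, seed = 49)
  out1 <- simulate_counts(cfg1)
  lm1 <- estimate_ltq(qc_filter(out1$counts))
  tree1 <- recursive_typing(lm1, data.frame(cell_type = "only",
                                            gene = rownames(lm1$ltq)[1:10]),
                            min_cells = 40, seed = 50)
  expect_length(tree1$children, 0)
})
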