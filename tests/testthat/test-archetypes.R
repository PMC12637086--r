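test_that("hull volumes are exact in 1, 2 and 3 dimensions", {
  expect_equal(convex_hull_volume(matrix(c(0, 1, 0.3, 0.7), 4, 1)), 1)
  sq <- rbind(c(0, 0), c(2, 0), c(2, 3), c(0, 3), c(1, 1))
  expect_equal(convex_hull_volume(sq), 6)
  ## unit cube corners plus interior points: volume 1
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  set.seed(51)
  pts <- rbind(cube, matrix(runif(300), ncol = 3))
  expect_equal(convex_hull_volume(pts), 1, tolerance = 1e-10)
  ## random cloud: quickhull agrees with the simplex formula on a tetra
  tet <- tetra_archetypes(2)
  expect_equal(convex_hull_volume(tet[c(1:4, 1), ]),
               tmedyn:::.simplex_volume(tet), tolerance = 1e-12)
  expect_error(convex_hull_volume(matrix(rnorm(40), 10, 4)), "d <= 3")
})

test_that("fit_simplex returns exact vertices for replicated archetype points", {
  arch <- tetra_archetypes()
  w <- diag(4)[rep(1:4, each = 50), ]
  pop <- simulate_simplex_population(200, arch, noise_sd = 0, weights = w,
                                     seed = 52)
  fit <- fit_simplex(pop$x, 4, seed = 52)
  expect_lt(match_archetype_error(fit$archetypes, arch), 1e-6)
  expect_equal(fit$t_ratio, 1, tolerance = 1e-6)
  expect_true(all(fit$weights >= 0))
  expect_equal(rowSums(fit$weights), rep(1, 200), tolerance = 1e-6)
})

test_that("fit_simplex recovers archetypes from noisy simplex data", {
  arch <- tetra_archetypes()
  diam <- max(stats::dist(arch))
  pop <- simulate_simplex_population(2000, arch, noise_sd = 0.05 * diam,
                                     concentration = 0.8, seed = 7)
  fit <- fit_simplex(pop$x, 4, n_restarts = 5, seed = 7)
  expect_lt(match_archetype_error(fit$archetypes, arch), 0.1 * diam)

  ## recovery improves with sample size
  popS <- simulate_simplex_population(200, arch, noise_sd = 0.05 * diam,
                                      concentration = 0.8, seed = 53)
  popL <- simulate_simplex_population(2000, arch, noise_sd = 0.05 * diam,
                                      concentration = 0.8, seed = 53)
  eS <- match_archetype_error(
    fit_simplex(popS$x, 4, n_restarts = 3, seed = 5)$archetypes, arch)
  eL <- match_archetype_error(
    fit_simplex(popL$x, 4, n_restarts = 3, seed = 5)$archetypes, arch)
  expect_lt(eL, eS)

  ## collinear data cannot span the fitted dimensions
  line <- cbind(seq(0, 1, length.out = 50), seq(0, 2, length.out = 50))
  expect_warning(fit_simplex(line, 3, seed = 1), "degenerate")

  ## fewer cells than archetypes is an error
  expect_error(fit_simplex(matrix(rnorm(6), 3, 2), 4), "fewer cells")
})

test_that("principal-convex-hull path handles extra archetypes monotonically", {
  arch <- tetra_archetypes()
  pop <- simulate_simplex_population(400, arch, noise_sd = 0.1, seed = 54)
  ## 5 archetypes in 3 dims: PCHA path, objective trace never increases
  f5 <- fit_simplex(pop$x, 5, n_restarts = 2, seed = 54)
  expect_equal(dim(f5$archetypes), c(5L, 3L))
  tr <- tmedyn:::.pcha(t(pop$x), 5,
                       tmedyn:::.furthest_first(pop$x, 5, 1),
                       maxiter = 80)$trace
  expect_true(all(diff(tr) <= 1e-8))
})

test_that("t_ratio compares simplex and data-hull volumes", {
  arch <- tetra_archetypes()
  ## the vertices themselves: hull equals simplex
  expect_equal(t_ratio(arch, arch), 1, tolerance = 1e-12)

  ## uniform points in a triangle with the true vertices: ratio -> 1
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  u <- simulate_simplex_population(5000, tri, noise_sd = 0,
                                   concentration = 1, seed = 55)
  expect_equal(t_ratio(u$x, tri), 1, tolerance = 0.05)

  ## a gaussian cloud against its minimal enclosing simplex: ratio > 1.3
  ratios <- vapply(1:5, function(s) {
    set.seed(55 + s)
    g <- matrix(rnorm(800 * 3), ncol = 3)
    fit_simplex(g, 4, n_restarts = 2, seed = s, enclose = TRUE)$t_ratio
  }, numeric(1))
  expect_true(all(ratios > 1.3))

  ## enclosure-mode fits always have t_ratio >= 1
  pop <- simulate_simplex_population(500, arch, noise_sd = 0.2, seed = 56)
  fe <- fit_simplex(pop$x, 4, seed = 56, enclose = TRUE)
  expect_gte(fe$t_ratio, 1 - 1e-9)
  expect_true(fe$enclosed)
})

test_that("t_ratio_test detects a planted simplex and reports honest p-values", {
  arch <- tetra_archetypes()
  diam <- max(stats::dist(arch))
  pop <- simulate_simplex_population(800, arch, noise_sd = 0.05 * diam,
                                     concentration = 0.8, seed = 57)
  tt <- t_ratio_test(pop$x, 4, n_shuffles = 99, seed = 57)
  expect_lte(tt$p_value, 0.01)
  ## the p-value is exactly the add-one permutation fraction
  expect_equal(tt$p_value,
               (1 + sum(tt$null_t_ratios <= tt$t_ratio)) / (1 + 99))
  expect_gte(tt$p_value, 1 / (1 + 99))
  expect_true(all(tt$null_t_ratios >= 1 - 1e-9))
  expect_warning(t_ratio_test(pop$x[1:50, ], 4, n_shuffles = 5, seed = 1),
                 "floor")
})

test_that("distances and proximity discretization follow the 25%/20% rules", {
  arch <- tetra_archetypes()
  ## distance at an archetype is 0; the centroid is equidistant
  d <- distance_to_archetype(arch, arch)
  expect_equal(unname(diag(d)), rep(0, 4))
  ## the centroid of a regular simplex is equidistant from every vertex
  reg <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  dc <- distance_to_archetype(matrix(colMeans(reg), 1), reg)
  expect_lt(diff(range(dc)), 1e-9)
  ## hand-computed 2D distances
  pts <- rbind(c(0, 0), c(3, 4))
  a2 <- rbind(A = c(0, 0), B = c(3, 0))
  expect_equal(unname(distance_to_archetype(pts, a2)),
               rbind(c(0, 3), c(5, 4)))

  ## 20 cells, frac 0.25: each archetype claims round(0.25*20) = 5 cells
  sq <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  set.seed(58)
  cells <- sq[rep(1:4, each = 5), ] + matrix(rnorm(40, 0, 0.1), 20, 2)
  lab <- discretize_archetypes(cells, sq, frac_closest = 0.25,
                               frac_generalist = 0)
  expect_equal(unname(table(lab)[c("A1", "A2", "A3", "A4")]),
               rep(5L, 4), ignore_attr = TRUE)

  ## 100 cells, frac_generalist 0.20: exactly 20 generalists
  set.seed(59)
  cloud <- matrix(rnorm(200), 100, 2)
  labg <- discretize_archetypes(cloud, sq, frac_closest = 0,
                                frac_generalist = 0.20)
  expect_equal(sum(labg == "generalist"), 20L)

  ## a cell exactly at an archetype is labeled with it
  one <- rbind(sq[2, ] + 0, c(100, 100))
  lab1 <- discretize_archetypes(rbind(one, cloud + 50), sq,
                                frac_closest = 0.02, frac_generalist = 0)
  expect_equal(unname(lab1[1]), "A2")
})

test_that("archetype_enrichment ranks planted gradients and stays calibrated", {
  arch <- tetra_archetypes()
  pop <- simulate_simplex_population(1000, arch, noise_sd = 0.1, seed = 60)
  d <- distance_to_archetype(pop$x, arch)
  set.seed(61)
  G <- 30
  ltq <- matrix(rnorm(G * 1000, -8, 0.2), G, 1000,
                dimnames = list(paste0("g", 1:G), paste0("c", 1:1000)))
  ## gene 1 increases linearly toward archetype 1
  ltq[1, ] <- -8 + 2 * pop$weights[, 1] + rnorm(1000, 0, 0.05)
  enr <- archetype_enrichment(ltq, d)
  a1 <- enr[enr$archetype == "A1", ]
  expect_equal(a1$feature[which.min(a1$q)], "g1")
  expect_lt(a1$q[a1$feature == "g1"], 0.01)
  expect_gt(a1$delta[a1$feature == "g1"], 0)

  ## genes unrelated to the geometry give uniform p-values
  ps <- vapply(1:80, function(r) {
    set.seed(1000 + r)
    g <- matrix(rnorm(1000, -8, 0.2), 1,
                dimnames = list("g", paste0("c", 1:1000)))
    archetype_enrichment(g, d[, 1, drop = FALSE])$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  ## empty feature selection: empty table
  expect_equal(nrow(archetype_enrichment(ltq, d, features = character())), 0)
})

test_that("continuum_diagnostic separates blurred clusters from a filled simplex", {
  set.seed(62)
  ## four tight blobs whose spread equals the measurement error
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6))
  err <- 0.3
  blobs <- centers[rep(1:4, each = 150), ] + matrix(rnorm(1200, 0, err),
                                                    600, 2)
  diag1 <- continuum_diagnostic(blobs, error_sd = err, bandwidth = err)
  expect_equal(diag1$verdict, "cluster-like")
  expect_gte(nrow(diag1$peaks), 2)

  ## a Dirichlet-filled simplex is far wider than the error
  tri <- rbind(c(0, 0), c(6, 0), c(0, 6))
  u <- simulate_simplex_population(1500, tri, noise_sd = err,
                                   concentration = 1.5, seed = 63)
  diag2 <- continuum_diagnostic(u$x, error_sd = err)
  expect_equal(diag2$verdict, "continuum-like")

  ## a single gaussian yields one reported peak
  g <- matrix(rnorm(1000, 0, 1), 500, 2)
  diag3 <- continuum_diagnostic(g, error_sd = 0.1)
  expect_equal(nrow(diag3$peaks), 1)
})
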