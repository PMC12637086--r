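test_that("simulated counts are deterministic, Poisson-sensible, and carry truth", {
  cfg <- two_type_config()
  out1 <- simulate_counts(cfg)
  out2 <- simulate_counts(cfg)
  expect_identical(out1$counts$counts, out2$counts$counts)
  expect_identical(out1$truth, out2$truth)

  ## zero depth: zero-rate limit of the Poisson draw
  cfg0 <- two_type_config(depth = 0)
  expect_true(all(simulate_counts(cfg0)$counts$counts == 0))

  ## disjoint marker blocks: analytic Poisson group means separate
  out <- simulate_counts(two_type_config(depth = 5000))
  cn <- out$counts$counts
  a_cells <- out$truth$cell_id[out$truth$cell_type == "A"]
  b_cells <- out$truth$cell_id[out$truth$cell_type == "B"]
  a_markers <- rownames(cn)[1:20]
  mean_aa <- mean(cn[a_markers, a_cells])
  mean_ab <- mean(cn[a_markers, b_cells])
  expect_gt(mean_aa, mean_ab)
  ## the planted log fold change is 2.5; allow sampling slack
  expect_gt(log(mean_aa / mean_ab), 1.5)
})

test_that("per-timepoint composition follows the configured temporal patterns", {
  ## each pattern against a constant background type, so the normalized
  ## fraction inherits the pattern's shape
  for (p in c("stable_colonization", "wave_like", "progressive_increase")) {
    cfg <- sim_config(
      n_genes = 100,
      cell_types = list(
        cell_type_spec("focal", markers = 1:5, pattern = p),
        cell_type_spec("background", markers = 6:10,
                       pattern = "constant")),
      n_timepoints = 4, cells_per_timepoint = 600, depth = 500, seed = 5)
    comp <- cfg$composition
    expect_equal(unname(rowSums(comp)), rep(1, 4), tolerance = 1e-9)
    f <- comp[, "focal"]
    if (p == "wave_like") {
      expect_true(which.max(f) > 1 && which.max(f) < length(f))
      expect_true(all(f[which.max(f)] > f[-which.max(f)]))
    }
    if (p == "progressive_increase")
      expect_true(all(diff(f) >= 0))
    if (p == "stable_colonization")
      expect_true(all(f[-1] > f[1]) && diff(range(f[-1])) < 1e-9)

    ## realized fractions stay within the binomial 99% CI of the target
    out <- simulate_counts(cfg)
    tab <- table(out$truth$timepoint, out$truth$cell_type)
    for (t in 1:4) for (ty in colnames(comp)) {
      n <- sum(tab[t, ])
      ci <- stats::qbinom(c(0.005, 0.995), n, comp[t, ty])
      expect_true(tab[t, ty] >= ci[1] - 1 && tab[t, ty] <= ci[2] + 1)
    }
  }
})

test_that("simplex population generator honors weights, hull and Dirichlet moments", {
  arch <- tetra_archetypes()
  ## identity weights + zero noise reproduce the archetypes exactly
  w <- diag(4)[rep(1:4, 3), ]
  pop <- simulate_simplex_population(12, arch, noise_sd = 0, weights = w,
                                     seed = 1)
  expect_equal(pop$x, w %*% arch, tolerance = 1e-12)

  ## zero noise: every cell inside the archetype hull (barycentric >= 0)
  pop2 <- simulate_simplex_population(500, arch, noise_sd = 0, seed = 2)
  bc <- tmedyn:::.barycentric(pop2$x, arch)
  expect_true(min(bc) >= -1e-9)
  expect_equal(rowSums(pop2$weights), rep(1, 500), tolerance = 1e-9)

  ## flat Dirichlet: mean weight per archetype 0.25 +/- 0.02
  pop3 <- simulate_simplex_population(2000, arch, noise_sd = 0,
                                      concentration = 1, seed = 3)
  expect_true(all(abs(colMeans(pop3$weights) - 0.25) < 0.02))
})

test_that("NormZ simulator plants the signature effect and nothing else", {
  ids <- sprintf("g%04d", 1:2000)
  sig <- 1:50

  ## no effect: signature and background agree within 3 standard errors
  nz0 <- simulate_normz(ids, sig, effect = 0, seed = 4)
  d0 <- mean(nz0$normz[sig]) - mean(nz0$normz[-sig])
  se <- sqrt(1 / 50 + 1 / 1950)
  expect_lt(abs(d0), 3 * se)

  ## effect 3: separation close to 3
  nz3 <- simulate_normz(ids, sig, effect = 3, seed = 4)
  expect_equal(mean(nz3$normz[sig]) - mean(nz3$normz[-sig]), 3,
               tolerance = 0.5)

  ## empty signature: a pure standard normal table
  nze <- simulate_normz(ids, integer(), effect = 5, seed = 4)
  expect_equal(mean(nze$normz), 0, tolerance = 3 / sqrt(2000))
  expect_equal(stats::sd(nze$normz), 1, tolerance = 0.1)
})

test_that("imaging intensity simulator produces gated bimodal channels", {
  ## single-type composition: every cell drawn from the positive mode
  h1 <- simulate_hifi_intensities(500, c(A = 1),
                                  panel = list(A = "m"),
                                  mode_locations = list(m = c(0.1, 1.5)),
                                  sd = 0.1, seed = 5)
  expect_equal(stats::median(log1p(h1$intensities$m)), 1.5, tolerance = 0.05)

  ## mixed composition: two detectable density maxima near the two modes
  h2 <- simulate_hifi_intensities(4000, c(A = 0.5, B = 0.5),
                                  panel = list(A = "m", B = character()),
                                  mode_locations = list(m = c(0.1, 1.5)),
                                  sd = 0.1, seed = 6)
  d <- stats::density(log1p(h2$intensities$m), n = 512)
  loc <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  loc <- loc[d$y[which(diff(sign(diff(d$y))) == -2) + 1] > 0.05 * max(d$y)]
  expect_length(loc, 2)
  expect_equal(sort(loc), c(0.1, 1.5), tolerance = 0.1)

  ## zero cells: empty table, no error
  h0 <- simulate_hifi_intensities(0, c(A = 1), panel = list(A = "m"),
                                  mode_locations = list(m = c(0.1, 1.5)))
  expect_equal(nrow(h0$intensities), 0)
  expect_length(h0$true_type, 0)
})

test_that("degenerate simplex specifications are rejected", {
  prof <- matrix(1, 3, 50)  # affinely dependent rows
  expect_error(
    sim_config(n_genes = 50,
               cell_types = list(cell_type_spec(
                 "s", simplex = list(profiles = prof))),
               n_timepoints = 2, cells_per_timepoint = 50),
    "degenerate simplex")
})
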