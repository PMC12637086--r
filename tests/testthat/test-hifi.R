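test_that("find_high_mode locates the rightmost qualifying mode", {
  set.seed(91)
  ## unimodal: the mode is the center
  expect_equal(find_high_mode(rnorm(2000, 2, 0.1)), 2, tolerance = 0.05)
  ## 90/10 mixture: returns the rare high mode, not the tall low one
  x <- c(rnorm(1800, 0.1, 0.1), rnorm(200, 1.5, 0.1))
  expect_equal(as.numeric(find_high_mode(x)), 1.5, tolerance = 0.1)
  expect_error(find_high_mode(numeric()), "empty")
})

test_that("scale_markers centers positive populations at one, gated for rare markers", {
  h <- simulate_hifi_intensities(5000, hifi_composition(), hifi_panel(),
                                 hifi_modes(), seed = 92)
  sc <- scale_markers(h$intensities,
                      gating = c(CD3 = "CD45", CD8 = "CD3",
                                 IBA1 = "CD45", F480 = "IBA1"))
  for (m in names(hifi_modes())) {
    pos_types <- names(hifi_panel())[vapply(hifi_panel(),
                                            function(p) m %in% p, TRUE)]
    v <- sc$scaled[[m]][h$true_type %in% pos_types]
    expect_equal(as.numeric(find_high_mode(v)), 1, tolerance = 0.1,
                 label = paste("scaled positive mode of", m))
  }

  ## rare child marker: ungated mode search lands on the negative mode,
  ## gating on the parent recovers the true positive mode
  rare <- simulate_hifi_intensities(
    4000, c(A = 0.98, B = 0.02),
    panel = list(A = character(), B = c("parent", "child")),
    mode_locations = list(parent = c(0.1, 1.4), child = c(0.1, 1.5)),
    seed = 93)
  ungated <- scale_markers(rare$intensities)
  gated <- scale_markers(rare$intensities, gating = c(child = "parent"))
  expect_lt(ungated$modes[["child"]], 0.5)     # stuck on the negative mode
  expect_true(ungated$fallback[["child"]])
  expect_equal(gated$modes[["child"]], 1.5, tolerance = 0.15)

  ## an all-negative marker stays far below 1 and is flagged
  neg <- simulate_hifi_intensities(
    1000, c(A = 1), panel = list(A = character()),
    mode_locations = list(m = c(0.1, 1.5)), seed = 94)
  scn <- scale_markers(neg$intensities)
  expect_true(scn$fallback[["m"]])
  ## the population mode stays far below the positive level of 1
  expect_lt(as.numeric(find_high_mode(scn$scaled$m)), 0.5)
  expect_lt(stats::median(scn$scaled$m), 0.5)
  ## scaling is invariant to multiplying the raw channel by a constant
  h2 <- h$intensities
  h2$SOX9 <- h2$SOX9 * 7
  sc2 <- scale_markers(h2, gating = c(CD3 = "CD45", CD8 = "CD3",
                                      IBA1 = "CD45", F480 = "IBA1"))
  pos <- h$true_type == "cancer"
  expect_equal(stats::median(sc2$scaled$SOX9[pos]),
               stats::median(sc$scaled$SOX9[pos]), tolerance = 0.1)
})

test_that("the imaging neighborhood-size rule follows k = max(round(n/1000), 10)", {
  expect_identical(hifi_k_neighbors(5000), 10L)   # max(5, 10)
  expect_identical(hifi_k_neighbors(50000), 50L)
  expect_identical(hifi_k_neighbors(100), 10L)
})

test_that("clustering plus rule-based annotation recovers planted cell types", {
  h <- simulate_hifi_intensities(5000, hifi_composition(), hifi_panel(),
                                 hifi_modes(), seed = 95)
  sc <- scale_markers(h$intensities,
                      gating = c(CD3 = "CD45", CD8 = "CD3",
                                 IBA1 = "CD45", F480 = "IBA1"))
  cl <- cluster_hifi(sc$scaled, seed = 96)
  expect_identical(cl$k, 10L)
  ann <- annotate_hifi(cl$labels, sc$scaled, hifi_rules())
  truth <- h$true_type[match(names(cl$labels), h$intensities$cell_id)]
  expect_gte(mean(ann$cell_type == truth), 0.9)

  ## a cluster positive for a marker outside every rule is undetermined
  odd <- data.frame(cell_id = paste0("x", 1:60),
                    SOX9 = rep(1, 60), weird = rep(1, 60))
  rules <- list(cancer = list(necessary = "SOX9", possible = character()))
  ann2 <- annotate_hifi(stats::setNames(rep(1L, 60), odd$cell_id), odd,
                        rules)
  expect_equal(unname(ann2$cluster_type), "undetermined")

  ## two matching rules: undetermined with a warning, never guessed
  amb <- data.frame(cell_id = paste0("y", 1:60), m1 = rep(1, 60))
  rules2 <- list(t1 = list(necessary = "m1", possible = character()),
                 t2 = list(necessary = "m1", possible = character()))
  expect_warning(
    ann3 <- annotate_hifi(stats::setNames(rep(1L, 60), amb$cell_id),
                          amb, rules2),
    "multiple types")
  expect_equal(unname(ann3$cluster_type), "undetermined")
})

test_that("compare_compositions correlates log fractions with a floor for absences", {
  f <- c(a = 0.5, b = 0.3, c = 0.2)
  expect_equal(compare_compositions(f, f)$r, 1)

  ## both modalities sampling one truth: high correlation
  set.seed(97)
  truth <- c(a = 0.4, b = 0.3, c = 0.15, d = 0.1, e = 0.05)
  h <- prop.table(table(factor(sample(names(truth), 2000, TRUE, truth),
                               levels = names(truth))))
  s <- prop.table(table(factor(sample(names(truth), 2000, TRUE, truth),
                               levels = names(truth))))
  cc <- compare_compositions(stats::setNames(as.numeric(h), names(truth)),
                             stats::setNames(as.numeric(s), names(truth)))
  expect_gte(cc$r, 0.9)

  ## a type absent from one modality gets the flagged pseudo-floor
  cc2 <- compare_compositions(c(a = 0.7, b = 0.3), c(a = 0.6, b = 0.3,
                                                     z = 0.1))
  expect_true(cc2$table$floored[cc2$table$type == "z"])
  expect_true(all(is.finite(cc2$table$log_hifi)))
})
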