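test_that("default patterns cover the vocabulary with the stated shapes", {
  pats <- default_patterns()
  expect_setequal(unique(pats$label), training_classes())
  expect_equal(nrow(pats), 9 * 4 * 23)

  curve <- function(cls, band) {
    pats$mean[pats$label == cls & pats$band == band][order(
      pats$step[pats$label == cls & pats$band == band])]
  }
  expect_gte(min(curve("forest", "ndvi")), 0.7)
  expect_equal(n_local_maxima_above(curve("soy-corn", "ndvi"), 0.6), 2)
  expect_equal(n_local_maxima_above(curve("soy-cotton", "ndvi"), 0.6), 2)
  expect_equal(n_local_maxima_above(curve("soy-fallow", "ndvi"), 0.55), 1)
  expect_equal(n_local_maxima_above(curve("fallow-cotton", "ndvi"), 0.55), 1)
  # MIR roughly anti-phase to NDVI for every class
  for (cls in training_classes()) {
    expect_lt(stats::cor(curve(cls, "ndvi"), curve(cls, "mir")), -0.9)
  }
  # forest NDVI nearly constant, pasture clearly seasonal
  expect_lt(diff(range(curve("forest", "ndvi"))), 0.1)
  expect_gt(diff(range(curve("pasture", "ndvi"))), 0.25)
})

test_that("generate_samples respects counts, labels, ranges and the seed", {
  s <- generate_samples(n_per_class = 50, mislabel_rate = 0, seed = 5)
  expect_equal(nrow(s), 450)
  expect_identical(s$label, s$true_label)
  expect_equal(as.vector(table(s$label)[training_classes()]), rep(50L, 9))
  vals <- as.matrix(s[, lucmap:::band_columns()])
  expect_true(all(vals[, 1:46] >= -1 & vals[, 1:46] <= 1))

  expect_identical(generate_samples(n_per_class = 10, seed = 9),
                   generate_samples(n_per_class = 10, seed = 9))
  expect_error(generate_samples(n_per_class = 0), "positive")
})

test_that("mislabel injection matches its binomial model", {
  s <- generate_samples(n_per_class = 200, mislabel_rate = 0.1, seed = 17)
  n_wrong <- sum(s$label != s$true_label)
  # central 99% interval of Binom(1800, 0.1): qbinom(c(.005, .995)) = 148, 214
  expect_gte(n_wrong, 148)
  expect_lte(n_wrong, 214)
  # relabels always move to a different class
  expect_false(any(s$label[s$label != s$true_label] ==
                     s$true_label[s$label != s$true_label]))
})

test_that("the separable limit is exactly classifiable by nearest pattern", {
  pats <- dplyr::mutate(default_patterns(), noise_sd = 0)
  s <- generate_samples(pats, n_per_class = 3, seed = 1)
  X <- sample_features(s)
  # independent oracle: nearest mean curve, built from the pattern tibble
  pm <- t(vapply(training_classes(), function(cls) {
    p <- dplyr::arrange(dplyr::filter(pats, label == cls),
                        match(band, c("ndvi", "evi", "nir", "mir")), step)
    p$mean
  }, numeric(92)))
  d2 <- outer(rowSums(X^2), rowSums(pm^2), `+`) - 2 * X %*% t(pm)
  pred <- training_classes()[max.col(-d2)]
  expect_identical(pred, s$true_label)
})

test_that("generate_scene honors the shape, truth and determinism contracts", {
  spec <- scene_spec(width = 20, height = 20, years = 2015:2016,
                     patches = list(list(rect = c(1, 20, 1, 20),
                                         labels = "forest")),
                     seed = 4)
  sc <- generate_scene(spec)
  expect_length(sc$cube, 2)
  expect_identical(dim(sc$cube[["2015"]]), c(4L, 23L, 20L, 20L))
  expect_true(all(unclass(sc$truth[["2015"]]) == class_code("forest")))
  expect_identical(attr(sc$truth[["2016"]], "year"), 2016L)

  sc2 <- generate_scene(spec)
  expect_identical(sc$cube, sc2$cube)
  expect_identical(sc$truth, sc2$truth)
})

test_that("scene reference layers and masks match the declared layout", {
  sc <- generate_scene(default_scene_spec(years = 2015:2016, seed = 2))
  am <- sc$ref$amazon
  cr <- sc$ref$cerrado
  # at most one non-absent reference value per pixel
  expect_true(all(!(am > 0 & cr > 0)))
  # amazon layer: forest truth -> Forest, deforestation rect declared
  t1 <- unclass(sc$truth[[1]])
  expect_true(all(am[t1 == class_code("forest") & am > 0] %in% c(1L, 3L)))
  expect_true(any(am == 3L))
  # masks disjoint
  expect_equal(max(sc$masks$water + sc$masks$urban + sc$masks$sugarcane), 1)
  expect_error(
    scene_spec(width = 10, height = 10, years = 2015,
               water_rect = c(1, 3, 1, 3), urban_rect = c(2, 4, 2, 4)),
    "overlap"
  )
  expect_error(
    scene_spec(width = 10, height = 10, years = 2015,
               patches = list(list(rect = c(1, 12, 1, 5), labels = "forest"))),
    "bounds"
  )
})
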