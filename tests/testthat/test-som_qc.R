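test_that("SOM training contracts to a single input and is deterministic", {
  s <- flat_samples("forest", 0.5, 1, sd = 0)
  X <- sample_features(s)
  som <- train_som(X, xdim = 1, ydim = 1, epochs = 50, seed = 1)
  expect_lt(max(abs(som$weights - 0.5)), 1e-3)

  s2 <- generate_samples(n_per_class = 5, seed = 8)
  X2 <- sample_features(s2)
  a <- train_som(X2, xdim = 3, ydim = 3, epochs = 20, seed = 7)
  b <- train_som(X2, xdim = 3, ydim = 3, epochs = 20, seed = 7)
  expect_identical(a$weights, b$weights)
  expect_error(train_som(X2, xdim = 0, ydim = 2), ">= 1")
})

test_that("a 2x1 SOM on two separated clusters recovers both cluster means", {
  ss <- flat_samples(c("forest", "pasture"), c(0.2, 0.8), 30, sd = 0.01,
                     seed = 3)
  som <- train_som(sample_features(ss), xdim = 2, ydim = 1, seed = 3)
  w <- som$weights
  dev <- function(row) min(max(abs(w[row, ] - 0.2)), max(abs(w[row, ] - 0.8)))
  expect_lt(dev(1), 3 * 0.01)
  expect_lt(dev(2), 3 * 0.01)
  # the two neurons settle on distinct clusters
  expect_gt(abs(mean(w[1, ]) - mean(w[2, ])), 0.3)
})

test_that("neurons take the majority label; ties go to the globally larger class", {
  # hand-built SOM: neuron 1 near 0.2, neuron 2 near 0.8
  som <- structure(list(weights = rbind(rep(0.2, 92), rep(0.8, 92)),
                        xdim = 2L, ydim = 1L, neuron_labels = NULL),
                   class = "luc_som")
  s <- flat_samples(c("pasture", "pasture", "pasture", "forest"),
                    c(0.19, 0.21, 0.2, 0.22), 1)
  som1 <- label_neurons(som, s)
  expect_identical(som1$neuron_labels[1], "pasture")  # 3 pasture vs 1 forest
  expect_true(is.na(som1$neuron_labels[2]))           # no mapped samples

  # 2 pasture vs 2 cerrado at the neuron; cerrado globally more frequent
  s2 <- flat_samples(c("pasture", "pasture", "cerrado", "cerrado",
                       "cerrado", "cerrado"),
                     c(0.2, 0.2, 0.2, 0.2, 0.8, 0.8), 1)
  som2 <- label_neurons(som, s2)
  expect_identical(som2$neuron_labels[1], "cerrado")
})

test_that("reliability frequencies are exact for separable clusters", {
  ss <- flat_samples(c("cerrado", "forest", "pasture"), c(0.2, 0.5, 0.8),
                     50, sd = 0.01, seed = 6)
  rel <- evaluate_samples(ss, n_runs = 10, epochs = 30, seed = 20)
  # frequencies sum to 1 per sample
  sums <- dplyr::summarise(dplyr::group_by(rel, sample_id),
                           s = sum(frequency))
  expect_equal(sums$s, rep(1, 150), tolerance = 1e-9)
  own <- dplyr::filter(rel, cluster_label == original_label)
  expect_equal(nrow(own), 150)
  expect_equal(own$frequency, rep(1, 150))
})

test_that("a relabelled sample is clustered with its true class", {
  ss <- flat_samples(c("cerrado", "forest", "pasture"), c(0.2, 0.5, 0.8),
                     50, sd = 0.01, seed = 6)
  ss$label[1] <- "pasture"  # a 0.2-cluster sample claimed to be the 0.8 class
  rel <- evaluate_samples(ss, n_runs = 10, epochs = 30, seed = 21)
  own1 <- dplyr::filter(rel, sample_id == 1, cluster_label == "pasture")
  expect_lte(ifelse(nrow(own1) == 0, 0, own1$frequency), 0.2)
  qc <- filter_samples(rel, ss, threshold = 0.8)
  expect_false(1 %in% qc$detail$sample_id[qc$detail$retained])
})

test_that("filtering is a partition, respects the boundary and is monotone", {
  rel <- tibble::tibble(
    sample_id = c(1L, 2L, 2L, 3L, 3L),
    original_label = c("pasture", "pasture", "pasture", "pasture", "pasture"),
    cluster_label = c("pasture", "pasture", "cerrado", "cerrado", "pasture"),
    frequency = c(1, 0.80, 0.20, 0.95, 0.05)
  )
  s <- flat_samples(rep("pasture", 3), c(0.2, 0.3, 0.4), 1)
  out <- filter_samples(rel, s, threshold = 0.8)
  # frequency exactly 0.80 is retained ("at least 80%")
  expect_identical(out$detail$retained, c(TRUE, TRUE, FALSE))
  expect_equal(nrow(out$retained) + nrow(out$removed), 3)
  expect_equal(dplyr::bind_rows(out$retained, out$removed)[
    order(c(which(out$detail$retained), which(!out$detail$retained))), ],
    s)
  # monotonicity in the threshold
  kept <- vapply(seq(0.05, 1, by = 0.05), function(th) {
    nrow(filter_samples(rel, s, threshold = th)$retained)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
  expect_error(filter_samples(rel, s, threshold = 0), "threshold")
})

test_that("qc_report arithmetic matches its definition", {
  rep1 <- qc_report(200, 150)
  expect_equal(rep1$n_removed, 50L)
  expect_equal(rep1$pct_reduction, 25.0)
})
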