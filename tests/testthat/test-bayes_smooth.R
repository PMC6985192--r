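test_that("logit transform matches its closed form and inverts", {
  expect_equal(to_logits(0.5), 0)
  expect_equal(to_logits(0, epsilon = 1e-6), log(1e-6) - log1p(-1e-6))
  expect_equal(to_logits(0, epsilon = 1e-6), -13.81551, tolerance = 1e-6)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(to_probs(to_logits(p)), p, tolerance = 1e-12)
})

test_that("sigma2 = 0 leaves labels unchanged on random cubes", {
  for (seed in 1:5) {
    cube <- random_prob_cube(8, 8, 4, seed = seed)
    out <- smooth_cube(cube, sigma2 = 0)
    raw_labels <- apply(unclass(cube), c(1, 2), which.max)
    expect_identical(bare(out$map),
                     matrix(class_code(attr(cube, "class_labels")[raw_labels]),
                            8, 8))
    # identity up to the epsilon clamp of the logit transform
    expect_lt(max(abs(unclass(out$probs) - unclass(cube))), 1e-5)
  }
})

test_that("spatially constant cubes are fixed points for any sigma2", {
  a <- array(rep(c(0.6, 0.3, 0.1), each = 36), dim = c(6, 6, 3))
  cube <- prob_cube(a, 2015, training_classes()[1:3])
  for (s2 in c(0, 1, 10, 100)) {
    out <- smooth_cube(cube, sigma2 = s2)
    expect_lt(max(abs(bare(out$probs) - a)), 1e-9)
    expect_true(all(unclass(out$map) == class_code("cerrado")))
  }
})

test_that("a unanimous neighborhood flips a low-confidence center", {
  # center (0.45, 0.55), all 8 neighbors (0.9, 0.1): neighbor logits are
  # constant so s2 = 0 and the posterior equals the neighborhood mean
  a <- array(NA_real_, dim = c(3, 3, 2))
  a[, , 1] <- 0.9; a[, , 2] <- 0.1
  a[2, 2, ] <- c(0.45, 0.55)
  cube <- prob_cube(a, 2015, c("cerrado", "forest"))
  out <- smooth_cube(cube, sigma2 = 10)
  expect_identical(unclass(out$map)[2, 2], class_code("cerrado"))
  # posterior logit of the center equals m = logit(0.9) exactly
  expect_equal(unclass(out$probs)[2, 2, 1] / sum(unclass(out$probs)[2, 2, ]),
               0.9, tolerance = 1e-9)
})

test_that("posterior weights move monotonically with sigma2 and s2", {
  # neighbor logits m +/- delta: the mean m stays fixed while the
  # neighborhood variance s2 grows with delta
  m <- log(0.8 / 0.2)
  mk <- function(delta) {
    a <- array(NA_real_, dim = c(3, 3, 2))
    nb <- to_probs(m + delta * c(-1, 1, -1, 1, -1, 1, -1, 1))
    k <- 1
    for (j in 1:3) for (i in 1:3) {
      if (i == 2 && j == 2) next
      a[i, j, ] <- c(nb[k], 1 - nb[k]); k <- k + 1
    }
    a[2, 2, ] <- c(0.1, 0.9)
    prob_cube(a, 2015, c("cerrado", "forest"))
  }
  # in a mirrored 2-class cube the renormalized posterior reproduces the
  # class-1 posterior logit exactly: log(sigmoid(l)/sigmoid(-l)) = l
  center_logit <- function(cube, sigma2) {
    p <- unclass(smooth_cube(cube, sigma2 = sigma2)$probs)[2, 2, ]
    log(p[1] / p[2])
  }
  cube <- mk(0.5)
  lg <- vapply(c(0.1, 1, 10, 100), function(s) center_logit(cube, s),
               numeric(1))
  # increasing sigma2 pulls the posterior monotonically toward m (> x here)
  expect_true(all(diff(lg) > 0))
  expect_true(all(lg < m + 1e-6))
  # increasing neighbor variance keeps more of the original value x
  lg_s2 <- vapply(c(0.1, 0.5, 1, 2), function(d) center_logit(mk(d), 10),
                  numeric(1))
  expect_true(all(diff(lg_s2) < 0))  # pulled back toward x = logit(0.1) < 0
})

test_that("smoothing never relabels the confident interior of a patch", {
  set.seed(42)
  h <- 12; w <- 12
  a <- array(NA_real_, dim = c(h, w, 2))
  left <- cbind(rep(TRUE, h), matrix(rep(c(TRUE, FALSE), each = h * 5),
                                     h, 10), rep(FALSE, h))
  p1 <- ifelse(left, 0.88, 0.12) + stats::runif(h * w, -0.05, 0.05)
  a[, , 1] <- p1; a[, , 2] <- 1 - p1
  cube <- prob_cube(a, 2015, c("cerrado", "forest"))
  out <- smooth_cube(cube, sigma2 = 10)
  before <- apply(unclass(cube), c(1, 2), which.max)
  after <- apply(unclass(out$probs), c(1, 2), which.max)
  changed <- which(before != after, arr.ind = TRUE)
  if (nrow(changed) > 0) {
    expect_true(all(abs(changed[, 2] - 6.5) <= 1))  # within 1 px of border
  }
  expect_identical(dim(unclass(out$probs)), dim(a))
})

test_that("confidence is the top-two probability margin", {
  a <- array(NA_real_, dim = c(1, 3, 3))
  a[1, 1, ] <- c(1, 0, 0)
  a[1, 2, ] <- rep(1 / 3, 3)
  a[1, 3, ] <- c(0.55, 0.45, 0)
  cube <- prob_cube(a, 2015, training_classes()[1:3])
  cm <- confidence_map(cube)
  expect_equal(cm[1, ], c(1, 0, 0.10), tolerance = 1e-9)
})
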