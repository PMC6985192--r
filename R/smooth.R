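#' Bayesian neighborhood smoothing of class probabilities
#'
#' Pixel-wise classification leaves salt-and-pepper noise where the
#' classifier is unsure. Smoothing borrows strength from the neighborhood:
#' for every class, each pixel's class score is combined with the mean of
#' its neighbors' scores, weighted by how much the neighbors agree among
#' themselves. Scores are class logits (log-odds of the class
#' probabilities), which makes the Gaussian conjugate update well-posed:
#' with `x` the pixel's logit, `m` and `s2` the mean and sample variance of
#' the logits over the Chebyshev-radius neighborhood excluding the center,
#' the posterior logit is
#'
#' \deqn{(s2 x + \sigma^2 m) / (s2 + \sigma^2).}
#'
#' `sigma2 = 0` leaves every posterior unchanged (no smoothing); larger
#' `sigma2` pulls pixels toward their neighborhood mean; a large neighbor
#' variance `s2` (neighbors disagree) protects the pixel's own value. When
#' the neighbors are unanimous (`s2 = 0`) and `sigma2 > 0` the pixel adopts
#' the neighborhood mean outright. Labels are then re-derived as the argmax
#' of the posterior logits and the smoothed probabilities are the
#' renormalized inverse logits.
#'
#' @param probs Probabilities in \[0, 1\].
#' @param epsilon Clamp applied before the log-odds transform, so that hard
#'   0/1 probabilities stay finite.
#' @return `to_logits()`: log-odds `log(p / (1 - p))` after clamping `p` to
#'   `[epsilon, 1 - epsilon]`; `to_probs()` is its inverse on that range.
#' @export
to_logits <- function(probs, epsilon = 1e-6) {
  p <- clamp(probs, epsilon, 1 - epsilon)
  log(p / (1 - p))
}

#' @rdname to_logits
#' @param logits Real-valued log-odds.
#' @export
to_probs <- function(logits) 1 / (1 + exp(-logits))

# Shift a matrix by (dr, dc) with NA padding outside the raster.
#' @keywords internal
shift_matrix <- function(M, dr, dc) {
  H <- nrow(M); W <- ncol(M)
  out <- matrix(NA_real_, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- M[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Smooth a probability cube
#'
#' @param cube A [prob_cube()].
#' @param sigma2 Nonnegative global smoothness parameter \eqn{\sigma^2}
#'   (default 10); 0 disables smoothing.
#' @param radius Chebyshev neighborhood radius (default 1, a 3 x 3 window);
#'   the window is truncated at raster edges and always excludes the center
#'   pixel. Neighbor variance uses the n - 1 denominator.
#' @param epsilon Probability clamp for the log-odds transform.
#' @return A list with `probs` (smoothed, renormalized [prob_cube()]) and
#'   `map` (argmax [class_map()], ties toward the lowest class code).
#' @export
smooth_cube <- function(cube, sigma2 = 10, radius = 1, epsilon = 1e-6) {
  stopifnot(inherits(cube, "luc_prob_cube"), sigma2 >= 0, radius >= 1)
  H <- dim(cube)[1]; W <- dim(cube)[2]; K <- dim(cube)[3]
  labels <- attr(cube, "class_labels")
  year <- attr(cube, "year")

  offsets <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offsets <- offsets[!(offsets$dr == 0 & offsets$dc == 0), ]
  ones <- matrix(1, H, W)
  n_nb <- Reduce(`+`, purrr::map2(offsets$dr, offsets$dc, function(dr, dc) {
    v <- shift_matrix(ones, dr, dc)
    v[is.na(v)] <- 0
    v
  }))

  post <- array(NA_real_, dim = c(H, W, K))
  for (k in seq_len(K)) {
    x <- to_logits(unclass(cube)[, , k], epsilon)
    s <- matrix(0, H, W); ss <- matrix(0, H, W)
    for (o in seq_len(nrow(offsets))) {
      v <- shift_matrix(x, offsets$dr[o], offsets$dc[o])
      v[is.na(v)] <- 0
      s <- s + v
      ss <- ss + v^2
    }
    m <- s / pmax(n_nb, 1)
    m[n_nb == 0] <- x[n_nb == 0]  # degenerate 1x1 raster: no neighbors
    s2 <- pmax((ss - n_nb * m^2) / pmax(n_nb - 1, 1), 0)
    denom <- s2 + sigma2
    post[, , k] <- ifelse(denom > 0, (s2 * x + sigma2 * m) / denom, x)
  }

  flat <- matrix(post, nrow = H * W, ncol = K)
  cls <- labels[max.col(flat, ties.method = "first")]
  p <- to_probs(flat)
  p <- p / rowSums(p)
  list(probs = prob_cube(array(p, dim = c(H, W, K)), year, labels),
       map = class_map(matrix(class_code(cls), H, W), year))
}

#' Per-pixel classification confidence
#'
#' Confidence is the margin between the largest and second-largest class
#' probability of a pixel: 1 for a one-hot pixel, 0 for a uniform one. Low
#' margins are typical of borders and mixed pixels, which is where smoothing
#' is allowed to act.
#'
#' @param cube A [prob_cube()].
#' @return An H x W numeric matrix of margins in \[0, 1\].
#' @export
confidence_map <- function(cube) {
  stopifnot(inherits(cube, "luc_prob_cube"))
  H <- dim(cube)[1]; W <- dim(cube)[2]; K <- dim(cube)[3]
  flat <- matrix(unclass(cube), nrow = H * W, ncol = K)
  top <- apply(flat, 1, function(p) {
    s <- sort(p, decreasing = TRUE)
    s[1] - ifelse(K >= 2, s[2], 0)
  })
  matrix(top, H, W)
}
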