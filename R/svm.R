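#' SVM configuration
#'
#' Defaults follow the mapping method: an RBF kernel with cost `C = 1` and
#' width `gamma = 1/92` (one over the feature dimension, on the raw physical
#' feature scale), evaluated by stratified 5-fold cross-validation.
#'
#' @param C Positive soft-margin cost.
#' @param gamma Positive RBF width.
#' @param k_folds Folds for cross-validation (>= 2).
#' @param seed Integer seed (stratified fold assignment and probability
#'   calibration splits).
#' @return A `luc_svm_config` list.
#' @export
svm_config <- function(C = 1, gamma = 1 / 92, k_folds = 5, seed = 1L) {
  stopifnot(C > 0, gamma > 0, k_folds >= 2)
  structure(list(C = C, gamma = gamma, k_folds = as.integer(k_folds),
                 seed = as.integer(seed)),
            class = "luc_svm_config")
}

# ---- kernel and binary solver -----------------------------------------

#' @keywords internal
rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Soft-margin binary SVM dual, solved as a box-constrained QP.
# K: kernel matrix of the pair's samples; y in {-1, +1}.
#' @keywords internal
svm_binary_fit <- function(K, y, C) {
  n <- length(y)
  ridge <- 1e-8 * mean(diag(K))
  Dmat <- (y %o% y) * K + diag(ridge, n)
  Amat <- cbind(y, diag(n), -diag(n))
  bvec <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat, rep(1, n), Amat, bvec, meq = 1)
  alpha <- sol$solution
  alpha[alpha < 1e-8 * C] <- 0
  alpha[alpha > C * (1 - 1e-8)] <- C
  sv <- which(alpha > 0)
  coef <- alpha[sv] * y[sv]
  g <- as.vector(K[, sv, drop = FALSE] %*% coef)
  free <- which(alpha > 0 & alpha < C)
  b <- if (length(free) > 0) {
    mean(y[free] - g[free])
  } else {
    # no free vectors: the KKT conditions bracket b between
    #   max over {y=+1, alpha=0} u {y=-1, alpha=C} of (y - g)  and
    #   min over {y=+1, alpha=C} u {y=-1, alpha=0} of (y - g)
    lo <- suppressWarnings(max(c((1 - g)[y == +1 & alpha == 0],
                                 (-1 - g)[y == -1 & alpha == C])))
    hi <- suppressWarnings(min(c((1 - g)[y == +1 & alpha == C],
                                 (-1 - g)[y == -1 & alpha == 0])))
    if (!is.finite(lo)) lo <- hi
    if (!is.finite(hi)) hi <- lo
    (lo + hi) / 2
  }
  list(sv = sv, coef = coef, b = b)
}

# Platt sigmoid P(y=1|f) = 1 / (1 + exp(A f + B)) fitted by Newton descent
# with the usual smoothed targets.
#' @keywords internal
platt_fit <- function(f, y) {
  prior1 <- sum(y > 0)
  prior0 <- sum(y <= 0)
  hi <- (prior1 + 1) / (prior1 + 2)
  lo <- 1 / (prior0 + 2)
  t <- ifelse(y > 0, hi, lo)
  A <- 0
  B <- log((prior0 + 1) / (prior1 + 1))
  fval <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  fv <- fval(A, B)
  for (it in 1:100) {
    z <- A * f + B
    p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      nA <- A + step * dA
      nB <- B + step * dB
      nf <- fval(nA, nB)
      if (nf < fv + 1e-4 * step * gd) {
        A <- nA; B <- nB; fv <- nf
        break
      }
      step <- step / 2
      if (step < 1e-10) return(c(A = A, B = B))
    }
  }
  c(A = A, B = B)
}

# Stratified fold assignment (seed handled by the caller's RNG state).
#' @keywords internal
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# ---- multiclass training ----------------------------------------------

#' Train the one-vs-one RBF-SVM classifier
#'
#' Trains a support vector machine on quality-controlled samples in the
#' 92-dimensional feature space, with a radial-basis-function kernel. The
#' multiclass decomposition is one-vs-one: one soft-margin binary SVM per
#' class pair, each solved exactly as a quadratic program. Class
#' probabilities come from a Platt sigmoid per pair - fitted on held-out
#' decision values from an internal 3-fold split so the sigmoid is not fit
#' on optimistically separated training scores - combined across pairs by
#' iterative pairwise coupling into a probability vector that sums to 1.
#'
#' @param samples Validated sample tibble with at least two classes.
#' @param config An [svm_config()].
#' @return A `luc_svm` model object.
#' @export
train_svm <- function(samples, config = svm_config()) {
  samples <- validate_samples(samples)
  X <- sample_features(samples)
  classes <- intersect(training_classes(), unique(samples$label))
  if (length(classes) < 2) {
    stop("need samples from at least two classes", call. = FALSE)
  }
  y <- samples$label
  with_seed(config$seed, {
    pairs <- utils::combn(classes, 2, simplify = FALSE)
    models <- purrr::map(pairs, function(pr) {
      idx <- which(y %in% pr)
      Xi <- X[idx, , drop = FALSE]
      yi <- ifelse(y[idx] == pr[1], 1, -1)
      K <- rbf_kernel(Xi, Xi, config$gamma)
      fit <- svm_binary_fit(K, yi, config$C)
      # held-out decision values for sigmoid calibration
      n_min <- min(table(yi))
      dec <- rep(NA_real_, length(yi))
      if (n_min >= 3) {
        fold <- stratified_folds(yi, 3)
        for (fd in 1:3) {
          tr <- fold != fd
          ft <- svm_binary_fit(K[tr, tr, drop = FALSE], yi[tr], config$C)
          dec[!tr] <- as.vector(
            K[!tr, which(tr)[ft$sv], drop = FALSE] %*% ft$coef) + ft$b
        }
      } else {
        dec <- as.vector(K[, fit$sv, drop = FALSE] %*% fit$coef) + fit$b
      }
      sig <- platt_fit(dec, yi)
      list(classes = pr, sv_x = Xi[fit$sv, , drop = FALSE], coef = fit$coef,
           b = fit$b, A = sig[["A"]], B = sig[["B"]])
    })
    structure(list(classes = classes, pairs = models, config = config),
              class = "luc_svm")
  })
}

# Pairwise-coupled class probabilities for a feature matrix; returns an
# n x K matrix (columns in model class order).
#' @keywords internal
svm_prob_matrix <- function(model, X) {
  classes <- model$classes
  K <- length(classes)
  n <- nrow(X)
  r <- array(0, dim = c(n, K, K))
  for (pm in model$pairs) {
    i <- match(pm$classes[1], classes)
    j <- match(pm$classes[2], classes)
    f <- as.vector(rbf_kernel(X, pm$sv_x, model$config$gamma) %*% pm$coef) +
      pm$b
    pij <- 1 / (1 + exp(pm$A * f + pm$B))
    pij <- clamp(pij, 1e-7, 1 - 1e-7)
    r[, i, j] <- pij
    r[, j, i] <- 1 - pij
  }
  couple_pairwise(r)
}

# Iterative pairwise coupling (the standard second coupling method),
# vectorized across instances.
#' @keywords internal
couple_pairwise <- function(r) {
  n <- dim(r)[1]
  K <- dim(r)[2]
  if (K == 2) {
    p <- cbind(r[, 1, 2], r[, 2, 1])
    return(p / rowSums(p))
  }
  Q <- array(0, dim = c(n, K, K))
  for (t in 1:K) {
    for (u in 1:K) {
      if (t == u) {
        s <- matrix(0, n, 1)
        for (j in setdiff(1:K, t)) s <- s + r[, j, t]^2
        Q[, t, t] <- s
      } else {
        Q[, t, u] <- -r[, u, t] * r[, t, u]
      }
    }
  }
  p <- matrix(1 / K, n, K)
  Qp <- matrix(0, n, K)
  for (iter in 1:200) {
    for (t in 1:K) {
      Qp[, t] <- rowSums(Q[, t, ] * p)
    }
    pQp <- rowSums(p * Qp)
    max_err <- max(abs(Qp - pQp))
    if (max_err < 1e-7) break
    for (t in 1:K) {
      diff <- (-Qp[, t] + pQp) / Q[, t, t]
      p[, t] <- p[, t] + diff
      pQp <- (pQp + diff * (diff * Q[, t, t] + 2 * Qp[, t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t, ]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p / rowSums(p)
}

#' Predict classes and probabilities from a trained SVM
#'
#' @param object A `luc_svm` model.
#' @param new_data A sample tibble or a numeric feature matrix (n x 92).
#' @param ... Unused.
#' @return A tibble with the predicted class (`.pred_class`, ties broken
#'   toward the lowest class code) and one `.pred_<class>` probability
#'   column per class; probabilities sum to 1 per row.
#' @export
predict.luc_svm <- function(object, new_data, ...) {
  X <- if (is.matrix(new_data)) new_data else sample_features(new_data)
  if (ncol(X) != 92L) stop("features must have 92 columns", call. = FALSE)
  p <- svm_prob_matrix(object, X)
  # model classes follow vocabulary (code) order, so ties.method = "first"
  # breaks argmax ties toward the lowest class code
  cls <- object$classes[max.col(p, ties.method = "first")]
  out <- tibble::as_tibble(p, .name_repair = "minimal")
  names(out) <- paste0(".pred_", object$classes)
  dplyr::bind_cols(tibble::tibble(.pred_class = cls), out)
}

# ---- cross-validation -------------------------------------------------

#' Stratified k-fold cross-validation of the SVM
#'
#' Splits the samples into `k_folds` stratified folds (classes with fewer
#' members than folds trigger a warning and a non-stratified assignment for
#' those samples), trains on each fold complement, predicts the held-out
#' fold, and pools the held-out predictions into one confusion matrix.
#'
#' @inheritParams train_svm
#' @return A `luc_cv` list: `overall` accuracy, `by_class` tibble (user's
#'   and producer's accuracy), and the pooled `confusion` matrix.
#' @export
cross_validate <- function(samples, config = svm_config()) {
  samples <- validate_samples(samples)
  k <- config$k_folds
  if (k > nrow(samples)) stop("more folds than samples", call. = FALSE)
  counts <- table(samples$label)
  if (any(counts < k)) {
    warning("class(es) with fewer members than folds: ",
            paste(names(counts)[counts < k], collapse = ", "),
            "; their samples are assigned to folds unstratified")
  }
  with_seed(config$seed, {
    fold <- integer(nrow(samples))
    strat <- samples$label %in% names(counts)[counts >= k]
    fold[strat] <- stratified_folds(samples$label[strat], k)
    if (any(!strat)) {
      fold[!strat] <- sample(rep_len(seq_len(k), sum(!strat)))
    }
    pred <- character(nrow(samples))
    for (fd in seq_len(k)) {
      hold <- fold == fd
      fit <- train_svm(samples[!hold, , drop = FALSE], config)
      pred[hold] <- predict(fit, samples[hold, , drop = FALSE])$.pred_class
    }
    cm <- confusion(pred, samples$label)
    acc <- accuracies(cm)
    structure(list(overall = acc$overall, by_class = acc$by_class,
                   confusion = cm, k_folds = k),
              class = "luc_cv")
  })
}

# ---- raster classification --------------------------------------------

#' Per-class probability cubes
#'
#' @param probs An H x W x K array of per-pixel class probabilities (each
#'   pixel's vector sums to 1).
#' @param year Map year.
#' @param class_labels Character vector of the K class labels (column
#'   order of the probability planes).
#' @return A `luc_prob_cube` object.
#' @export
prob_cube <- function(probs, year, class_labels) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[3] == length(class_labels))
  sums <- apply(probs, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("pixel probabilities must sum to 1", call. = FALSE)
  }
  structure(probs, year = as.integer(year), class_labels = class_labels,
            class = c("luc_prob_cube", "array"))
}

#' Classify a raster cube into class probabilities and labels
#'
#' Builds each pixel's 92-dimensional feature vector exactly as for training
#' samples and predicts per-class probabilities with the trained SVM; the
#' label map is the per-pixel argmax with ties broken toward the lowest
#' class code.
#'
#' @param model A `luc_svm`.
#' @param cube A 4 band x 23 step x H x W array (one year of a scene cube).
#' @param year Map year for the outputs.
#' @return A list with `probs` (a [prob_cube()]) and `map` (a
#'   [class_map()]).
#' @export
classify_cube <- function(model, cube, year) {
  X <- cube_features(cube)
  H <- dim(cube)[3]; W <- dim(cube)[4]
  p <- svm_prob_matrix(model, X)
  cls <- model$classes[max.col(p, ties.method = "first")]
  probs <- array(p, dim = c(H, W, length(model$classes)))
  map <- matrix(class_code(cls), H, W)
  list(probs = prob_cube(probs, year, model$classes),
       map = class_map(map, year))
}
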