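#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a confusion matrix into long counts
#'
#' @param x A `luc_confusion`.
#' @param ... Unused.
#' @return A tibble with `predicted`, `reference`, `n`.
#' @export
tidy.luc_confusion <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    predicted = rep(rownames(m), times = ncol(m)),
    reference = rep(colnames(m), each = nrow(m)),
    n = as.integer(m)
  )
}

#' @rdname tidy.luc_confusion
#' @export
glance.luc_confusion <- function(x, ...) {
  acc <- accuracies(x)
  tibble::tibble(overall_accuracy = acc$overall, n = sum(unclass(x)))
}

#' Tidy cross-validation results
#'
#' @param x A `luc_cv` from [cross_validate()].
#' @param ... Unused.
#' @return `tidy()`: per-class user's and producer's accuracy; `glance()`:
#'   one row with the overall accuracy and fold count.
#' @export
tidy.luc_cv <- function(x, ...) x$by_class

#' @rdname tidy.luc_cv
#' @export
glance.luc_cv <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall, k_folds = x$k_folds)
}

#' Summaries of a trained SVM
#'
#' @param x A `luc_svm`.
#' @param ... Unused.
#' @return `tidy()`: one row per class pair with its support-vector count;
#'   `glance()`: one row with class count, total support vectors and kernel
#'   parameters.
#' @export
tidy.luc_svm <- function(x, ...) {
  purrr::map_dfr(x$pairs, function(p) {
    tibble::tibble(class_1 = p$classes[1], class_2 = p$classes[2],
                   n_support = length(p$coef))
  })
}

#' @rdname tidy.luc_svm
#' @export
glance.luc_svm <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes),
                 n_support = sum(purrr::map_int(x$pairs,
                                                ~ length(.x$coef))),
                 C = x$config$C, gamma = x$config$gamma)
}

#' @export
print.luc_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation: overall accuracy %.1f%%\n",
              x$k_folds, 100 * x$overall))
  print(x$by_class)
  invisible(x)
}

#' @export
print.luc_som <- function(x, ...) {
  cat(sprintf("SOM %dx%d lattice, %d-dim codebook%s\n", x$xdim, x$ydim,
              ncol(x$weights),
              if (is.null(x$neuron_labels)) " (unlabelled)" else ""))
  invisible(x)
}

#' Convert rasters to tibbles
#'
#' @param x A `luc_class_map` or `luc_prob_cube`.
#' @param ... Unused.
#' @return Long tibbles: per-pixel `row`, `col` plus `code`/`label` for
#'   maps, or `class`/`probability` for probability cubes.
#' @export
as_tibble.luc_class_map <- function(x, ...) {
  g <- unclass(x)
  tibble::tibble(
    row = rep(seq_len(nrow(g)), times = ncol(g)),
    col = rep(seq_len(ncol(g)), each = nrow(g)),
    year = attr(x, "year"),
    code = as.integer(g),
    label = code_label(as.integer(g))
  )
}

#' @rdname as_tibble.luc_class_map
#' @export
as_tibble.luc_prob_cube <- function(x, ...) {
  a <- unclass(x)
  labels <- attr(x, "class_labels")
  H <- dim(a)[1]; W <- dim(a)[2]; K <- dim(a)[3]
  tibble::tibble(
    row = rep(seq_len(H), times = W * K),
    col = rep(rep(seq_len(W), each = H), times = K),
    year = attr(x, "year"),
    class = rep(labels, each = H * W),
    probability = as.numeric(a)
  )
}
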