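#' Confusion matrix between predicted and reference labels
#'
#' Counts follow the convention rows = predicted, columns = reference.
#'
#' @param predicted,reference Equal-length label vectors drawn from the
#'   class vocabulary.
#' @param classes Class labels fixing the matrix order; defaults to the
#'   vocabulary-ordered union of the labels present.
#' @return A `luc_confusion` object: a K x K integer matrix of counts.
#' @export
confusion <- function(predicted, reference, classes = NULL) {
  if (length(predicted) != length(reference)) {
    stop("predicted and reference must have equal length", call. = FALSE)
  }
  if (is.null(classes)) {
    classes <- intersect(luc_classes()$label, union(predicted, reference))
  }
  bad <- setdiff(union(predicted, reference), classes)
  if (length(bad) > 0) {
    stop("labels outside the class set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cm <- table(factor(predicted, levels = classes),
              factor(reference, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(predicted = classes, reference = classes))
  structure(m, class = c("luc_confusion", "matrix", "array"))
}

#' Overall, user's and producer's accuracy
#'
#' Overall accuracy is `trace / total`. For each class, user's accuracy
#' (1 - commission error, the map user's view) is the diagonal count over
#' the row (predicted) sum, and producer's accuracy (1 - omission error)
#' the diagonal count over the column (reference) sum. Ratios with a zero
#' denominator are reported as `NA`, never as 0.
#'
#' @param cm A [confusion()] matrix.
#' @return A list with `overall` (single number) and `by_class`, a tibble
#'   with `class`, `users_acc` and `producers_acc`.
#' @export
accuracies <- function(cm) {
  stopifnot(inherits(cm, "luc_confusion"))
  m <- unclass(cm)
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  diagm <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  list(
    overall = sum(diagm) / total,
    by_class = tibble::tibble(
      class = rownames(m),
      users_acc = unname(ifelse(rs > 0, diagm / rs, NA_real_)),
      producers_acc = unname(ifelse(cs > 0, diagm / cs, NA_real_))
    )
  )
}

#' Class area time series
#'
#' Tallies, for each map year, the pixel count of every class times the
#' pixel area. Total area is conserved each year by construction.
#'
#' @param maps Named list (by year) of aligned [class_map()]s.
#' @param pixel_area Area of one pixel in hectares (6.25 ha for a 250 m
#'   pixel).
#' @return A tibble with `class`, `year` and `area_ha`.
#' @export
area_series <- function(maps, pixel_area = 6.25) {
  purrr::map_dfr(maps, function(map) {
    counts <- table(factor(code_label(as.vector(unclass(map))),
                           levels = luc_classes()$label))
    tibble::tibble(class = names(counts),
                   year = attr(map, "year"),
                   area_ha = as.numeric(counts) * pixel_area)
  })
}

#' Pearson correlation between two area series
#'
#' @param series_a,series_b Equal-length numeric vectors (length >= 2) with
#'   nonzero variance.
#' @return The Pearson correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(series_a, series_b) {
  if (length(series_a) != length(series_b) || length(series_a) < 2) {
    stop("series must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(series_a) == 0 || stats::sd(series_b) == 0) {
    stop("series must have nonzero variance", call. = FALSE)
  }
  stats::cor(series_a, series_b)
}
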