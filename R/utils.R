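# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Clamp x to [lo, hi].
#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# rect = c(row_min, row_max, col_min, col_max), 1-based inclusive.
#' @keywords internal
rect_cells <- function(rect, nrow, ncol) {
  stopifnot(length(rect) == 4)
  if (rect[1] < 1 || rect[2] > nrow || rect[3] < 1 || rect[4] > ncol ||
      rect[1] > rect[2] || rect[3] > rect[4]) {
    stop("rectangle out of scene bounds", call. = FALSE)
  }
  as.vector(outer(rect[1]:rect[2], (rect[3]:rect[4] - 1) * nrow, `+`))
}
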