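#' Land use and cover class vocabulary
#'
#' The mapping vocabulary consists of nine training classes (the classes a
#' classifier can be trained on from labelled time-series samples) plus four
#' auxiliary classes that only ever enter a map through masks or
#' post-processing rules: `water`, `urban` and `sugarcane` (overlaid from
#' external masks) and `secondary-vegetation` (created by the trajectory
#' rules for forest regrowth on previously cleared land). Raster code 0 is
#' reserved for no-data.
#'
#' @return A tibble with columns `label`, `code` (small integer raster code),
#'   `kind` (`"training"` or `"auxiliary"`) and `color` (hex rendering color).
#' @examples
#' luc_classes()
#' @export
luc_classes <- function() {
  tibble::tibble(
    label = c(
      "cerrado", "fallow-cotton", "forest", "pasture", "soy-corn",
      "soy-cotton", "soy-fallow", "soy-millet", "soy-sunflower",
      "water", "urban", "sugarcane", "secondary-vegetation"
    ),
    code = 1:13,
    kind = c(rep("training", 9L), rep("auxiliary", 4L)),
    color = c(
      "#D6BC74", "#E7D5AD", "#1B7837", "#FFD92F", "#D7191C",
      "#AF26B0", "#FB8072", "#9C413C", "#FDB462",
      "#2B83BA", "#666666", "#9E198F", "#80B475"
    )
  )
}

#' @rdname luc_classes
#' @export
training_classes <- function() {
  voc <- luc_classes()
  voc$label[voc$kind == "training"]
}

#' @rdname luc_classes
#' @export
auxiliary_classes <- function() {
  voc <- luc_classes()
  voc$label[voc$kind == "auxiliary"]
}

#' Translate between class labels and raster codes
#'
#' @param label Character vector of class labels.
#' @param code Integer vector of raster codes (0 allowed, meaning no-data).
#' @return `class_code()` returns the integer codes; `code_label()` the
#'   labels (`NA` for code 0).
#' @export
class_code <- function(label) {
  voc <- luc_classes()
  idx <- match(label, voc$label)
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  voc$code[idx]
}

#' @rdname class_code
#' @export
code_label <- function(code) {
  voc <- luc_classes()
  out <- rep(NA_character_, length(code))
  known <- code %in% voc$code
  if (any(!known & code != 0)) {
    stop("unknown class code(s): ",
         paste(unique(code[!known & code != 0]), collapse = ", "),
         call. = FALSE)
  }
  out[known] <- voc$label[match(code[known], voc$code)]
  out
}

#' Write the class code table sidecar
#'
#' Writes a `label,code,color` CSV next to exported rasters so categorical
#' maps are self-describing and can be rendered consistently.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_code_table <- function(path) {
  readr::write_csv(luc_classes()[, c("label", "code", "color")], path)
  invisible(path)
}
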