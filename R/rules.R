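#' Map class codes to the trajectory-rule alphabet
#'
#' The trajectory rules reason over a compressed alphabet: forest (`F`),
#' cerrado (`C`), pasture (`P`), soybean (`S`, any of the five soy-* classes
#' - fallow-cotton has no soybean cycle and is not `S`), secondary
#' vegetation (`SV`), and `other` for every remaining code (auxiliary
#' classes, fallow-cotton, no-data), which is opaque to the rules: windows
#' containing `other` never match.
#'
#' @param code Integer vector of class codes.
#' @return Character vector of letters in
#'   `{"F", "C", "P", "S", "SV", "other"}`.
#' @export
to_alphabet <- function(code) {
  lab <- code_label(code)  # errors on unknown codes
  out <- rep("other", length(code))
  out[lab == "forest"] <- "F"
  out[lab == "cerrado"] <- "C"
  out[lab == "pasture"] <- "P"
  out[lab %in% c("soy-corn", "soy-cotton", "soy-fallow", "soy-millet",
                 "soy-sunflower")] <- "S"
  out[lab == "secondary-vegetation"] <- "SV"
  out[code == 0L] <- "other"
  out
}

# The ten land-use transition rules: left-hand letter pattern, starred
# positions, and the letters written at those positions.
#' @keywords internal
luc_rules <- function() {
  list(
    list(id = 1L,  lhs = c("C", "F"),                stars = 2L,      repl = "C"),
    list(id = 2L,  lhs = c("C", "C", "P", "C"),      stars = 3L,      repl = "C"),
    list(id = 3L,  lhs = c("C", "C", "S", "C"),      stars = 3L,      repl = "C"),
    list(id = 4L,  lhs = c("P", "P", "C", "C", "P"), stars = c(3L, 4L),
         repl = c("P", "P")),
    list(id = 5L,  lhs = c("F", "C", "F", "F"),      stars = 2L,      repl = "F"),
    list(id = 6L,  lhs = c("F", "F", "C", "F"),      stars = 3L,      repl = "F"),
    list(id = 7L,  lhs = c("F", "C", "F"),           stars = 2L,      repl = "F"),
    list(id = 8L,  lhs = c("F", "C"),                stars = 2L,      repl = "F"),
    list(id = 9L,  lhs = c("F", "F", "P", "F"),      stars = 4L,      repl = "SV"),
    list(id = 10L, lhs = c("P", "P", "F", "P"),      stars = 3L,      repl = "SV")
  )
}

#' @keywords internal
letter_code <- function(letter) {
  class_code(c("F" = "forest", "C" = "cerrado", "P" = "pasture",
               "SV" = "secondary-vegetation")[letter])
}

#' Overlay auxiliary masks on a class map
#'
#' Pixels flagged by the water, urban or sugarcane masks are overwritten
#' with the corresponding auxiliary class code, with precedence
#' water > urban > sugarcane where masks overlap; all other pixels are
#' unchanged.
#'
#' @param map A [class_map()].
#' @param water,urban,sugarcane Logical mask matrices aligned with `map`
#'   (or `NULL` for no mask).
#' @return The masked [class_map()].
#' @export
apply_masks <- function(map, water = NULL, urban = NULL, sugarcane = NULL) {
  g <- unclass(map)
  for (m in list(sugarcane, urban, water)) {
    if (!is.null(m) && !identical(dim(m), dim(g))) {
      stop("mask raster not aligned with map", call. = FALSE)
    }
  }
  if (!is.null(sugarcane)) g[sugarcane] <- class_code("sugarcane")
  if (!is.null(urban)) g[urban] <- class_code("urban")
  if (!is.null(water)) g[water] <- class_code("water")
  class_map(g, attr(map, "year"))
}

#' Fuse the base-year map with reference deforestation layers
#'
#' The classifier has no knowledge of land-cover history before the first
#' mapped year, so the base map is reconciled with official
#' deforestation-monitoring layers. With `A` the Amazon-layer value, `C`
#' the Cerrado-layer value and `M` the classified value of a pixel, the
#' rules are evaluated in order and the first match wins:
#'
#' 1. `A = Forest` -> Forest
#' 2. `A = Non-Forest` and `M = Forest` -> Cerrado
#' 3. `A = Deforestation` and `M = Forest` -> Secondary vegetation
#' 4. `C = Non-Anthropized` and `M = Forest` -> Cerrado
#' 5. `C = Anthropized` and `M = Forest` -> Secondary vegetation
#'
#' Unmatched pixels are unchanged.
#'
#' @param map The base-year [class_map()].
#' @param refs A list with `amazon` (integer matrix, 0 absent / 1 Forest /
#'   2 Non-Forest / 3 Deforestation) and `cerrado` (0 absent /
#'   1 Anthropized / 2 Non-Anthropized), aligned with `map`.
#' @return The corrected [class_map()].
#' @export
apply_basemap_rules <- function(map, refs) {
  g <- unclass(map)
  A <- refs$amazon; Cr <- refs$cerrado
  stopifnot(identical(dim(A), dim(g)), identical(dim(Cr), dim(g)))
  forest <- class_code("forest")
  out <- g
  done <- matrix(FALSE, nrow(g), ncol(g))
  fire <- function(cond, value) {
    hit <- cond & !done
    out[hit] <<- value
    done[hit] <<- TRUE
  }
  fire(A == 1L, forest)
  fire(A == 2L & g == forest, class_code("cerrado"))
  fire(A == 3L & g == forest, class_code("secondary-vegetation"))
  fire(Cr == 2L & g == forest, class_code("cerrado"))
  fire(Cr == 1L & g == forest, class_code("secondary-vegetation"))
  class_map(out, attr(map, "year"))
}

#' Rewrite multi-year trajectories with the land-use transition rules
#'
#' Maps produced independently per year can contain impossible transitions
#' (forest appearing inside cerrado, crops flickering to natural
#' vegetation). The ten transition rules rewrite each pixel's multi-year
#' class sequence: every rule's left-hand letter pattern is matched against
#' every contiguous window of the trajectory, scanning left to right with
#' immediate in-place replacement of the starred positions, one full pass
#' per rule in numbered order. Rules 9 and 10 are the only producers of the
#' secondary-vegetation class, marking forest signal that regrew on
#' previously cleared land. Rules whose pattern is longer than the
#' trajectory are skipped.
#'
#' @param stack Integer matrix of class codes, pixels x years (columns in
#'   year order), or a list of aligned [class_map()]s.
#' @param frozen Optional logical vector (length = pixels): frozen pixels
#'   (e.g. masked water/urban/sugarcane) neither match nor are rewritten.
#' @return A list with `stack` (rewritten code matrix, same shape) and
#'   `report`, a tibble with `rule` and `n_pixels` changed by that rule.
#' @export
apply_luc_rules <- function(stack, frozen = NULL) {
  maps <- NULL
  if (is.list(stack)) {
    maps <- stack
    stack <- do.call(cbind, lapply(maps, as.vector))
  }
  stopifnot(is.matrix(stack))
  n_years <- ncol(stack)
  letters_m <- matrix(to_alphabet(as.vector(stack)), nrow = nrow(stack))
  active <- if (is.null(frozen)) rep(TRUE, nrow(stack)) else !frozen
  changed <- matrix(0L, nrow(stack), 10L)
  for (rule in luc_rules()) {
    len <- length(rule$lhs)
    if (len > n_years) next
    repl_codes <- letter_code(rule$repl)
    for (start in seq_len(n_years - len + 1L)) {
      win <- start:(start + len - 1L)
      hit <- active
      for (k in seq_len(len)) {
        hit <- hit & letters_m[, win[k]] == rule$lhs[k]
        if (!any(hit)) break
      }
      if (!any(hit)) next
      for (k in seq_along(rule$stars)) {
        col <- start + rule$stars[k] - 1L
        stack[hit, col] <- repl_codes[k]
        letters_m[hit, col] <- rule$repl[k]
      }
      changed[hit, rule$id] <- 1L
    }
  }
  report <- tibble::tibble(rule = 1:10, n_pixels = colSums(changed))
  if (!is.null(maps)) {
    years <- vapply(maps, attr, integer(1), "year")
    maps <- purrr::map(seq_along(maps), function(i) {
      class_map(matrix(stack[, i], nrow(maps[[i]])), years[i])
    })
    return(list(stack = stack, maps = maps, report = report))
  }
  list(stack = stack, report = report)
}

#' Full post-processing pipeline for smoothed maps
#'
#' Runs, in order: base-map fusion with the reference layers on the first
#' year, trajectory rewriting over the full stack (masked pixels frozen),
#' then the water/urban/sugarcane masks on every year.
#'
#' @param maps Named list (by year) of smoothed [class_map()]s for
#'   consecutive years.
#' @param masks List of logical matrices `water`, `urban`, `sugarcane`.
#' @param refs Reference layers, see [apply_basemap_rules()].
#' @return A list with `maps` (final per-year [class_map()]s) and the
#'   trajectory-rule change `report`.
#' @export
run_postprocessing <- function(maps, masks, refs) {
  years <- vapply(maps, attr, integer(1), "year")
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("maps must cover consecutive years", call. = FALSE)
  }
  maps[[1]] <- apply_basemap_rules(maps[[1]], refs)
  frozen <- as.vector(masks$water | masks$urban | masks$sugarcane)
  if (length(maps) >= 2) {
    rewritten <- apply_luc_rules(maps, frozen = frozen)
    maps <- rewritten$maps
    report <- rewritten$report
  } else {
    report <- tibble::tibble(rule = 1:10, n_pixels = 0)
  }
  maps <- purrr::map(maps, apply_masks, water = masks$water,
                     urban = masks$urban, sugarcane = masks$sugarcane)
  names(maps) <- as.character(years)
  list(maps = maps, report = report)
}
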