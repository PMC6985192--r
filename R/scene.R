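#' Categorical class-map rasters
#'
#' A class map is an integer matrix of raster codes (see [luc_classes()])
#' with a `year` attribute. Maps are small in-memory matrices; [as_tibble()]
#' methods and plain-text grid I/O keep them inspectable.
#'
#' @param grid Integer matrix of class codes (0 = no-data).
#' @param year Map (harvest) year.
#' @return An object of class `luc_class_map`.
#' @export
class_map <- function(grid, year) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "integer"
  bad <- !(grid %in% c(0L, luc_classes()$code))
  if (any(bad)) stop("class map contains unknown codes", call. = FALSE)
  structure(grid, year = as.integer(year), class = c("luc_class_map", "matrix", "array"))
}

#' @rdname class_map
#' @param path File path for the plain-text grid (space-separated codes, one
#'   raster row per line, preceded by a `# year:` comment).
#' @param map A `luc_class_map`.
#' @export
write_class_map <- function(map, path) {
  lines <- c(sprintf("# year: %d", attr(map, "year") %||% NA_integer_),
             apply(unclass(map), 1, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname class_map
#' @export
read_class_map <- function(path) {
  lines <- readLines(path)
  year <- as.integer(sub("# year: ", "", lines[1], fixed = TRUE))
  grid <- do.call(rbind, lapply(lines[-1], function(l) {
    as.integer(strsplit(l, " ", fixed = TRUE)[[1]])
  }))
  class_map(grid, year)
}

#' Specify a synthetic raster scene
#'
#' A scene is a small multi-year raster world with known truth: a background
#' class, rectangular patches carrying a (possibly per-year) class label,
#' disjoint water/urban/sugarcane mask rectangles, a declared sub-rectangle
#' covered by an Amazon deforestation-monitoring reference layer
#' (Forest / Non-Forest / Deforestation; the complement is covered by a
#' Cerrado layer with Anthropized / Non-Anthropized), and rectangles declared
#' as historically deforested.
#'
#' Rectangles are `c(row_min, row_max, col_min, col_max)`, 1-based inclusive.
#'
#' @param width,height Scene size in pixels.
#' @param years Ordered integer vector of map years (consecutive).
#' @param background Background training-class label.
#' @param patches List of `list(rect =, labels =)`; `labels` has length 1
#'   (static) or one label per year. Later patches override earlier ones.
#' @param water_rect,urban_rect,sugarcane_rect Optional mask rectangles;
#'   they must be pairwise disjoint.
#' @param amazon_rect Rectangle covered by the Amazon-like reference layer.
#' @param deforestation_rects List of rectangles marked Deforestation in the
#'   Amazon-like layer.
#' @param mislabel_rate Fraction of pixel-years whose series is drawn from a
#'   uniformly random other class (spectral noise pixels); truth is unchanged.
#' @param seed Integer seed.
#' @return A `luc_scene_spec` list.
#' @export
scene_spec <- function(width, height, years, background = "cerrado",
                       patches = list(), water_rect = NULL, urban_rect = NULL,
                       sugarcane_rect = NULL, amazon_rect = NULL,
                       deforestation_rects = list(), mislabel_rate = 0,
                       seed = 1L) {
  stopifnot(width >= 1, height >= 1, length(years) >= 1)
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("years must be consecutive", call. = FALSE)
  }
  if (mislabel_rate < 0 || mislabel_rate > 1) {
    stop("mislabel_rate must be in [0, 1]", call. = FALSE)
  }
  for (p in patches) {
    rect_cells(p$rect, height, width)
    if (!(length(p$labels) %in% c(1L, length(years)))) {
      stop("patch labels must have length 1 or one per year", call. = FALSE)
    }
    class_code(p$labels)
  }
  masks <- list(water = water_rect, urban = urban_rect,
                sugarcane = sugarcane_rect)
  cells <- lapply(Filter(Negate(is.null), masks), rect_cells, nrow = height,
                  ncol = width)
  if (length(unlist(cells)) != length(unique(unlist(cells)))) {
    stop("mask rectangles overlap", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 years = years, background = background, patches = patches,
                 water_rect = water_rect, urban_rect = urban_rect,
                 sugarcane_rect = sugarcane_rect, amazon_rect = amazon_rect,
                 deforestation_rects = deforestation_rects,
                 mislabel_rate = mislabel_rate, seed = as.integer(seed)),
            class = "luc_scene_spec")
}

#' Default demonstration scene
#'
#' A 30 x 30, four-year scene: the left half is the Amazon-reference region,
#' mostly forest with a pasture strip declared as past deforestation and one
#' interior forest patch that is cut to pasture in the third year and regrows
#' in the fourth (the secondary-vegetation showcase); the right half is
#' cerrado background with soy-corn and pasture blocks; small water, urban
#' and sugarcane masks sit in the top-right corner.
#'
#' @param years Integer vector of map years.
#' @param seed Integer seed.
#' @return A `luc_scene_spec`.
#' @export
default_scene_spec <- function(years = 2014:2017, seed = 1L) {
  ny <- length(years)
  revert <- if (ny >= 4) {
    c(rep("forest", ny - 2), "pasture", "forest")
  } else {
    "forest"
  }
  scene_spec(
    width = 30, height = 30, years = years,
    background = "cerrado",
    patches = list(
      list(rect = c(1, 24, 1, 15), labels = "forest"),
      list(rect = c(25, 30, 1, 15), labels = "pasture"),
      list(rect = c(9, 16, 4, 11), labels = revert),
      list(rect = c(11, 20, 16, 30), labels = "soy-corn"),
      list(rect = c(21, 30, 16, 30), labels = "pasture")
    ),
    water_rect = c(1, 3, 16, 18),
    urban_rect = c(1, 3, 19, 21),
    sugarcane_rect = c(1, 3, 22, 24),
    amazon_rect = c(1, 30, 1, 15),
    deforestation_rects = list(c(25, 30, 1, 15)),
    seed = seed
  )
}

# Truth class-code matrix for one year index.
#' @keywords internal
scene_truth_grid <- function(spec, year_index) {
  g <- matrix(class_code(spec$background), spec$height, spec$width)
  for (p in spec$patches) {
    lab <- if (length(p$labels) == 1L) p$labels else p$labels[year_index]
    g[rect_cells(p$rect, spec$height, spec$width)] <- class_code(lab)
  }
  g
}

#' Generate a synthetic multi-year scene
#'
#' Draws every pixel-year series from its truth label's pattern (mean curve
#' plus clipped Gaussian noise), and derives the reference layers from the
#' first-year truth: inside `amazon_rect`, forest pixels are Forest and the
#' rest Non-Forest, with `deforestation_rects` overriding to Deforestation;
#' outside it, pixels whose truth is pasture or a crop are Anthropized and
#' natural-vegetation pixels Non-Anthropized.
#'
#' @param spec A [scene_spec()].
#' @param patterns Pattern tibble, see [default_patterns()].
#' @return A `luc_scene` list with elements `cube` (per-year arrays of shape
#'   4 bands x 23 steps x height x width), `truth` (per-year
#'   `luc_class_map`), `masks` (logical matrices `water`, `urban`,
#'   `sugarcane`), `ref` (integer matrices `amazon`: 0 absent / 1 Forest /
#'   2 Non-Forest / 3 Deforestation, and `cerrado`: 0 absent /
#'   1 Anthropized / 2 Non-Anthropized) and the `spec`.
#' @export
generate_scene <- function(spec, patterns = default_patterns()) {
  stopifnot(inherits(spec, "luc_scene_spec"))
  pm <- pattern_matrix(patterns)
  sd_m <- pattern_matrix(patterns, what = "noise_sd")
  H <- spec$height; W <- spec$width
  n_pix <- H * W
  classes <- training_classes()

  with_seed(spec$seed, {
    truth <- list()
    cube <- list()
    for (yi in seq_along(spec$years)) {
      g <- scene_truth_grid(spec, yi)
      labels <- code_label(as.vector(g))
      draw_from <- labels
      if (spec$mislabel_rate > 0) {
        flip <- stats::runif(n_pix) < spec$mislabel_rate
        if (any(flip)) {
          draw_from[flip] <- vapply(labels[flip], function(cls) {
            sample(setdiff(classes, cls), 1L)
          }, character(1))
        }
      }
      vals <- pm[draw_from, , drop = FALSE] +
        matrix(stats::rnorm(n_pix * 92L,
                            sd = as.vector(sd_m[draw_from, , drop = FALSE])),
               nrow = n_pix)
      vals[, 1:46] <- clamp(vals[, 1:46], -1, 1)
      vals[, 47:92] <- clamp(vals[, 47:92], 0, 1)
      a <- aperm(array(t(vals), dim = c(23L, 4L, H, W)), c(2, 1, 3, 4))
      dimnames(a) <- list(band = luc_bands(), NULL, NULL, NULL)
      yr <- spec$years[yi]
      cube[[as.character(yr)]] <- a
      truth[[as.character(yr)]] <- class_map(g, yr)
    }

    mask_of <- function(rect) {
      m <- matrix(FALSE, H, W)
      if (!is.null(rect)) m[rect_cells(rect, H, W)] <- TRUE
      m
    }
    masks <- list(water = mask_of(spec$water_rect),
                  urban = mask_of(spec$urban_rect),
                  sugarcane = mask_of(spec$sugarcane_rect))

    amazon <- matrix(0L, H, W)
    cerrado_ref <- matrix(0L, H, W)
    t1 <- unclass(truth[[1]])
    anthropic <- class_code(c("pasture", "fallow-cotton", "soy-corn",
                              "soy-cotton", "soy-fallow", "soy-millet",
                              "soy-sunflower"))
    if (!is.null(spec$amazon_rect)) {
      am_cells <- rect_cells(spec$amazon_rect, H, W)
      amazon[am_cells] <- ifelse(t1[am_cells] == class_code("forest"), 1L, 2L)
      for (r in spec$deforestation_rects) {
        cells <- intersect(rect_cells(r, H, W), am_cells)
        amazon[cells] <- 3L
      }
      cer_cells <- setdiff(seq_len(n_pix), am_cells)
    } else {
      cer_cells <- seq_len(n_pix)
    }
    cerrado_ref[cer_cells] <-
      ifelse(t1[cer_cells] %in% anthropic, 1L, 2L)

    structure(list(cube = cube, truth = truth, masks = masks,
                   ref = list(amazon = amazon, cerrado = cerrado_ref),
                   spec = spec),
              class = "luc_scene")
  })
}

# One year's cube array (4 x 23 x H x W) as an n_pix x 92 feature matrix,
# pixels in column-major raster order.
#' @keywords internal
cube_features <- function(a) {
  stopifnot(length(dim(a)) == 4, dim(a)[1] == 4L, dim(a)[2] == 23L)
  matrix(aperm(a, c(3, 4, 2, 1)), nrow = dim(a)[3] * dim(a)[4])
}
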