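#' Reference seasonal patterns for the nine training classes
#'
#' Hand-designed mean seasonal curves (23 composite steps over one
#' agricultural year, September through August) for each training class and
#' band, emulating the qualitative structure of vegetation-index profiles in
#' the Brazilian agricultural frontier: forest holds a high, nearly constant
#' NDVI; cerrado (savanna) an intermediate NDVI with mild wet-season
#' seasonality; pasture a stronger seasonal swing on a lower dry-season
#' baseline; single-crop classes one NDVI peak (soy early in the season,
#' cotton late); double-crop classes two peaks. EVI tracks NDVI at reduced
#' amplitude, NIR rises with green biomass, and MIR runs roughly anti-phase
#' to NDVI (bare/dry surfaces are MIR-bright).
#'
#' The curves are sums of at most two Gaussian bumps plus a baseline, with
#' per-class reflectance offsets in NIR/MIR that carry additional
#' discriminative information. Default noise is 0.05 (sd) for NDVI/EVI and
#' 0.03 for NIR/MIR.
#'
#' @return A tibble of class `luc_patterns` with columns `label`, `band`,
#'   `step` (1..23), `mean` and `noise_sd`.
#' @examples
#' pats <- default_patterns()
#' dplyr::count(pats, label)
#' @export
default_patterns <- function() {
  steps <- seq_len(luc_n_steps())
  bump <- function(c0, w, a) a * exp(-0.5 * ((steps - c0) / w)^2)

  ndvi <- list(
    "cerrado"       = 0.45 + bump(11, 6.0, 0.13),
    "fallow-cotton" = 0.25 + bump(15, 2.8, 0.55),
    "forest"        = 0.85 + 0.03 * cos(2 * pi * (steps - 11) / 23),
    "pasture"       = 0.30 + bump(11, 5.0, 0.35),
    "soy-corn"      = 0.22 + bump(7.0, 1.8, 0.63) + bump(15.0, 2.0, 0.58),
    "soy-cotton"    = 0.22 + bump(6.5, 1.7, 0.60) + bump(16.5, 2.6, 0.55),
    "soy-fallow"    = 0.25 + bump(8.0, 2.2, 0.60),
    "soy-millet"    = 0.22 + bump(7.0, 1.8, 0.60) + bump(14.0, 1.6, 0.42),
    "soy-sunflower" = 0.22 + bump(7.5, 1.9, 0.58) + bump(17.0, 1.4, 0.36)
  )
  # band = offset + slope * ndvi; offsets differ by class (canopy structure,
  # soil exposure and residue make NIR/MIR class-specific beyond greenness).
  evi_off <- c("cerrado" = 0.04, "fallow-cotton" = 0.03, "forest" = 0.10,
               "pasture" = 0.00, "soy-corn" = 0.05, "soy-cotton" = 0.05,
               "soy-fallow" = 0.05, "soy-millet" = 0.05, "soy-sunflower" = 0.05)
  nir_off <- c("cerrado" = 0.12, "fallow-cotton" = 0.12, "forest" = 0.17,
               "pasture" = 0.13, "soy-corn" = 0.16, "soy-cotton" = 0.13,
               "soy-fallow" = 0.14, "soy-millet" = 0.11, "soy-sunflower" = 0.15)
  mir_off <- c("cerrado" = 0.32, "fallow-cotton" = 0.36, "forest" = 0.27,
               "pasture" = 0.37, "soy-corn" = 0.33, "soy-cotton" = 0.38,
               "soy-fallow" = 0.33, "soy-millet" = 0.34, "soy-sunflower" = 0.35)
  noise <- c(ndvi = 0.05, evi = 0.05, nir = 0.03, mir = 0.03)

  out <- purrr::map_dfr(training_classes(), function(cls) {
    nd <- ndvi[[cls]]
    curves <- list(
      ndvi = nd,
      evi = evi_off[[cls]] + 0.62 * nd,
      nir = nir_off[[cls]] + 0.15 * nd,
      mir = mir_off[[cls]] - 0.25 * nd
    )
    purrr::map_dfr(luc_bands(), function(b) {
      tibble::tibble(label = cls, band = b, step = steps,
                     mean = curves[[b]], noise_sd = noise[[b]])
    })
  })
  class(out) <- c("luc_patterns", class(out))
  out
}

#' @keywords internal
validate_patterns <- function(patterns) {
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(c("label", "band", "step", "mean", "noise_sd") %in%
                  names(patterns)))
  if (!all(is.finite(patterns$mean))) stop("pattern curves must be finite")
  if (any(patterns$noise_sd < 0)) stop("noise_sd must be nonnegative")
  patterns
}

# Per-class mean curves as a label -> 92-vector matrix in feature order.
#' @keywords internal
pattern_matrix <- function(patterns, what = "mean") {
  patterns <- validate_patterns(patterns)
  wide <- patterns[order(match(patterns$band, luc_bands()), patterns$step), ]
  labs <- unique(wide$label)
  m <- vapply(labs, function(cls) wide[[what]][wide$label == cls], numeric(92L))
  t(m)
}

#' Generate labelled synthetic samples
#'
#' Draws `n_per_class` samples per training class: each band series is the
#' class mean curve plus independent Gaussian noise (per-band `noise_sd`),
#' clipped to the physical range (\[-1, 1\] for NDVI/EVI, \[0, 1\] for
#' NIR/MIR). A fraction `mislabel_rate` of samples has its label replaced by
#' one drawn uniformly from the other eight classes while keeping the series
#' of its true class - the error model the SOM quality control is designed to
#' catch. The true generating class is kept in a `true_label` column (dropped
#' on CSV export).
#'
#' @param patterns Pattern tibble, see [default_patterns()].
#' @param n_per_class Positive integer, samples per class.
#' @param mislabel_rate Fraction in \[0, 1\] of relabelled samples.
#' @param seed Integer seed; output is reproducible for a fixed seed.
#' @param year Map (harvest) year; the agricultural year runs 1 September of
#'   `year - 1` to 31 August of `year`.
#' @return A validated sample tibble with `9 * n_per_class` rows.
#' @export
generate_samples <- function(patterns = default_patterns(), n_per_class = 100,
                             mislabel_rate = 0, seed = 1L, year = 2015L) {
  if (n_per_class <= 0) stop("n_per_class must be positive", call. = FALSE)
  if (mislabel_rate < 0 || mislabel_rate > 1) {
    stop("mislabel_rate must be in [0, 1]", call. = FALSE)
  }
  pm <- pattern_matrix(patterns)
  classes <- training_classes()
  if (!all(classes %in% rownames(pm))) {
    stop("patterns must cover all nine training classes", call. = FALSE)
  }
  sd_m <- pattern_matrix(patterns, what = "noise_sd")
  n_total <- length(classes) * n_per_class

  with_seed(seed, {
    true_label <- rep(classes, each = n_per_class)
    sds <- sd_m[true_label, , drop = FALSE]
    vals <- pm[true_label, , drop = FALSE] +
      matrix(stats::rnorm(n_total * 92L, sd = as.vector(sds)), nrow = n_total)
    vals[, 1:46] <- clamp(vals[, 1:46], -1, 1)   # ndvi, evi
    vals[, 47:92] <- clamp(vals[, 47:92], 0, 1)  # nir, mir
    colnames(vals) <- band_columns()

    label <- true_label
    flip <- stats::runif(n_total) < mislabel_rate
    if (any(flip)) {
      label[flip] <- vapply(true_label[flip], function(cls) {
        sample(setdiff(classes, cls), 1L)
      }, character(1))
    }
    out <- tibble::tibble(
      longitude = stats::runif(n_total, -58, -54),
      latitude = stats::runif(n_total, -16, -10),
      start_date = as.Date(sprintf("%d-09-01", year - 1L)),
      end_date = as.Date(sprintf("%d-08-31", year)),
      label = label,
      true_label = true_label
    )
    out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
    validate_samples(out)
  })
}
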