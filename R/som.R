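#' Self-organizing-map quality control of training samples
#'
#' Mislabelled ground samples degrade a classifier, so before training the
#' samples are screened with a self-organizing map (SOM): a 2-D lattice of
#' neurons, each carrying a weight vector in the 92-dimensional feature
#' space, trained by online competitive learning. Samples with similar
#' seasonal profiles map to nearby neurons; each neuron is labelled by a
#' majority vote of the samples it attracts, and a sample whose own label
#' disagrees with its neuron's label across repeated SOM runs is flagged as
#' unreliable.
#'
#' `train_som()` runs online Kohonen training: for each presented sample the
#' best-matching unit (BMU, smallest Euclidean distance) and its lattice
#' neighbors move toward the sample, with the learning rate decaying
#' linearly from `alpha_start` to `alpha_end` and a Gaussian lattice
#' neighborhood whose radius decays from `max(xdim, ydim) / 2` to 1. The
#' codebook is initialized from randomly drawn samples.
#'
#' @param features Numeric matrix of 92-dimensional feature vectors (rows),
#'   from [sample_features()].
#' @param xdim,ydim Lattice dimensions; default [som_grid_size()].
#' @param epochs Passes over the data (default 100).
#' @param alpha_start,alpha_end Linear learning-rate schedule.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return A `luc_som` object: `weights` (neurons x 92), lattice dims,
#'   `neuron_labels` (filled by [label_neurons()]) and the parameters used.
#' @export
train_som <- function(features, xdim = NULL, ydim = NULL, epochs = 100,
                      alpha_start = 0.05, alpha_end = 0.01, seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 1) stop("need at least one feature vector", call. = FALSE)
  if (is.null(xdim)) xdim <- som_grid_size(n)
  if (is.null(ydim)) ydim <- som_grid_size(n)
  if (xdim < 1 || ydim < 1) stop("grid dimensions must be >= 1", call. = FALSE)
  m <- as.integer(xdim) * as.integer(ydim)
  with_seed(seed, {
    init <- sample.int(n, m, replace = TRUE)
    order <- as.integer(unlist(lapply(seq_len(epochs),
                                      function(e) sample.int(n))))
    W <- t(som_train_cpp(t(features), as.integer(xdim), as.integer(ydim),
                         init, order, alpha_start, alpha_end))
    structure(list(weights = W, xdim = as.integer(xdim),
                   ydim = as.integer(ydim), neuron_labels = NULL,
                   params = list(epochs = epochs, alpha_start = alpha_start,
                                 alpha_end = alpha_end, seed = seed)),
              class = "luc_som")
  })
}

#' Kohonen grid-size heuristic
#'
#' `ceiling(sqrt(5 * sqrt(n)))` neurons per side, so the lattice holds about
#' `5 * sqrt(n)` neurons in total.
#'
#' @param n Number of training samples.
#' @return Integer lattice side length.
#' @export
som_grid_size <- function(n) as.integer(ceiling(sqrt(5 * sqrt(n))))

#' @rdname train_som
#' @param som A trained `luc_som`.
#' @param samples Sample tibble whose features the SOM was trained on.
#' @details `label_neurons()` assigns each neuron the modal class of the
#'   samples whose BMU it is; ties are broken toward the class with the
#'   higher global sample count, then by lexicographic label order. Neurons
#'   attracting no samples stay unlabelled (`NA`).
#' @export
label_neurons <- function(som, samples) {
  stopifnot(inherits(som, "luc_som"))
  samples <- validate_samples(samples)
  features <- sample_features(samples)
  bmu <- som_bmu_cpp(t(features), t(som$weights))
  global_count <- table(samples$label)
  labels <- rep(NA_character_, nrow(som$weights))
  for (k in unique(bmu)) {
    votes <- table(samples$label[bmu == k])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      g <- global_count[top]
      top <- top[g == max(g)]
      top <- sort(top)[1]
    }
    labels[k] <- top
  }
  som$neuron_labels <- labels
  som$bmu <- bmu
  som
}

#' Per-sample label reliability from repeated SOM runs
#'
#' Runs `n_runs` independent SOM trainings (run seeds are
#' `seed + run index`), labels the neurons of each run by majority vote, and
#' records for every sample the label of its best-matching unit. The
#' frequency with which each cluster label occurs across runs estimates the
#' probability that the sample belongs to that class; frequencies sum to 1
#' for every sample. A sample's own BMU always maps at least the sample
#' itself, so it is never unlabelled.
#'
#' @inheritParams train_som
#' @param samples Validated sample tibble.
#' @param n_runs Number of independent SOM runs (default 20).
#' @return A `luc_reliability` tibble in long form: `sample_id`,
#'   `original_label`, `cluster_label`, `frequency`.
#' @export
evaluate_samples <- function(samples, n_runs = 20, xdim = NULL, ydim = NULL,
                             epochs = 100, alpha_start = 0.05,
                             alpha_end = 0.01, seed = 1L) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  samples <- validate_samples(samples)
  features <- sample_features(samples)
  n <- nrow(features)
  hits <- purrr::map(seq_len(n_runs), function(r) {
    som <- train_som(features, xdim = xdim, ydim = ydim, epochs = epochs,
                     alpha_start = alpha_start, alpha_end = alpha_end,
                     seed = seed + r)
    som <- label_neurons(som, samples)
    som$neuron_labels[som$bmu]
  })
  hit_m <- do.call(cbind, hits)  # n x n_runs of BMU labels
  out <- tibble::tibble(
    sample_id = rep(seq_len(n), each = n_runs),
    original_label = rep(samples$label, each = n_runs),
    cluster_label = as.vector(t(hit_m))
  )
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$sample_id, .data$original_label,
                    .data$cluster_label),
    frequency = dplyr::n() / n_runs, .groups = "drop"
  )
  class(out) <- c("luc_reliability", class(out))
  out
}

#' Filter samples by reliability threshold
#'
#' A sample is retained if and only if the frequency of its own original
#' label across SOM runs is at least `threshold` (default 0.8: the label and
#' the cluster must agree at least 80% of the time).
#'
#' @param reliabilities A `luc_reliability` tibble from [evaluate_samples()].
#' @param samples The sample tibble the reliabilities refer to (row order
#'   must match `sample_id`).
#' @param threshold Retention threshold in (0, 1\].
#' @return A list with `retained` and `removed` sample tibbles, a one-row
#'   `report` tibble (`n_in`, `n_retained`, `n_removed`, `pct_reduction`
#'   rounded to one decimal), and `detail`, a wide per-sample table
#'   (one frequency column per cluster label plus a `retained` flag)
#'   suitable for CSV export.
#' @export
filter_samples <- function(reliabilities, samples, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  samples <- validate_samples(samples)
  own <- dplyr::filter(tibble::as_tibble(reliabilities),
                       .data$cluster_label == .data$original_label)
  own_freq <- rep(0, nrow(samples))
  own_freq[own$sample_id] <- own$frequency
  keep <- own_freq >= threshold - 1e-9
  report <- qc_report(nrow(samples), sum(keep))
  detail <- tidyr::pivot_wider(
    tibble::as_tibble(reliabilities),
    id_cols = c("sample_id", "original_label"),
    names_from = "cluster_label", values_from = "frequency",
    values_fill = 0
  )
  detail$retained <- keep[detail$sample_id]
  list(retained = samples[keep, , drop = FALSE],
       removed = samples[!keep, , drop = FALSE],
       report = report, detail = detail)
}

#' Quality-control reduction arithmetic
#'
#' @param n_in,n_retained Sample counts before and after filtering.
#' @return A one-row tibble with the counts and the percentage reduction
#'   `(n_in - n_retained) / n_in * 100`, rounded to one decimal.
#' @export
qc_report <- function(n_in, n_retained) {
  tibble::tibble(
    n_in = as.integer(n_in),
    n_retained = as.integer(n_retained),
    n_removed = as.integer(n_in - n_retained),
    pct_reduction = round((n_in - n_retained) / n_in * 100, 1)
  )
}
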