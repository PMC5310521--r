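# y-randomisation (target shuffling) significance machinery. Null models
# are built on label-permuted data with descriptors re-selected against the
# shuffled labels, then run through the identical cross-validation
# protocol. DT/PLS models are judged by the ECDF percentile of the real
# balanced accuracy within 300 null values (significant at or above the
# 99th percentile); RF model collections are judged by the mean probability
# that a real-model balanced accuracy exceeds a null one (significant above
# 80%), with the histogram-overlap statistic recorded alongside.

#' Shuffle class labels (y-randomisation)
#'
#' Uniform random permutation of the label multiset; class counts are
#' conserved.
#'
#' @param labels label vector.
#' @param seed optional seed.
#' @return permuted labels.
#' @export
y_randomise <- function(labels, seed = NULL) {
  with_seed(seed, sample(labels))
}

#' Null balanced-accuracy distribution for one learner
#'
#' Builds `n_random` y-randomised models: each shuffles the labels,
#' re-selects descriptors against the shuffled labels inside each training
#' fold, and runs the identical cross-validation protocol.
#'
#' @param dataset a [build_dataset()] result.
#' @param method `"decision_tree"` or `"pls"` (RF uses [validate_rf()]).
#' @param n_random number of null models (300 in the screening protocol;
#'   reducible for desk-scale runs).
#' @param k folds.
#' @param seed master seed.
#' @param ... passed to [cross_validate()].
#' @return numeric vector of `n_random` balanced accuracies.
#' @export
null_distribution <- function(dataset, method, n_random = 300, k = 10,
                              seed = 1, ...) {
  vapply(seq_len(n_random), function(j) {
    ds <- dataset
    ds$labels[] <- y_randomise(unname(ds$labels), derive_seed(seed, j))
    cross_validate(ds, method, k = k, seed = derive_seed(seed, 50000 + j),
                   ...)$balanced_accuracy
  }, numeric(1))
}

#' ECDF percentile of a value within a distribution
#'
#' `100 * mean(distribution <= value)`; the weak inequality means a value
#' tied with the 99th-percentile null still counts as "in or above" it.
#'
#' @param value observed statistic.
#' @param distribution non-empty numeric vector of null statistics.
#' @return percentile in \[0, 100\].
#' @export
ecdf_percentile <- function(value, distribution) {
  if (!length(distribution)) stop("empty distribution")
  100 * mean(distribution <= value)
}

#' Histogram-overlap statistic between two distributions
#'
#' Both samples are binned on a shared equal-width partition of \[0, 1\];
#' the overlap is the sum over bins of the minimum of the two bin
#' proportions. Identical samples give 1; samples occupying disjoint bins
#' give 0.
#'
#' @param dist_a,dist_b non-empty numeric samples (balanced accuracies).
#' @param n_bins number of equal-width bins on \[0, 1\].
#' @return overlap proportion in \[0, 1\].
#' @export
overlap_coefficient <- function(dist_a, dist_b, n_bins = 20) {
  if (!length(dist_a) || !length(dist_b)) stop("empty distribution")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- function(x) {
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), n_bins) / length(x)
  }
  sum(pmin(bin(dist_a), bin(dist_b)))
}

#' Exceedance probability between two distributions
#'
#' Probability that a value drawn from `dist_real` exceeds one drawn from
#' `dist_null`, computed exhaustively over all pairs with ties counting
#' one half (which makes p(A,B) + p(B,A) = 1 exactly). The standard error
#' treats the estimate as a proportion over the pair count.
#'
#' @param dist_real,dist_null non-empty numeric samples.
#' @return list with `p` and `se`.
#' @export
exceedance_probability <- function(dist_real, dist_null) {
  if (!length(dist_real) || !length(dist_null)) stop("empty distribution")
  n_pairs <- length(dist_real) * length(dist_null)
  gt <- sum(outer(dist_real, dist_null, ">"))
  eq <- sum(outer(dist_real, dist_null, "=="))
  p <- (gt + 0.5 * eq) / n_pairs
  list(p = p, se = sqrt(p * (1 - p) / n_pairs))
}

#' Validate a DT or PLS model by y-randomisation percentile
#'
#' Compares the real cross-validated balanced accuracy against the null
#' distribution; the model is significant when the real value sits in or
#' above the nulls' 99th ECDF percentile.
#'
#' @param dataset a [build_dataset()] result.
#' @param method `"decision_tree"` or `"pls"`.
#' @param n_random number of null models (default 300).
#' @param k folds.
#' @param seed master seed.
#' @param percentile_cutoff significance percentile (default 99).
#' @param real_run optional precomputed [cross_validate()] run to reuse.
#' @param ... passed to [cross_validate()].
#' @return list of class `validation_report`: `method`, `real_ba`,
#'   `null` (vector), `n_random`, `percentile`, `percentile_cutoff`,
#'   `significant`, `reduced_nulls` (TRUE when fewer than 300 nulls were
#'   used).
#' @export
validate_dt_pls <- function(dataset, method = c("decision_tree", "pls"),
                            n_random = 300, k = 10, seed = 1,
                            percentile_cutoff = 99, real_run = NULL, ...) {
  method <- match.arg(method)
  if (is.null(real_run)) {
    real_run <- cross_validate(dataset, method, k = k,
                               seed = derive_seed(seed, 1), ...)
  }
  nulls <- null_distribution(dataset, method, n_random = n_random, k = k,
                             seed = derive_seed(seed, 2), ...)
  pct <- ecdf_percentile(real_run$balanced_accuracy, nulls)
  structure(list(method = method, real_ba = real_run$balanced_accuracy,
                 null = nulls, n_random = n_random, percentile = pct,
                 percentile_cutoff = percentile_cutoff,
                 significant = pct >= percentile_cutoff,
                 reduced_nulls = n_random < 300, k = k, seed = seed),
            class = "validation_report")
}

#' Validate an RF model collection by exceedance probability
#'
#' Builds the real distribution of `n_models` re-seeded RF balanced
#' accuracies, then `n_shuffles` y-randomised distributions of
#' `n_models_per_shuffle` each. For every null distribution the histogram
#' overlap and the exceedance probability against the real distribution are
#' computed; the collection is significant when the mean exceedance
#' probability exceeds `prob_cutoff` (0.8 by default, an arbitrary but
#' fixed cut). The overlap is recorded but never used alone as the
#' discriminating value.
#'
#' @param dataset a [build_dataset()] result.
#' @param n_models real-model count (100 in the screening protocol).
#' @param n_shuffles number of y-randomisations (100 in the protocol).
#' @param n_models_per_shuffle models per y-randomisation.
#' @param k folds.
#' @param seed master seed.
#' @param prob_cutoff mean-exceedance-probability cut.
#' @param n_bins histogram bins for the overlap statistic.
#' @param rf_ntree trees per forest.
#' @param real optional precomputed real distribution ([rf_distribution()]).
#' @return list of class `validation_report`: `real` (vector), `nulls`
#'   (list of vectors), `overlaps`, `probabilities`, `ses`,
#'   `mean_probability`, `sd_probability`, `mean_overlap`, `sd_overlap`,
#'   `significant`.
#' @export
validate_rf <- function(dataset, n_models = 100, n_shuffles = 100,
                        n_models_per_shuffle = n_models, k = 10, seed = 1,
                        prob_cutoff = 0.8, n_bins = 20, rf_ntree = 100,
                        real = NULL) {
  if (is.null(real)) {
    real <- rf_distribution(dataset, n_models, k = k,
                            seed = derive_seed(seed, 1), rf_ntree = rf_ntree)
  }
  nulls <- vector("list", n_shuffles)
  overlaps <- numeric(n_shuffles)
  probs <- numeric(n_shuffles)
  ses <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    ds <- dataset
    ds$labels[] <- y_randomise(unname(ds$labels), derive_seed(seed, 200 + s))
    nulls[[s]] <- rf_distribution(ds, n_models_per_shuffle, k = k,
                                  seed = derive_seed(seed, 400 + s),
                                  rf_ntree = rf_ntree)
    overlaps[s] <- overlap_coefficient(real, nulls[[s]], n_bins)
    ex <- exceedance_probability(real, nulls[[s]])
    probs[s] <- ex$p
    ses[s] <- ex$se
  }
  structure(list(method = "random_forest", real = real, nulls = nulls,
                 overlaps = overlaps, probabilities = probs, ses = ses,
                 mean_probability = mean(probs), sd_probability =
                   stats::sd(probs),
                 mean_overlap = mean(overlaps),
                 sd_overlap = stats::sd(overlaps),
                 prob_cutoff = prob_cutoff, n_bins = n_bins,
                 n_models = n_models, n_shuffles = n_shuffles,
                 significant = mean(probs) > prob_cutoff, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$method == "random_forest") {
    cat(sprintf(paste0("RF validation: mean exceedance probability %.3f",
                       " (SD %.3f), mean overlap %.3f (SD %.3f)\n"),
                x$mean_probability, x$sd_probability, x$mean_overlap,
                x$sd_overlap))
    cat(sprintf("  %d real models vs %d y-randomisations; significant: %s\n",
                x$n_models, x$n_shuffles, x$significant))
  } else {
    cat(sprintf("%s validation: real balanced accuracy %.3f at percentile %.1f of %d nulls%s\n",
                x$method, x$real_ba, x$percentile, x$n_random,
                if (isTRUE(x$reduced_nulls)) " (reduced null count)" else ""))
    cat("  significant:", x$significant, "\n")
  }
  invisible(x)
}
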