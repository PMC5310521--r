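# End-to-end convenience wrapper: records -> aggregate curves -> AUC
# comparison -> compound labels -> modelling dataset -> classifier ->
# y-randomisation validation.

#' Run the vehicle-comparison pipeline
#'
#' Chains all stages for one vehicle pair: aggregates the records, compares
#' the two vehicles' curves under the chosen strategy and threshold, rolls
#' verdicts up to compound labels, assembles the modelling dataset, fits
#' the classifier under cross-validation and validates it by
#' y-randomisation.
#'
#' @param records a `tox_records` data.frame (e.g. from
#'   [simulate_toxicity()] or [read_records()]).
#' @param features descriptor matrix with compound-id row names.
#' @param vehicle_a,vehicle_b the vehicle pair (label 0 = less toxic in
#'   `vehicle_a`).
#' @param strategy one of [auc_strategies()].
#' @param threshold_pct AUC-difference threshold (30, 40 or 60 in the
#'   screening protocol).
#' @param method classifier family.
#' @param min_n minimum dataset size.
#' @param k folds.
#' @param n_random null-model count for DT/PLS validation.
#' @param n_models,n_shuffles RF validation sizes.
#' @param seed master seed for folds, forests and y-randomisation.
#' @return list of class `pipeline_result`: `curves`, `comparisons`,
#'   `verdicts`, `dataset`, and (when the dataset passes the size gate)
#'   `model` and `validation`.
#' @export
run_pipeline <- function(records, features, vehicle_a, vehicle_b,
                         strategy = "extrapolate_high_low",
                         threshold_pct = 40,
                         method = c("pls", "decision_tree", "random_forest"),
                         min_n = 50, k = 10, n_random = 300,
                         n_models = 100, n_shuffles = 100, seed = 1) {
  method <- match.arg(method)
  curves <- aggregate_curves(records)
  comparisons <- compare_conditions(curves, vehicle_a, vehicle_b,
                                    strategy, threshold_pct)
  verdicts <- compound_verdicts(comparisons)
  dataset <- build_dataset(verdicts, features, min_n = min_n)
  out <- list(curves = curves, comparisons = comparisons,
              verdicts = verdicts, dataset = dataset, method = method,
              seed = seed)
  if (!dataset$too_small) {
    if (method == "random_forest") {
      out$validation <- validate_rf(dataset, n_models = n_models,
                                    n_shuffles = n_shuffles, k = k,
                                    seed = seed)
      out$model <- list(balanced_accuracy = mean(out$validation$real))
    } else {
      run <- cross_validate(dataset, method, k = k,
                            seed = derive_seed(seed, 1))
      out$model <- run
      out$validation <- validate_dt_pls(dataset, method,
                                        n_random = n_random, k = k,
                                        seed = seed, real_run = run)
    }
  }
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$dataset)
  if (!is.null(x$model) && inherits(x$model, "model_run")) print(x$model)
  if (!is.null(x$validation)) print(x$validation)
  invisible(x)
}
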