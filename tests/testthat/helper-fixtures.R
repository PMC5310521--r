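# In-code fixtures shared across test files.

# A records data.frame built directly in the internal schema.
make_records <- function(compound_id = "cmpd1", vehicle = "saline",
                         dose = c(100, 200, 400),
                         survival = c(1, 0.5, 0),
                         experiment_id = "e01", screener = "s01",
                         species = "mouse", assessment_day = "5",
                         n_animals = 6) {
  n <- max(length(dose), length(survival))
  df <- data.frame(
    compound_id = compound_id, route = "ip", species = species,
    n_injections = "1", injection_interval = "1",
    first_injection_day = "1", n_repetitions = "1",
    assessment_day = assessment_day, restart_days = "",
    vehicle = vehicle, screener = screener, experiment_id = experiment_id,
    dose = dose, survival = survival, n_animals = n_animals,
    stringsAsFactors = FALSE)
  class(df) <- c("tox_records", "data.frame")
  df
}

# Write a records CSV in the canonical file header, with raw string cells.
write_records_csv <- function(rows, path) {
  header <- paste("compound_id,route,species,n_injections,injection_interval",
                  "first_injection_day,n_repetitions,assessment_day",
                  "restart_days,vehicle,screener,experiment_id",
                  "dose_mg_per_kg_per_injection,survival,n_animals",
                  sep = ",")
  writeLines(c(header, rows), path)
}

# One comparison row in the shape compare_conditions() emits, for tests
# that exercise verdict roll-up logic directly.
make_comparison <- function(compound_id, verdict,
                            strategy = "interpolation_only",
                            threshold_pct = 0, species = "mouse",
                            vehicle_a = "saline", vehicle_b = "CMC") {
  data.frame(
    compound_id = compound_id, route = "ip", species = species,
    n_injections = "1", injection_interval = "1",
    first_injection_day = "1", n_repetitions = "1", assessment_day = "5",
    restart_days = "", vehicle_a = vehicle_a, vehicle_b = vehicle_b,
    strategy = strategy, threshold_pct = threshold_pct,
    auc_a = 1, auc_b = 1, rel_diff = 0, verdict = verdict,
    stringsAsFactors = FALSE)
}

# A dataset whose label is a deterministic function of the first feature.
make_separable_dataset <- function(n = 60, p = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * p, 1, 0.4), n, p,
                dimnames = list(sprintf("C%03d", seq_len(n)),
                                paste0("f", seq_len(p))))
    X[, 1] <- rep(c(0, 1), length.out = n)
    y <- X[, 1]
    fake_dataset(X, y)
  })
}

# A dataset whose labels are independent of every feature.
make_null_dataset <- function(n = 60, p = 20, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rbinom(n * p, 1, 0.4), n, p,
                dimnames = list(sprintf("C%03d", seq_len(n)),
                                paste0("f", seq_len(p))))
    y <- rep(c(0, 1), length.out = n)[sample(n)]
    fake_dataset(X, y)
  })
}

# Wrap a feature matrix + labels as a modelling_dataset.
fake_dataset <- function(X, y) {
  structure(list(compounds = rownames(X),
                 labels = stats::setNames(as.integer(y), rownames(X)),
                 features = X, vehicle_a = "saline", vehicle_b = "CMC",
                 counts = list(n_a = sum(y == 0), n_b = sum(y == 1),
                               n_equivocal = 0, n_contradictory = 0,
                               n_no_preference = 0),
                 n = length(y), too_small = FALSE, min_n = 0),
            class = "modelling_dataset")
}

# Independent AUC oracle: dense-grid trapezoidal integration of the
# piecewise-linear interpolant (stats::approxfun), with the curve knots
# merged into the grid so kinks are sampled exactly.
fine_grid_auc <- function(curve, lo, hi, n_grid = 10000) {
  f <- stats::approxfun(curve$dose, curve$survival)
  xs <- sort(unique(c(seq(lo, hi, length.out = n_grid + 1),
                      curve$dose[curve$dose > lo & curve$dose < hi])))
  ys <- f(xs)
  sum(diff(xs) * (ys[-length(ys)] + ys[-1]) / 2)
}

# A random piecewise-linear survival curve for AUC property tests.
random_curve <- function() {
  n <- sample(2:8, 1)
  dose <- sort(runif(n, 1, 1000))
  while (any(diff(dose) < 1e-6)) dose <- sort(runif(n, 1, 1000))
  survival_curve(dose, runif(n))
}
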