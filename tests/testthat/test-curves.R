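test_that("interpolation is linear on the dose axis", {
  c1 <- survival_curve(c(100, 200), c(1, 0))
  expect_equal(interpolate_at(c1, 150), 0.5)
  c2 <- survival_curve(c(1, 2, 4), c(1, 0.8, 0.2))
  expect_equal(interpolate_at(c2, 2), 0.8)   # grid dose returns the point
  expect_equal(interpolate_at(c2, 3), 0.5)   # hand linear-interp oracle
  expect_error(interpolate_at(c2, 5), "outside")
})

test_that("trapezoidal AUC handles rectangle, triangle and kinked curves", {
  flat <- survival_curve(c(1, 101), c(1, 1))
  expect_equal(curve_auc(flat, 1, 101), 100)
  tri <- survival_curve(c(1, 101), c(1, 0))
  expect_equal(curve_auc(tri, 1, 101), 50)
  kinked <- survival_curve(c(1, 2, 4), c(1, 0.8, 0.2))
  expect_equal(curve_auc(kinked, 1, 4), 1.9)  # frozen fine-grid oracle value
  expect_error(curve_auc(kinked, 0.5, 4), "span")
  expect_error(curve_auc(kinked, 3, 3), "empty")
})

test_that("AUC matches fine-grid numeric integration on random curves", {
  set.seed(101)
  for (i in 1:50) {
    cv <- random_curve()
    lo <- min(cv$dose)
    hi <- max(cv$dose)
    oracle <- fine_grid_auc(cv, lo, hi)
    expect_equal(curve_auc(cv, lo, hi), oracle, tolerance = 1e-9)
  }
})

test_that("AUC is monotone in survival", {
  set.seed(7)
  for (i in 1:30) {
    cv <- random_curve()
    lo <- min(cv$dose); hi <- max(cv$dose)
    a0 <- curve_auc(cv, lo, hi)
    j <- sample(length(cv$dose), 1)
    up <- cv
    up$survival[j] <- min(1, up$survival[j] + runif(1, 0, 0.5))
    expect_gte(curve_auc(up, lo, hi), a0 - 1e-12)
  }
})

test_that("high-dose extrapolation extends flat at zero only when eligible", {
  saline <- survival_curve(c(10, 100, 1000), c(1, 0.5, 0), vehicle = "saline")
  cmc <- survival_curve(c(10, 100, 5000), c(1, 0.6, 0.1), vehicle = "CMC")
  ext <- extend_curve(saline, cmc, "extrapolate_high")
  expect_equal(max(ext$dose), 5000)
  expect_equal(ext$survival[length(ext$survival)], 0)
  # survival 0.2 at its own top dose: not eligible, unchanged
  partial <- survival_curve(c(10, 100), c(1, 0.2))
  expect_equal(extend_curve(partial, cmc, "extrapolate_high")$dose,
               partial$dose)
  # interpolation_only never extends
  expect_equal(extend_curve(saline, cmc, "interpolation_only")$dose,
               saline$dose)
})

test_that("low-dose extrapolation requires 100% survival at the lowest dose", {
  a <- survival_curve(c(100, 1000), c(1, 0), vehicle = "a")
  b <- survival_curve(c(10, 2000), c(1, 0.4), vehicle = "b")
  ext <- extend_curve(a, b, "extrapolate_high_low")
  expect_equal(ext$dose[1], 10)
  expect_equal(ext$survival[1], 1)
  expect_equal(max(ext$dose), 2000)  # high end also eligible here
  not_full <- survival_curve(c(100, 1000), c(0.9, 0))
  expect_equal(extend_curve(not_full, b, "extrapolate_high_low")$dose[1], 100)
})

test_that("extension never alters survival inside the original dose range", {
  set.seed(33)
  for (i in 1:20) {
    a <- random_curve()
    b <- random_curve()
    a$survival[length(a$survival)] <- 0
    a$survival[1] <- 1
    ext <- extend_curve(a, b, "extrapolate_high_low")
    probe <- runif(5, min(a$dose), max(a$dose))
    expect_equal(interpolate_at(ext, probe), interpolate_at(a, probe))
  }
})

test_that("the common window is the intersection of dose ranges", {
  mk <- function(lo, hi) survival_curve(c(lo, hi), c(1, 0))
  expect_equal(common_window(mk(1, 10), mk(2, 8)), c(2, 8))
  expect_equal(common_window(mk(1, 10), mk(1, 10)), c(1, 10))
  expect_null(common_window(mk(1, 2), mk(3, 4)))
})

test_that("compare_pair applies the relative-difference threshold", {
  a <- survival_curve(c(1, 101), c(1, 1), vehicle = "A")
  b <- survival_curve(c(1, 101), c(0.5, 0.5), vehicle = "B")
  cmp <- compare_pair(a, b, "interpolation_only", 40)
  expect_equal(cmp$auc_a, 100)
  expect_equal(cmp$auc_b, 50)
  expect_equal(cmp$rel_diff, 50)
  expect_equal(cmp$verdict, "a_less_toxic")
  # equal areas: no difference at every threshold
  for (t in c(0, 30, 40, 60)) {
    expect_equal(compare_pair(a, a, "interpolation_only", t)$verdict,
                 "no_difference")
  }
  # threshold above the observed difference
  expect_equal(compare_pair(a, b, "interpolation_only", 60)$verdict,
               "no_difference")
  # swapping the arguments flips the verdict with identical rel_diff
  rev <- compare_pair(b, a, "interpolation_only", 40)
  expect_equal(rev$verdict, "b_less_toxic")
  expect_equal(rev$rel_diff, cmp$rel_diff)
})

test_that("incomparable pairs are skipped with a reason", {
  a <- survival_curve(c(1, 2), c(1, 0))
  b <- survival_curve(c(10, 20), c(1, 0))
  cmp <- compare_pair(a, b)
  expect_s3_class(cmp, "comparison_skip")
  expect_equal(cmp$reason, "no dose overlap")
  single <- survival_curve(5, 0.5)
  expect_equal(compare_pair(single, a)$reason, "single-point curve")
})

test_that("no-difference counts never decrease as the threshold rises", {
  sim <- simulate_toxicity(sim_config(n_compounds = 40, seed = 5))
  curves <- aggregate_curves(sim$records)
  counts <- vapply(c(30, 40, 60), function(t) {
    cmp <- compare_conditions(curves, "saline", "CMC",
                              "extrapolate_high_low", t)
    sum(cmp$verdict != "no_difference")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("compare_conditions keys comparisons by condition and logs skips", {
  rec <- rbind(
    make_records(vehicle = "saline"),
    make_records(vehicle = "CMC", survival = c(1, 0.9, 0.5),
                 experiment_id = "e02"),
    make_records(compound_id = "lonely", vehicle = "saline",
                 experiment_id = "e03"),
    make_records(compound_id = "apart", vehicle = "saline",
                 dose = c(1, 2), survival = c(1, 0), experiment_id = "e04"),
    make_records(compound_id = "apart", vehicle = "CMC",
                 dose = c(50, 60), survival = c(1, 0), experiment_id = "e05"))
  curves <- aggregate_curves(rec)
  cmp <- compare_conditions(curves, "saline", "CMC")
  expect_equal(cmp$compound_id, "cmpd1")  # lonely has one vehicle only
  skipped <- attr(cmp, "skipped")
  expect_equal(skipped$compound_id, "apart")
  expect_equal(skipped$reason, "no dose overlap")
})
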