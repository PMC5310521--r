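test_that("reading converts percent survival and preserves row order", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- sprintf(
    "cmpd%d,ip,mouse,1,1,1,1,day5,,saline,s01,e%02d,%g,%s,6",
    1:10, 1:10, seq(100, 1000, by = 100),
    c("83%", "100%", "0%", "0.5", "50", "1", "0.33", "17%", "66%", "0"))
  write_records_csv(rows, path)
  rec <- read_records(path)
  expect_equal(nrow(rec), 10)
  expect_equal(rec$compound_id, paste0("cmpd", 1:10))
  expect_equal(rec$survival[1], 0.83)
  expect_equal(rec$survival[4], 0.5)
  expect_equal(rec$survival[5], 0.5)  # bare 50 read as percent
  expect_equal(rec$dose, seq(100, 1000, by = 100))
})

test_that("rows violating invariants are rejected with reasons, not dropped silently", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_records_csv(c(
    "cmpd1,ip,mouse,1,1,1,1,5,,saline,s01,e01,100,0.5,6",
    "cmpd2,ip,mouse,1,1,1,1,5,,saline,s01,e02,0,0.5,6",
    "cmpd3,ip,mouse,1,1,1,1,5,,saline,s01,e03,100,150%,6",
    "cmpd4,ip,mouse,1,1,1,1,5,,saline,s01,e04,100,0.5,7"), path)
  rec <- read_records(path)
  rej <- attr(rec, "rejected")
  expect_equal(rec$compound_id, "cmpd1")
  expect_setequal(rej$compound_id, c("cmpd2", "cmpd3", "cmpd4"))
  expect_equal(rej$reason[rej$compound_id == "cmpd2"], "non-positive dose")
  expect_equal(rej$reason[rej$compound_id == "cmpd3"],
               "survival outside [0,1]")
  # 0.5 * 7 animals = 3.5 survivors: inconsistent with a whole-animal count
  expect_match(rej$reason[rej$compound_id == "cmpd4"], "animal count")
})

test_that("a missing column raises a schema error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,dose", "cmpd1,100"), path)
  expect_error(read_records(path), "vehicle")
})

test_that("a dialect map renames foreign headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    paste("NSC,route,species,n_injections,injection_interval",
          "first_injection_day,n_repetitions,assessment_day,restart_days",
          "vehicle,screener,experiment_id,DOSE,pct_survival,n_animals",
          sep = ","),
    "123,ip,mouse,1,1,1,1,5,,saline,s01,e01,100,83%,6"), path)
  rec <- read_records(path, dialect = c(
    compound_id = "NSC", dose_mg_per_kg_per_injection = "DOSE",
    survival = "pct_survival"))
  expect_equal(rec$compound_id, "123")
  expect_equal(rec$survival, 0.83)
})

test_that("aggregation averages survival per dose within a condition-vehicle group", {
  rec <- rbind(
    make_records(dose = 100, survival = 1.0, experiment_id = "e01"),
    make_records(dose = 100, survival = 0.0, experiment_id = "e02"))
  cur <- aggregate_curves(rec)
  expect_equal(nrow(cur), 1)
  expect_equal(cur$dose, 100)
  expect_equal(cur$survival, 0.5)
  expect_equal(cur$n_experiments, 2)
})

test_that("replicate experiments combine into one mean curve per condition", {
  # six replicates, two of them identical, at shared dose levels
  survs <- list(c(1, 0.8, 0), c(1, 0.6, 0.2), c(0.8, 0.4, 0),
                c(1, 1, 0), c(1, 0.5, 0), c(1, 0.5, 0))
  rec <- do.call(rbind, lapply(1:6, function(i) {
    make_records(dose = c(100, 200, 400), survival = survs[[i]],
                 experiment_id = sprintf("e%02d", i))
  }))
  cur <- aggregate_curves(rec)
  expect_equal(nrow(cur), 3)
  expect_equal(cur$n_experiments, rep(6L, 3))
  expect_equal(cur$survival,
               colMeans(do.call(rbind, survs)), ignore_attr = TRUE)
})

test_that("records differing in a condition-key field form separate curves", {
  rec <- rbind(make_records(assessment_day = "5"),
               make_records(assessment_day = "6", experiment_id = "e02"))
  cur <- aggregate_curves(rec)
  expect_equal(length(unique(cur$assessment_day)), 2)
  expect_equal(nrow(cur), 6)
})

test_that("aggregation is idempotent and permutation invariant", {
  set.seed(42)
  rec <- do.call(rbind, lapply(1:5, function(i) {
    make_records(compound_id = paste0("c", i), dose = sort(runif(4, 1, 100)),
                 survival = round(runif(4) * 6) / 6,
                 experiment_id = paste0("e", i))
  }))
  cur <- aggregate_curves(rec)
  # single-experiment groups: re-aggregating the curve points changes nothing
  rec2 <- cur
  rec2$screener <- "s01"
  rec2$experiment_id <- "re"
  rec2$n_animals <- 6
  cur2 <- aggregate_curves(rec2)
  expect_equal(cur2$dose, cur$dose)
  expect_equal(cur2$survival, cur$survival)
  shuffled <- rec[sample(nrow(rec)), ]
  cur3 <- aggregate_curves(shuffled)
  expect_equal(cur3$dose, cur$dose)
  expect_equal(cur3$survival, cur$survival)
})

test_that("every input row contributes to exactly one aggregated point", {
  sim <- simulate_toxicity(sim_config(n_compounds = 6, seed = 11))
  rec <- sim$records
  cur <- aggregate_curves(rec)
  key <- function(df) do.call(paste, c(df[c(condition_fields(), "vehicle")],
                                       list(df$dose), sep = "|"))
  # observation conservation: the output has one point per distinct
  # (condition, vehicle, dose) and the per-point input counts sum back to
  # the input row count
  expect_equal(nrow(cur), length(unique(key(rec))))
  counts <- table(key(rec))
  expect_equal(sum(counts[key(cur)]), nrow(rec), ignore_attr = TRUE)
})

test_that("curves round-trip losslessly through CSV", {
  sim <- simulate_toxicity(sim_config(n_compounds = 4, seed = 3))
  cur <- aggregate_curves(sim$records)
  cur$survival[1] <- 1 / 3  # not exactly representable in short decimals
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(cur, path)
  back <- read_curves(path)
  expect_identical(back$dose, cur$dose)
  expect_identical(back$survival, cur$survival)
  expect_identical(back$compound_id, cur$compound_id)
  # empty input gives a header-only file
  write_curves(cur[0, ], path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_curves(path)), 0)
})

test_that("get_curve extracts a single condition's curve", {
  rec <- rbind(make_records(vehicle = "saline"),
               make_records(vehicle = "CMC", survival = c(1, 0.8, 0.2),
                            experiment_id = "e02"))
  cur <- aggregate_curves(rec)
  c1 <- get_curve(cur, "cmpd1", "CMC")
  expect_s3_class(c1, "survival_curve")
  expect_equal(c1$survival, c(1, 0.8, 0.2))
  expect_error(get_curve(cur, "cmpdX", "CMC"), "no curve")
})
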