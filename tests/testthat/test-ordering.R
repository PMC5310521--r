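test_that("the preference-ratio rule matches the cluster tallies", {
  expect_equal(preference_shown(17, 4, 1)$direction, "a")
  expect_true(preference_shown(17, 4, 1)$shows_difference)
  expect_equal(preference_shown(12, 12, 5)$direction, "none")
  expect_equal(preference_shown(13, 7, 9)$direction, "none")  # 13 <= 7 + 9
  expect_equal(preference_shown(4, 17, 1)$direction, "b")
  expect_error(preference_shown(-1, 2, 0), "non-negative")
})

test_that("the two directions are mutually exclusive for all count triples", {
  g <- expand.grid(a = 0:50, b = 0:50, nd = c(0:10, 25, 50))
  both <- (g$a > g$b + g$nd) & (g$b > g$a + g$nd)
  expect_false(any(both))
})

dap_tallies <- data.frame(
  vehicle_a = c("CMC", "saline", "MC", "CMC", "saline", "saline"),
  vehicle_b = c("DWA", "DWA", "DWA", "MC", "CMC", "MC"),
  n_a = c(17, 22, 8, 9, 18, 7),
  n_b = c(4, 11, 5, 5, 7, 3),
  n_no_difference = c(1, 0, 0, 1, 9, 1),
  stringsAsFactors = FALSE)

test_that("the phosphoramide-cluster tallies give the linear order saline > CMC > MC > DWA", {
  ord <- build_order_graph(dap_tallies)
  expect_length(ord$findings, 0)
  expect_equal(nrow(ord$equivalent), 0)
  expect_equal(linear_order(ord), c("saline", "CMC", "MC", "DWA"))
})

test_that("a tied pair becomes an equivalence edge without breaking consistency", {
  azir <- data.frame(
    vehicle_a = c("CMC", "saline", "MC", "CMC", "saline", "saline"),
    vehicle_b = c("DWA", "DWA", "DWA", "MC", "CMC", "MC"),
    n_a = c(26, 30, 12, 19, 39, 15),
    n_b = c(17, 18, 12, 12, 18, 8),
    n_no_difference = c(3, 3, 5, 3, 17, 5),
    stringsAsFactors = FALSE)
  ord <- build_order_graph(azir)
  expect_length(ord$findings, 0)
  expect_equal(nrow(ord$equivalent), 1)  # MC = DWA
  expect_setequal(c(ord$equivalent$a, ord$equivalent$b), c("MC", "DWA"))
  expect_null(linear_order(ord))  # not a total strict order
  expect_equal(nrow(ord$strict), 5)
})

test_that("directed cycles among strict relations are reported", {
  cyc <- data.frame(vehicle_a = c("A", "B", "C"),
                    vehicle_b = c("B", "C", "A"),
                    n_a = c(10, 10, 10), n_b = c(0, 0, 0),
                    n_no_difference = c(0, 0, 0))
  ord <- build_order_graph(cyc)
  expect_length(ord$findings, 1)
  expect_equal(ord$findings[[1]]$type, "cycle")
  expect_setequal(ord$findings[[1]]$vehicles, c("A", "B", "C"))
  expect_null(linear_order(ord))
})

test_that("an equivalence path contradicted by a strict relation is reported", {
  # the nitrogen-mustard pattern: A > B observed strictly while A = C and
  # C = B claim equivalence
  mix <- data.frame(vehicle_a = c("A", "A", "C"),
                    vehicle_b = c("B", "C", "B"),
                    n_a = c(10, 3, 3), n_b = c(0, 3, 3),
                    n_no_difference = c(0, 3, 3))
  ord <- build_order_graph(mix)
  types <- vapply(ord$findings, `[[`, character(1), "type")
  expect_true("contradiction" %in% types)
  contra <- ord$findings[[which(types == "contradiction")[1]]]
  expect_setequal(contra$vehicles, c("A", "B"))
})

test_that("an empty tally list gives an empty graph", {
  ord <- build_order_graph(dap_tallies[0, ])
  expect_length(ord$vehicles, 0)
  expect_length(ord$findings, 0)
  expect_equal(nrow(ord$strict), 0)
})

test_that("adding a tally never removes existing edges", {
  part <- build_order_graph(dap_tallies[1:3, ])
  full <- build_order_graph(dap_tallies)
  key <- function(o) paste(o$strict$from, o$strict$to)
  expect_true(all(key(part) %in% key(full)))
})

test_that("DOT export lists vehicles, strict arrows and tallies", {
  dot <- order_to_dot(build_order_graph(dap_tallies))
  expect_match(dot, "digraph")
  expect_match(dot, '"saline" -> "CMC" \\[label="18 : 7 : 9"\\]')
  path <- withr::local_tempfile(fileext = ".dot")
  order_to_dot(build_order_graph(dap_tallies), path)
  expect_true(file.exists(path))
})

test_that("cluster verdicts demand unanimity across strategies and conditions", {
  mk <- function(compound, verdicts_by_strategy, species = "mouse") {
    do.call(rbind, Map(function(s, v) {
      make_comparison(compound, v, strategy = s, species = species)
    }, auc_strategies(), verdicts_by_strategy))
  }
  cmp <- rbind(
    mk("u1", c("a_less_toxic", "a_less_toxic", "a_less_toxic")),
    mk("u2", c("b_less_toxic", "b_less_toxic", "b_less_toxic")),
    mk("u3", c("a_less_toxic", "b_less_toxic", "a_less_toxic")),
    mk("u4", c("no_difference", "no_difference", "no_difference")),
    mk("u5", c("a_less_toxic", "a_less_toxic", "no_difference")),
    mk("u6", c("a_less_toxic", "a_less_toxic", "a_less_toxic")),
    mk("u6", c("a_less_toxic", "a_less_toxic", "b_less_toxic"),
       species = "rat"))
  v <- cluster_compound_verdicts(cmp)
  got <- setNames(v$verdict, v$compound_id)
  expect_equal(got[["u1"]], "less_toxic_a")
  expect_equal(got[["u2"]], "less_toxic_b")
  expect_equal(got[["u3"]], "excluded")
  expect_equal(got[["u4"]], "no_difference")
  expect_equal(got[["u5"]], "excluded")
  expect_equal(got[["u6"]], "excluded")  # disagreement across conditions
  tal <- tally_preferences(v)
  expect_equal(tal$n_a, 1)
  expect_equal(tal$n_b, 1)
  expect_equal(tal$n_no_difference, 1)
})

test_that("missing strategy coverage is an input error", {
  cmp <- make_comparison("u1", "a_less_toxic",
                         strategy = "interpolation_only")
  expect_error(cluster_compound_verdicts(cmp), "strategy")
  thr <- make_comparison("u1", "a_less_toxic", threshold_pct = 30)
  expect_error(cluster_compound_verdicts(thr), "threshold")
})

test_that("SMARTS matching finds phosphoramide and aziridine substructures", {
  skip_if_not_installed("ChemmineR")
  skip_if_not_installed("ChemmineOB")
  smiles <- c(thiotepa = "C1CN1P(=S)(N1CC1)N1CC1",
              benzene = "c1ccccc1",
              aziridine = "C1CN1CCO")
  expect_setequal(match_cluster(smiles, "NP(=[O,S])(N)(N)"), "thiotepa")
  expect_setequal(match_cluster(smiles, "C1CN1"),
                  c("thiotepa", "aziridine"))
  expect_equal(match_cluster(character(), "C1CN1"), character())
  expect_warning(m <- match_cluster(c(good = "CCO", bad = "not_a_smiles"),
                                    "CO"), "unparseable")
  expect_equal(m, "good")
})

test_that("an injected vehicle hierarchy is recovered from synthetic curves", {
  vehicles <- c("V1", "V2", "V3", "V4")
  cfg <- sim_config(n_compounds = 20, vehicles = vehicles,
                    effect_fraction = 0,
                    vehicle_offsets = c(V1 = 2.25, V2 = 0.75,
                                        V3 = -0.75, V4 = -2.25),
                    animals_per_dose = c(8, 8),
                    replicates_per_condition = c(1, 1), seed = 31)
  curves <- aggregate_curves(simulate_toxicity(cfg)$records)
  tallies <- do.call(rbind, lapply(seq_len(nrow(vehicle_pairs(vehicles))),
    function(i) {
      p <- vehicle_pairs(vehicles)[i, ]
      cmp <- compare_all_strategies(curves, p$vehicle_a, p$vehicle_b, 0)
      tally_preferences(cluster_compound_verdicts(cmp))
    }))
  ord <- build_order_graph(tallies)
  expect_length(ord$findings, 0)
  expect_equal(linear_order(ord), vehicles)
})
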