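# Synthetic dose-survival generator with known ground-truth vehicle
# effects. The model: survival of a dose group follows a logistic in
# log-dose, s(d) = 1 / (1 + exp(slope * (ln d - ln LD50))), where the
# compound-and-vehicle LD50 is a base value shifted by structural-feature x
# vehicle interactions and/or whole-vehicle offsets. Observed survival is
# Binomial(n_animals, s) / n_animals, so the non-monotone "noise" typical of
# small-group screens (single-animal deaths) arises naturally; no extra
# noise term is added.

#' Configuration for the synthetic screen
#'
#' @param n_compounds number of compounds.
#' @param n_features number of binary structural keys; the feature matrix
#'   doubles as the descriptor matrix downstream.
#' @param vehicles character vector of at least two vehicle names.
#' @param n_effect_features how many leading features are predictive; by
#'   default half shift toxicity down and half up in `vehicles[2]`.
#' @param shift_magnitude absolute log-potency shift (natural-log LD50
#'   units) attached to each effect feature.
#' @param feature_shifts optional data.frame (`feature`, `vehicle`, `shift`)
#'   overriding the default effect-feature construction.
#' @param vehicle_offsets optional named numeric vector of whole-vehicle
#'   log-LD50 offsets (used for cluster-level vehicle hierarchies).
#' @param effect_fraction fraction of compounds carrying an effect feature.
#' @param slope logistic steepness on the natural-log dose axis.
#' @param base_log_ld50_range range (natural log, mg/kg/injection) from
#'   which each compound's baseline LD50 is drawn.
#' @param doses_per_experiment number of dose levels per experiment (>= 2).
#' @param dose_step geometric spacing of the dose grid in natural-log units.
#' @param animals_per_dose integer range `c(lo, hi)` of animals per dose
#'   group; screens typically used 6-10.
#' @param replicates_per_condition integer range of replicate experiments
#'   per (compound, vehicle).
#' @param background_feature_rate Bernoulli rate of non-effect features.
#' @param null_mode logical; `TRUE` zeroes every shift and offset so no
#'   compound has a vehicle effect.
#' @param seed master seed; all randomness flows from it through
#'   per-compound substreams, so compound `i`'s data is stable when
#'   `n_compounds` changes.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_compounds = 100, n_features = 20,
                       vehicles = c("saline", "CMC"),
                       n_effect_features = 2, shift_magnitude = 2,
                       feature_shifts = NULL, vehicle_offsets = NULL,
                       effect_fraction = 0.5, slope = 3,
                       base_log_ld50_range = log(c(50, 500)),
                       doses_per_experiment = 5, dose_step = 1.5,
                       animals_per_dose = c(6, 10),
                       replicates_per_condition = c(1, 2),
                       background_feature_rate = 0.3,
                       null_mode = FALSE, seed = 1) {
  if (length(vehicles) < 2) stop("need at least two vehicles")
  if (effect_fraction < 0 || effect_fraction > 1) {
    stop("effect_fraction must lie in [0, 1]")
  }
  if (doses_per_experiment < 2) stop("need at least two doses per experiment")
  if (diff(range(animals_per_dose)) < 0 || min(animals_per_dose) < 1) {
    stop("animals_per_dose must be a positive range")
  }
  if (is.null(feature_shifts)) {
    if (n_effect_features > n_features) stop("more effect features than features")
    k <- n_effect_features
    feature_shifts <- data.frame(
      feature = seq_len(k),
      vehicle = vehicles[2],
      # half the keys make vehicles[2] safer, half make it more toxic, so
      # labelled datasets contain both classes
      shift = shift_magnitude * rep(c(1, -1), length.out = k),
      stringsAsFactors = FALSE)
  }
  if (is.null(vehicle_offsets)) {
    vehicle_offsets <- stats::setNames(numeric(length(vehicles)), vehicles)
  }
  structure(list(
    n_compounds = n_compounds, n_features = n_features, vehicles = vehicles,
    feature_shifts = feature_shifts, vehicle_offsets = vehicle_offsets,
    effect_fraction = effect_fraction, slope = slope,
    base_log_ld50_range = base_log_ld50_range,
    doses_per_experiment = doses_per_experiment, dose_step = dose_step,
    animals_per_dose = animals_per_dose,
    replicates_per_condition = replicates_per_condition,
    background_feature_rate = background_feature_rate,
    null_mode = null_mode, seed = seed), class = "sim_config")
}

# One experiment's worth of records for a compound in one vehicle under a
# given condition. Assumes the caller controls the RNG stream.
.sim_experiment <- function(cfg, cid, vehicle, ln_ld50, base_ln, exp_id,
                            condition) {
  m <- cfg$doses_per_experiment
  jitter <- stats::runif(1, -0.25, 0.25)
  lnd <- base_ln + jitter + cfg$dose_step * (seq_len(m) - (m + 1) / 2)
  n_animals <- sample(seq(cfg$animals_per_dose[1], cfg$animals_per_dose[2]),
                      m, replace = TRUE)
  s_true <- stats::plogis(-cfg$slope * (lnd - ln_ld50))
  surv <- stats::rbinom(m, n_animals, s_true) / n_animals
  data.frame(compound_id = cid, route = condition$route,
             species = condition$species, n_injections = "1",
             injection_interval = "1", first_injection_day = "1",
             n_repetitions = "1", assessment_day = "5", restart_days = "",
             vehicle = vehicle,
             screener = sample(c("s01", "s02", "s03"), 1),
             experiment_id = exp_id, dose = exp(lnd), survival = surv,
             n_animals = n_animals, stringsAsFactors = FALSE)
}

#' Simulate a synthetic dose-survival screen
#'
#' Generates records for every compound in every configured vehicle, the
#' per-pair ground truth (which vehicle is genuinely less toxic, or "none"),
#' and the binary feature matrix. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `tox_simulation` with `records` (a `tox_records`
#'   data.frame), `truth` (data.frame `compound_id`, `vehicle_a`,
#'   `vehicle_b`, `less_toxic` with `"none"` for no effect), `features`
#'   (compound x feature 0/1 matrix) and `config`.
#' @export
simulate_toxicity <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n <- cfg$n_compounds
  ids <- sprintf("C%04d", seq_len(n))
  eff_feats <- unique(cfg$feature_shifts$feature)
  pairs <- vehicle_pairs(cfg$vehicles)
  feats <- matrix(0L, n, cfg$n_features,
                  dimnames = list(ids, paste0("f", seq_len(cfg$n_features))))
  rec_list <- vector("list", n)
  truth_list <- vector("list", n)
  for (i in seq_len(n)) {
    with_seed(derive_seed(cfg$seed, i), {
      fv <- stats::rbinom(cfg$n_features, 1, cfg$background_feature_rate)
      fv[eff_feats] <- 0L
      is_effect <- stats::runif(1) < cfg$effect_fraction
      if (is_effect && length(eff_feats)) {
        fv[sample(eff_feats, 1)] <- 1L
      }
      feats[i, ] <- fv
      base_ln <- stats::runif(1, cfg$base_log_ld50_range[1],
                              cfg$base_log_ld50_range[2])
      ln_ld50 <- vapply(cfg$vehicles, function(v) {
        if (cfg$null_mode) return(base_ln)
        shift <- sum(cfg$feature_shifts$shift[
          cfg$feature_shifts$vehicle == v &
            fv[cfg$feature_shifts$feature] == 1L])
        base_ln + cfg$vehicle_offsets[[v]] + shift
      }, numeric(1))
      truth_list[[i]] <- data.frame(
        compound_id = ids[i], vehicle_a = pairs$vehicle_a,
        vehicle_b = pairs$vehicle_b,
        less_toxic = ifelse(
          abs(ln_ld50[pairs$vehicle_a] - ln_ld50[pairs$vehicle_b]) < 1e-12,
          "none",
          ifelse(ln_ld50[pairs$vehicle_a] > ln_ld50[pairs$vehicle_b],
                 pairs$vehicle_a, pairs$vehicle_b)),
        stringsAsFactors = FALSE)
      exps <- list()
      for (v in cfg$vehicles) {
        n_rep <- sample(seq(cfg$replicates_per_condition[1],
                            cfg$replicates_per_condition[2]), 1)
        for (r in seq_len(n_rep)) {
          exps[[length(exps) + 1]] <- .sim_experiment(
            cfg, ids[i], v, ln_ld50[[v]], base_ln,
            exp_id = sprintf("e_%s_%s_%d", ids[i], v, r),
            condition = list(route = "ip", species = "mouse"))
        }
      }
      rec_list[[i]] <- do.call(rbind, exps)
    })
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  class(records) <- c("tox_records", "data.frame")
  structure(list(records = records,
                 truth = do.call(rbind, truth_list),
                 features = feats, config = cfg),
            class = "tox_simulation")
}

#' Inject equivocal outcomes
#'
#' For a chosen fraction of the compounds with a genuine vehicle effect,
#' adds a second experimental condition (a different host species) whose
#' simulated vehicle shift is zero. Downstream, such compounds show a
#' preference under one condition and no difference under the other, so the
#' labelling stage should call them equivocal.
#'
#' @param sim a [simulate_toxicity()] result.
#' @param fraction fraction of effect compounds to degrade, in \[0, 1\].
#' @param seed seed for the compound selection and the extra records.
#' @return the simulation with extra records appended and the chosen
#'   compound ids in `$degraded`.
#' @export
degrade_to_equivocal <- function(sim, fraction, seed = sim$config$seed + 1) {
  stopifnot(inherits(sim, "tox_simulation"))
  if (fraction < 0 || fraction > 1) stop("fraction must lie in [0, 1]")
  cfg <- sim$config
  effect_ids <- unique(sim$truth$compound_id[sim$truth$less_toxic != "none"])
  n_pick <- round(fraction * length(effect_ids))
  if (n_pick == 0) {
    sim$degraded <- character()
    return(sim)
  }
  picked <- with_seed(derive_seed(seed, 0), {
    sort(sample(effect_ids, n_pick))
  })
  extra <- vector("list", length(picked))
  for (j in seq_along(picked)) {
    cid <- picked[j]
    i <- match(cid, rownames(sim$features))
    extra[[j]] <- with_seed(derive_seed(seed, 100000 + i), {
      base_ln <- mean(cfg$base_log_ld50_range)
      exps <- lapply(cfg$vehicles, function(v) {
        .sim_experiment(cfg, cid, v, base_ln, base_ln,
                        exp_id = sprintf("e_%s_%s_eq", cid, v),
                        condition = list(route = "ip", species = "rat"))
      })
      do.call(rbind, exps)
    })
  }
  records <- rbind(as.data.frame(sim$records), do.call(rbind, extra))
  rownames(records) <- NULL
  class(records) <- c("tox_records", "data.frame")
  sim$records <- records
  sim$degraded <- picked
  sim
}
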