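# Pairwise comparison of aggregate dose-survival curves by area under the
# curve (AUC). Larger AUC over a common dose window means higher survival,
# i.e. the compound is less toxic in that vehicle. The dose axis is LINEAR
# throughout; log axes in screening plots are cosmetic only.

#' Interpolation/extrapolation strategies
#'
#' Three ways to align the dose windows of two curves before integration:
#' `interpolation_only` (boundary interpolation, no extension),
#' `extrapolate_high` (additionally extend a curve flat at zero survival
#' beyond its top dose when survival has already fallen to zero), and
#' `extrapolate_high_low` (additionally extend flat at 100% survival below
#' the lowest dose when survival there is still 100%).
#'
#' @return character vector of the three strategy names.
#' @export
auc_strategies <- function() {
  c("interpolation_only", "extrapolate_high", "extrapolate_high_low")
}

#' Construct a dose-survival curve
#'
#' @param dose numeric vector of positive doses (mg per kg per injection).
#' @param survival survival fractions in \[0, 1\], same length as `dose`.
#' @param vehicle optional vehicle name carried along for reporting.
#' @param n_experiments optional count of aggregated experiments.
#' @return object of class `survival_curve` with points sorted by strictly
#'   increasing dose.
#' @export
survival_curve <- function(dose, survival, vehicle = NA_character_,
                           n_experiments = NA_integer_) {
  if (length(dose) < 1 || length(dose) != length(survival)) {
    stop("dose and survival must be non-empty and of equal length")
  }
  if (any(!is.finite(dose)) || any(dose <= 0)) stop("doses must be positive")
  if (any(!is.finite(survival)) || any(survival < -1e-12) ||
      any(survival > 1 + 1e-12)) {
    stop("survival values must lie in [0, 1]")
  }
  o <- order(dose)
  dose <- dose[o]
  survival <- pmin(pmax(survival[o], 0), 1)
  if (any(diff(dose) <= 0)) stop("doses must be strictly increasing")
  structure(list(dose = dose, survival = survival, vehicle = vehicle,
                 n_experiments = n_experiments),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  cat("dose-survival curve",
      if (!is.na(x$vehicle)) paste0("(", x$vehicle, ")"), "with",
      length(x$dose), "points over [",
      format(min(x$dose)), ",", format(max(x$dose)), "] mg/kg/injection\n")
  invisible(x)
}

#' Survival at a dose by linear interpolation
#'
#' Linear interpolation between the bracketing curve points on the linear
#' dose axis; a dose equal to a grid level returns that point's survival.
#'
#' @param curve a [survival_curve()].
#' @param dose dose(s) inside the curve's range.
#' @return survival fraction(s).
#' @export
interpolate_at <- function(curve, dose) {
  rng <- range(curve$dose)
  if (any(dose < rng[1] - 1e-12) || any(dose > rng[2] + 1e-12)) {
    stop("dose outside curve range [", rng[1], ", ", rng[2], "]")
  }
  if (length(curve$dose) == 1) return(rep(curve$survival, length(dose)))
  stats::approx(curve$dose, curve$survival, xout = pmin(pmax(dose, rng[1]),
                                                        rng[2]))$y
}

#' Extend a curve toward another curve's dose range
#'
#' Flat (constant-survival) extension only. Under `extrapolate_high` (and
#' `extrapolate_high_low`) a curve whose survival at its own top dose is
#' zero is extended at zero up to the other curve's larger top dose. Under
#' `extrapolate_high_low` a curve whose survival at its lowest recorded dose
#' is 100% is additionally extended at 100% down to the other curve's
#' smaller bottom dose. Ineligible curves pass through unchanged. End-point
#' survival is tested against 0/1 with tolerance 1e-9 since aggregated means
#' are floats.
#'
#' @param curve curve to extend.
#' @param other the comparison curve whose range may be wider.
#' @param strategy one of [auc_strategies()].
#' @return possibly extended `survival_curve`.
#' @export
extend_curve <- function(curve, other,
                         strategy = c("interpolation_only",
                                      "extrapolate_high",
                                      "extrapolate_high_low")) {
  strategy <- match.arg(strategy)
  if (strategy == "interpolation_only") return(curve)
  tol <- 1e-9
  dose <- curve$dose
  surv <- curve$survival
  n <- length(dose)
  if (surv[n] <= tol && max(other$dose) > dose[n]) {
    dose <- c(dose, max(other$dose))
    surv <- c(surv, 0)
  }
  if (strategy == "extrapolate_high_low" &&
      surv[1] >= 1 - tol && min(other$dose) < dose[1]) {
    dose <- c(min(other$dose), dose)
    surv <- c(1, surv)
  }
  survival_curve(dose, surv, vehicle = curve$vehicle,
                 n_experiments = curve$n_experiments)
}

#' Common dose window of two curves
#'
#' @param curve_a,curve_b curves (after any extension).
#' @return numeric `c(lo, hi)`, or `NULL` when the ranges do not overlap
#'   (the pair is incomparable and the comparison is skipped).
#' @export
common_window <- function(curve_a, curve_b) {
  lo <- max(min(curve_a$dose), min(curve_b$dose))
  hi <- min(max(curve_a$dose), max(curve_b$dose))
  if (!(lo < hi)) return(NULL)
  c(lo, hi)
}

#' Area under a dose-survival curve
#'
#' Trapezoidal area of the piecewise-linear curve over \[lo, hi\] on the
#' linear dose axis, with boundary survivals obtained by interpolation.
#' Units: survival fraction x dose.
#'
#' @param curve a [survival_curve()] spanning the window.
#' @param lo,hi window bounds, `lo < hi`.
#' @return non-negative area.
#' @export
curve_auc <- function(curve, lo, hi) {
  if (!(lo < hi)) stop("window is empty (lo >= hi)")
  if (lo < min(curve$dose) - 1e-12 || hi > max(curve$dose) + 1e-12) {
    stop("curve does not span the window")
  }
  inner <- curve$dose[curve$dose > lo & curve$dose < hi]
  knots <- c(lo, inner, hi)
  s <- interpolate_at(curve, knots)
  sum(diff(knots) * (s[-length(s)] + s[-1]) / 2)
}

#' Compare two curves by AUC
#'
#' Extends both curves according to the strategy, computes the common dose
#' window and both trapezoidal AUCs, and calls the larger-AUC vehicle less
#' toxic when the relative difference `100 * |auc_a - auc_b| /
#' max(auc_a, auc_b)` meets the threshold. With `threshold_pct = 0` the
#' comparison is a strict sign test (relative difference above 1e-9 counts).
#'
#' @param curve_a,curve_b curves sharing one condition key.
#' @param strategy one of [auc_strategies()].
#' @param threshold_pct percent AUC difference required to call a
#'   difference; the screening analysis uses 30, 40 or 60 (0 = sign test).
#' @return list of class `comparison_verdict` with fields `vehicle_a`,
#'   `vehicle_b`, `strategy`, `threshold_pct`, `auc_a`, `auc_b`, `rel_diff`
#'   (percent), `verdict` (`a_less_toxic`, `b_less_toxic` or
#'   `no_difference`) and `window`; or a `comparison_skip` object carrying
#'   a `reason` when the pair is incomparable (no window overlap or a
#'   single-point curve).
#' @export
compare_pair <- function(curve_a, curve_b,
                         strategy = "interpolation_only", threshold_pct = 0) {
  if (threshold_pct < 0) stop("threshold_pct must be >= 0")
  skip <- function(why) structure(list(reason = why),
                                  class = "comparison_skip")
  ea <- extend_curve(curve_a, curve_b, strategy)
  eb <- extend_curve(curve_b, curve_a, strategy)
  if (length(ea$dose) < 2 || length(eb$dose) < 2) {
    return(skip("single-point curve"))
  }
  win <- common_window(ea, eb)
  if (is.null(win)) return(skip("no dose overlap"))
  auc_a <- curve_auc(ea, win[1], win[2])
  auc_b <- curve_auc(eb, win[1], win[2])
  m <- max(auc_a, auc_b)
  rel <- if (m <= 0) 0 else 100 * abs(auc_a - auc_b) / m
  differs <- if (threshold_pct > 0) rel >= threshold_pct else rel > 1e-9 * 100
  verdict <- if (m <= 0 || !differs) "no_difference"
             else if (auc_a > auc_b) "a_less_toxic" else "b_less_toxic"
  structure(list(vehicle_a = curve_a$vehicle, vehicle_b = curve_b$vehicle,
                 strategy = strategy, threshold_pct = threshold_pct,
                 auc_a = auc_a, auc_b = auc_b, rel_diff = rel,
                 verdict = verdict, window = win),
            class = "comparison_verdict")
}

#' Compare two vehicles across all shared conditions
#'
#' Splits an aggregate-curve table by condition key and compares the two
#' vehicles' curves wherever both were tested under the same condition.
#' Incomparable conditions (no dose overlap, single-point curves) are
#' skipped and recorded in the `"skipped"` attribute.
#'
#' @param curves `tox_curves` data.frame from [aggregate_curves()].
#' @param vehicle_a,vehicle_b vehicle names; `vehicle_a` is the reference
#'   (label 0 downstream).
#' @param strategy one of [auc_strategies()].
#' @param threshold_pct AUC-difference threshold in percent.
#' @return data.frame with the condition-key columns plus `vehicle_a`,
#'   `vehicle_b`, `strategy`, `threshold_pct`, `auc_a`, `auc_b`, `rel_diff`
#'   and `verdict`; attribute `skipped` lists skipped conditions and reasons.
#' @export
compare_conditions <- function(curves, vehicle_a, vehicle_b,
                               strategy = "interpolation_only",
                               threshold_pct = 0) {
  df <- as.data.frame(curves)
  df <- df[df$vehicle %in% c(vehicle_a, vehicle_b), , drop = FALSE]
  key <- .group_id(df, with_vehicle = FALSE)
  rows <- list()
  skipped <- list()
  for (ix in split(seq_len(nrow(df)), key)) {
    g <- df[ix, , drop = FALSE]
    if (!all(c(vehicle_a, vehicle_b) %in% g$vehicle)) next
    ga <- g[g$vehicle == vehicle_a, , drop = FALSE]
    gb <- g[g$vehicle == vehicle_b, , drop = FALSE]
    ca <- survival_curve(ga$dose, ga$survival, vehicle = vehicle_a)
    cb <- survival_curve(gb$dose, gb$survival, vehicle = vehicle_b)
    cmp <- compare_pair(ca, cb, strategy, threshold_pct)
    keydf <- g[1, condition_fields(), drop = FALSE]
    if (inherits(cmp, "comparison_skip")) {
      skipped[[length(skipped) + 1]] <- cbind(keydf, reason = cmp$reason)
      next
    }
    rows[[length(rows) + 1]] <- cbind(
      keydf, vehicle_a = vehicle_a, vehicle_b = vehicle_b,
      strategy = strategy, threshold_pct = threshold_pct,
      auc_a = cmp$auc_a, auc_b = cmp$auc_b, rel_diff = cmp$rel_diff,
      verdict = cmp$verdict)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(df[0, condition_fields(), drop = FALSE],
          vehicle_a = character(), vehicle_b = character(),
          strategy = character(), threshold_pct = numeric(),
          auc_a = numeric(), auc_b = numeric(), rel_diff = numeric(),
          verdict = character())
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else NULL
  out
}

#' Compare two vehicles under all three strategies
#'
#' Convenience wrapper used by the cluster-ordering analysis, which requires
#' the AUC comparison to point the same way however the interpolation or
#' extrapolation is done.
#'
#' @inheritParams compare_conditions
#' @return row-bound data.frame of [compare_conditions()] results for the
#'   three strategies.
#' @export
compare_all_strategies <- function(curves, vehicle_a, vehicle_b,
                                   threshold_pct = 0) {
  out <- lapply(auc_strategies(), function(s) {
    compare_conditions(curves, vehicle_a, vehicle_b, s, threshold_pct)
  })
  res <- do.call(rbind, out)
  attr(res, "skipped") <- do.call(rbind, lapply(out, attr, "skipped"))
  res
}
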