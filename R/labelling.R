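# Roll per-condition AUC verdicts up to compound-level labels and assemble
# modelling datasets. A compound tested under several comparable conditions
# only receives a class label when every condition points the same way;
# mixed outcomes are excluded as equivocal (preference in some conditions,
# none in others) or contradictory (opposite preferences).

#' Compound-level verdicts from per-condition comparisons
#'
#' For each compound, reduces the multiset of its per-condition AUC verdicts
#' to one of: `prefers_a` / `prefers_b` (only that direction observed),
#' `no_preference` (only no-difference observed), `equivocal` (one direction
#' plus at least one no-difference) or `contradictory` (both directions
#' observed; takes precedence over equivocal).
#'
#' @param comparisons data.frame from [compare_conditions()] for a single
#'   vehicle pair, strategy and threshold.
#' @return data.frame `compound_id`, `vehicle_a`, `vehicle_b`,
#'   `n_conditions`, `verdict`.
#' @export
compound_verdicts <- function(comparisons) {
  df <- as.data.frame(comparisons)
  if (!nrow(df)) {
    return(data.frame(compound_id = character(), vehicle_a = character(),
                      vehicle_b = character(), n_conditions = integer(),
                      verdict = character(), stringsAsFactors = FALSE))
  }
  if (length(unique(df$vehicle_a)) > 1 || length(unique(df$vehicle_b)) > 1 ||
      length(unique(df$strategy)) > 1 ||
      length(unique(df$threshold_pct)) > 1) {
    stop("comparisons must come from one (vehicle pair, strategy, threshold)")
  }
  out <- lapply(split(df, df$compound_id), function(g) {
    has_a <- any(g$verdict == "a_less_toxic")
    has_b <- any(g$verdict == "b_less_toxic")
    has_nd <- any(g$verdict == "no_difference")
    verdict <- if (has_a && has_b) "contradictory"
      else if ((has_a || has_b) && has_nd) "equivocal"
      else if (has_a) "prefers_a"
      else if (has_b) "prefers_b"
      else "no_preference"
    data.frame(compound_id = g$compound_id[1], vehicle_a = g$vehicle_a[1],
               vehicle_b = g$vehicle_b[1], n_conditions = nrow(g),
               verdict = verdict, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble a modelling dataset
#'
#' Keeps only compounds with a decided preference (label 0 = less toxic in
#' `vehicle_a`, 1 = less toxic in `vehicle_b`), records the excluded
#' equivocal/contradictory/no-preference counts, and flags datasets smaller
#' than `min_n` (the screening analysis models only sets of 50 or more).
#'
#' @param verdicts data.frame from [compound_verdicts()].
#' @param features numeric descriptor matrix with compound ids as row
#'   names (binary structural keys and real-valued global properties both
#'   allowed), or a data.frame with a `compound_id` column.
#' @param min_n minimum dataset size; smaller sets are flagged `too_small`.
#' @return list of class `modelling_dataset`: `compounds`, `labels` (named
#'   0/1 integer), `features`, `vehicle_a`, `vehicle_b`, `counts` (n_a, n_b,
#'   n_equivocal, n_contradictory, n_no_preference), `n`, `too_small`,
#'   `min_n`.
#' @export
build_dataset <- function(verdicts, features, min_n = 50) {
  if (is.data.frame(features) && "compound_id" %in% names(features)) {
    rn <- features$compound_id
    features <- as.matrix(features[setdiff(names(features), "compound_id")])
    rownames(features) <- rn
  }
  v <- as.data.frame(verdicts)
  labelled <- v[v$verdict %in% c("prefers_a", "prefers_b"), , drop = FALSE]
  counts <- list(
    n_a = sum(v$verdict == "prefers_a"),
    n_b = sum(v$verdict == "prefers_b"),
    n_equivocal = sum(v$verdict == "equivocal"),
    n_contradictory = sum(v$verdict == "contradictory"),
    n_no_preference = sum(v$verdict == "no_preference"))
  ids <- labelled$compound_id
  missing <- setdiff(ids, rownames(features))
  if (length(missing)) {
    stop("no feature rows for compound(s): ", paste(missing, collapse = ", "))
  }
  labels <- stats::setNames(as.integer(labelled$verdict == "prefers_b"), ids)
  structure(list(
    compounds = ids, labels = labels,
    features = features[ids, , drop = FALSE],
    vehicle_a = if (nrow(v)) v$vehicle_a[1] else NA_character_,
    vehicle_b = if (nrow(v)) v$vehicle_b[1] else NA_character_,
    counts = counts, n = length(ids),
    too_small = length(ids) < min_n, min_n = min_n),
    class = "modelling_dataset")
}

#' @export
print.modelling_dataset <- function(x, ...) {
  cat(sprintf("modelling dataset %s vs %s: %d compounds (%d : %d)%s\n",
              x$vehicle_a, x$vehicle_b, x$n, x$counts$n_a, x$counts$n_b,
              if (x$too_small) sprintf(" [too small, min_n = %d]", x$min_n)
              else ""))
  cat(sprintf("  excluded: %d equivocal, %d contradictory, %d no-preference\n",
              x$counts$n_equivocal, x$counts$n_contradictory,
              x$counts$n_no_preference))
  invisible(x)
}

#' Class bias of a modelling dataset
#'
#' Ratio of the larger to the smaller class; the screening datasets were
#' quite balanced, with biases of 2.2:1 or less.
#'
#' @param dataset a [build_dataset()] result (or a list with `counts`).
#' @return numeric >= 1, or `NA` with a warning when a class is empty.
#' @export
class_bias <- function(dataset) {
  n_a <- dataset$counts$n_a
  n_b <- dataset$counts$n_b
  if (min(n_a, n_b) == 0) {
    warning("one class is empty; bias undefined")
    return(NA_real_)
  }
  max(n_a, n_b) / min(n_a, n_b)
}
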