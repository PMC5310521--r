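# Substructure-cluster vehicle ordering. Compounds sharing a substructure
# (matched by a SMARTS pattern) are tallied per vehicle pair using
# sign-consistent no-threshold AUC verdicts; the preference-ratio rule
# decides whether the cluster shows a difference for the pair; the
# resulting relations assemble into a partial-order graph over vehicles
# with consistency checking (directed cycles, equivalence contradictions).

#' Match compounds against a SMARTS substructure
#'
#' Returns the ids of compounds whose structure contains at least one match
#' of the pattern. Structures may be SMILES strings (named by compound id)
#' or a `ChemmineR::SDFset`. Requires the ChemmineR and ChemmineOB packages
#' (openbabel backend). Unparseable structures are skipped with a warning.
#'
#' @param structures named character vector of SMILES, or an `SDFset` whose
#'   ids are compound ids.
#' @param pattern SMARTS string, e.g. `"NP(=[O,S])(N)(N)"` for
#'   phosphoramides or `"C1CN1"` for an aziridine ring.
#' @return character vector of matching compound ids.
#' @export
match_cluster <- function(structures, pattern) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMARTS matching requires the ChemmineR and ChemmineOB packages")
  }
  if (!is.character(pattern) || length(pattern) != 1 || !nzchar(pattern)) {
    stop("pattern must be a single non-empty SMARTS string")
  }
  if (is.character(structures)) {
    if (!length(structures)) return(character())
    ids <- names(structures) %||% as.character(seq_along(structures))
    sdfs <- list()
    for (i in seq_along(structures)) {
      s <- tryCatch(ChemmineR::smiles2sdf(structures[i]),
                    error = function(e) NULL)
      if (is.null(s)) {
        warning("skipping unparseable structure for ", ids[i])
        next
      }
      ChemmineR::cid(s) <- ids[i]
      sdfs[[length(sdfs) + 1]] <- s
    }
    if (!length(sdfs)) return(character())
    sdfset <- Reduce(function(a, b) suppressWarnings(c(a, b)), sdfs)
  } else {
    sdfset <- structures
  }
  counts <- ChemmineR::smartsSearchOB(sdfset, pattern, uniqueMatches = FALSE)
  names(counts)[counts > 0]
}

#' Sign-consistent per-compound verdict for a cluster
#'
#' Reduces no-threshold AUC comparisons taken under all three
#' interpolation/extrapolation strategies (and all of a compound's
#' conditions) to a single call: `less_toxic_a` or `less_toxic_b` only when
#' every (strategy, condition) comparison points that way, `no_difference`
#' when all comparisons show equality, and `excluded` otherwise (or when a
#' strategy's comparison was skipped for some condition).
#'
#' @param comparisons data.frame from [compare_all_strategies()] with
#'   `threshold_pct = 0` for one vehicle pair.
#' @return data.frame `compound_id`, `vehicle_a`, `vehicle_b`, `verdict`.
#' @export
cluster_compound_verdicts <- function(comparisons) {
  df <- as.data.frame(comparisons)
  if (!nrow(df)) {
    return(data.frame(compound_id = character(), vehicle_a = character(),
                      vehicle_b = character(), verdict = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(df$threshold_pct != 0)) {
    stop("cluster verdicts require no-threshold (threshold_pct = 0) comparisons")
  }
  missing_strat <- setdiff(auc_strategies(), unique(df$strategy))
  if (length(missing_strat)) {
    stop("comparisons missing strategy coverage: ",
         paste(missing_strat, collapse = ", "))
  }
  out <- lapply(split(df, df$compound_id), function(g) {
    n_cond <- length(unique(.group_id(g, with_vehicle = FALSE)))
    complete <- nrow(g) == 3 * n_cond
    verdict <- if (!complete) "excluded"
      else if (all(g$verdict == "a_less_toxic")) "less_toxic_a"
      else if (all(g$verdict == "b_less_toxic")) "less_toxic_b"
      else if (all(g$verdict == "no_difference")) "no_difference"
      else "excluded"
    data.frame(compound_id = g$compound_id[1], vehicle_a = g$vehicle_a[1],
               vehicle_b = g$vehicle_b[1], verdict = verdict,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Tally cluster verdicts for a vehicle pair
#'
#' @param verdicts data.frame from [cluster_compound_verdicts()] (excluded
#'   compounds do not count).
#' @return one-row data.frame `vehicle_a`, `vehicle_b`, `n_a`, `n_b`,
#'   `n_no_difference`.
#' @export
tally_preferences <- function(verdicts) {
  v <- as.data.frame(verdicts)
  data.frame(vehicle_a = v$vehicle_a[1], vehicle_b = v$vehicle_b[1],
             n_a = sum(v$verdict == "less_toxic_a"),
             n_b = sum(v$verdict == "less_toxic_b"),
             n_no_difference = sum(v$verdict == "no_difference"),
             stringsAsFactors = FALSE)
}

#' Preference-ratio rule for a vehicle-pair tally
#'
#' A cluster shows a difference for a vehicle pair iff the count preferring
#' one vehicle exceeds the count preferring the other plus the count
#' showing no difference. The two directions are mutually exclusive for any
#' non-negative counts.
#'
#' @param n_a,n_b counts of compounds less toxic in vehicle a / b.
#' @param n_no_difference count showing no difference.
#' @return list with `shows_difference` (logical) and `direction`
#'   (`"a"`, `"b"` or `"none"`).
#' @export
preference_shown <- function(n_a, n_b, n_no_difference) {
  if (min(n_a, n_b, n_no_difference) < 0) stop("counts must be non-negative")
  direction <- if (n_a > n_b + n_no_difference) "a"
    else if (n_b > n_a + n_no_difference) "b"
    else "none"
  list(shows_difference = direction != "none", direction = direction)
}

#' Build a vehicle partial-order graph from pair tallies
#'
#' Applies the preference-ratio rule to every tally: a shown difference
#' becomes a strict edge from the less-toxic vehicle to the more-toxic one;
#' a tally with no shown difference becomes an equivalence edge.
#' Consistency findings (directed cycles among strict edges; equivalence
#' paths contradicted by strict paths) are computed immediately.
#' Equivalence is not treated as transitive for ordering claims; it is used
#' only for contradiction detection.
#'
#' @param tallies data.frame with columns `vehicle_a`, `vehicle_b`, `n_a`,
#'   `n_b`, `n_no_difference`, one row per vehicle pair.
#' @return list of class `vehicle_order`: `vehicles`, `strict` (data.frame
#'   `from`, `to`, counts: from = less toxic), `equivalent` (data.frame
#'   `a`, `b`, counts), `tallies`, `findings` (list, empty when fully
#'   consistent).
#' @export
build_order_graph <- function(tallies) {
  t <- as.data.frame(tallies)
  strict <- list()
  equiv <- list()
  if (nrow(t)) {
    for (i in seq_len(nrow(t))) {
      ps <- preference_shown(t$n_a[i], t$n_b[i], t$n_no_difference[i])
      if (ps$direction == "a") {
        strict[[length(strict) + 1]] <- data.frame(
          from = t$vehicle_a[i], to = t$vehicle_b[i],
          n_less_toxic = t$n_a[i], n_more_toxic = t$n_b[i],
          n_no_difference = t$n_no_difference[i], stringsAsFactors = FALSE)
      } else if (ps$direction == "b") {
        strict[[length(strict) + 1]] <- data.frame(
          from = t$vehicle_b[i], to = t$vehicle_a[i],
          n_less_toxic = t$n_b[i], n_more_toxic = t$n_a[i],
          n_no_difference = t$n_no_difference[i], stringsAsFactors = FALSE)
      } else {
        equiv[[length(equiv) + 1]] <- data.frame(
          a = t$vehicle_a[i], b = t$vehicle_b[i],
          n_a = t$n_a[i], n_b = t$n_b[i],
          n_no_difference = t$n_no_difference[i], stringsAsFactors = FALSE)
      }
    }
  }
  strict <- if (length(strict)) do.call(rbind, strict) else
    data.frame(from = character(), to = character(),
               n_less_toxic = integer(), n_more_toxic = integer(),
               n_no_difference = integer(), stringsAsFactors = FALSE)
  equiv <- if (length(equiv)) do.call(rbind, equiv) else
    data.frame(a = character(), b = character(), n_a = integer(),
               n_b = integer(), n_no_difference = integer(),
               stringsAsFactors = FALSE)
  vehicles <- unique(c(t$vehicle_a, t$vehicle_b))
  order <- structure(list(vehicles = vehicles, strict = strict,
                          equivalent = equiv, tallies = t,
                          findings = list()),
                     class = "vehicle_order")
  order$findings <- check_consistency(order)
  order
}

.strict_graph <- function(order) {
  igraph::graph_from_data_frame(order$strict[c("from", "to")],
                                directed = TRUE,
                                vertices = data.frame(name = order$vehicles))
}

#' Consistency findings of a vehicle order
#'
#' Reports (i) directed cycles among the strict less-toxic relations (as
#' strongly connected components of size > 1) and (ii) contradictions where
#' two vehicles joined by a path of equivalence relations also stand in a
#' strict relation.
#'
#' @param order a [build_order_graph()] result.
#' @return list of findings, each a list with `type` (`"cycle"` or
#'   `"contradiction"`) and `vehicles`; empty when fully consistent.
#' @export
check_consistency <- function(order) {
  findings <- list()
  if (!length(order$vehicles)) return(findings)
  g <- .strict_graph(order)
  comp <- igraph::components(g, mode = "strong")
  for (cid in which(comp$csize > 1)) {
    findings[[length(findings) + 1]] <- list(
      type = "cycle",
      vehicles = names(comp$membership)[comp$membership == cid])
  }
  if (nrow(order$equivalent)) {
    ge <- igraph::graph_from_data_frame(
      order$equivalent[c("a", "b")], directed = FALSE,
      vertices = data.frame(name = order$vehicles))
    ecomp <- igraph::components(ge)$membership
    reach <- igraph::distances(g, mode = "out")
    for (cid in unique(ecomp)) {
      members <- names(ecomp)[ecomp == cid]
      if (length(members) < 2) next
      pairs <- utils::combn(members, 2)
      for (j in seq_len(ncol(pairs))) {
        u <- pairs[1, j]; v <- pairs[2, j]
        if (is.finite(reach[u, v]) || is.finite(reach[v, u])) {
          findings[[length(findings) + 1]] <- list(
            type = "contradiction", vehicles = c(u, v))
        }
      }
    }
  }
  findings
}

#' Linear order of vehicles, when one exists
#'
#' Returns the vehicles from least to most toxic when the strict relations
#' totally order them (every pair comparable through strict paths), there
#' are no equivalence relations and no consistency findings; otherwise
#' `NULL`.
#'
#' @param order a [build_order_graph()] result.
#' @return character vector (safest first) or `NULL`.
#' @export
linear_order <- function(order) {
  if (length(order$findings) || nrow(order$equivalent)) return(NULL)
  if (length(order$vehicles) < 2) return(order$vehicles)
  g <- .strict_graph(order)
  reach <- igraph::distances(g, mode = "out")
  for (u in order$vehicles) {
    for (v in order$vehicles) {
      if (u != v && !is.finite(reach[u, v]) && !is.finite(reach[v, u])) {
        return(NULL)
      }
    }
  }
  # rank by number of strictly-more-toxic vehicles reachable from each node
  below <- rowSums(is.finite(reach)) - 1
  order$vehicles[base::order(-below[order$vehicles])]
}

#' Export a vehicle order as a DOT graph
#'
#' Strict relations become directed edges from the less-toxic vehicle to
#' the more-toxic one; equivalence relations become double-headed edges.
#' Edge labels carry the `less toxic : more toxic : no difference` tallies.
#'
#' @param order a [build_order_graph()] result.
#' @param path optional file to write.
#' @return the DOT text, invisibly when writing to a file.
#' @export
order_to_dot <- function(order, path = NULL) {
  q <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')
  lines <- c("digraph vehicle_order {")
  for (v in order$vehicles) lines <- c(lines, paste0("  ", q(v), ";"))
  s <- order$strict
  if (nrow(s)) {
    lines <- c(lines, sprintf('  %s -> %s [label="%d : %d : %d"];',
                              q(s$from), q(s$to), s$n_less_toxic,
                              s$n_more_toxic, s$n_no_difference))
  }
  e <- order$equivalent
  if (nrow(e)) {
    lines <- c(lines, sprintf('  %s -> %s [dir=both, label="%d : %d : %d"];',
                              q(e$a), q(e$b), e$n_a, e$n_b,
                              e$n_no_difference))
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.vehicle_order <- function(x, ...) {
  lin <- linear_order(x)
  cat("vehicle order over {", paste(x$vehicles, collapse = ", "), "}\n")
  if (!is.null(lin)) {
    cat("  linear:", paste(lin, collapse = " > "), "\n")
  } else {
    if (nrow(x$strict)) {
      cat("  strict:", paste(sprintf("%s > %s", x$strict$from, x$strict$to),
                             collapse = ", "), "\n")
    }
    if (nrow(x$equivalent)) {
      cat("  equivalent:",
          paste(sprintf("%s = %s", x$equivalent$a, x$equivalent$b),
                collapse = ", "), "\n")
    }
  }
  if (length(x$findings)) {
    cat("  findings:", length(x$findings), "inconsistency finding(s)\n")
  }
  invisible(x)
}
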