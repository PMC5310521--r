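`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a reproducible sub-seed from a master seed and a stream index.
# Keeps results stable when independent stochastic stages share one seed.
# Values stay below 2^31 - 1 (R integers are 32 bit).
derive_seed <- function(seed, stream) {
  s <- (abs(as.double(seed)) %% 2147483647) * 48271 + as.double(stream) * 16807
  as.integer(s %% 2147483629) + 1L
}

# Evaluate `code` under `set.seed(seed)` without disturbing the caller's
# RNG state. A NULL seed leaves the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  code
}

#' All unordered pairs of vehicles
#'
#' Enumerates the unique unordered pairs among a set of vehicle names, the
#' unit over which pairwise toxicity comparisons are organised (52 vehicles
#' give 1326 pairs).
#'
#' @param vehicles character vector of distinct vehicle names.
#' @return data.frame with columns `vehicle_a`, `vehicle_b`, one row per
#'   unordered pair.
#' @export
vehicle_pairs <- function(vehicles) {
  vehicles <- unique(as.character(vehicles))
  if (length(vehicles) < 2) {
    return(data.frame(vehicle_a = character(), vehicle_b = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- utils::combn(length(vehicles), 2)
  data.frame(vehicle_a = vehicles[idx[1, ]], vehicle_b = vehicles[idx[2, ]],
             stringsAsFactors = FALSE)
}
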