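`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' that seeded package functions never disturb the user's random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# One master seed fans out to named sub-streams (tree, drift, per-species
# noise, ...) so that changing one stage never re-orders the draws of
# another.  The derived seed stays below 2^31 - 1.
seed_stream <- function(seed, stage, index = 0L) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 104729
  as.integer((abs(as.numeric(seed)) %% 2147483629 + 104729 * h + 7919 * index) %% 2147483629) + 1L
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# recycle a per-species parameter (scalar, unnamed vector, or named vector)
# to the full species vector, preserving species order
per_species <- function(x, species, what) {
  n <- length(species)
  if (length(x) == 1L && is.null(names(x))) {
    return(stats::setNames(rep(x, n), species))
  }
  if (!is.null(names(x))) {
    if (!all(species %in% names(x))) {
      stop_invalid("`%s` is named but lacks entries for: %s", what,
                   paste(setdiff(species, names(x)), collapse = ", "))
    }
    return(x[species])
  }
  if (length(x) != n) {
    stop_invalid("`%s` must have length 1 or %d", what, n)
  }
  stats::setNames(x, species)
}
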