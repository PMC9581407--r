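# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
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

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

half_width <- function(w) {
  if (w %% 2L != 1L || w < 3L) stop("window size `w` must be an odd integer >= 3", call. = FALSE)
  (w - 1L) %/% 2L
}

# window centred on (i, j) fits inside [0, n_bins)^2 ?
window_in_bounds <- function(i, j, w, n_bins) {
  hw <- half_width(w)
  i - hw >= 0L & i + hw < n_bins & j - hw >= 0L & j + hw < n_bins
}
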