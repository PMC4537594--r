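# shared small helpers

#' Round half up to integer percent
#'
#' Percentages reported by the integration summaries use round-half-up
#' (2.5 -> 3), not the IEEE round-half-even of [base::round()], so printed
#' fractions like 108/179 -> 60% are stable.
#'
#' @param x Numeric vector of proportions in \[0, 1\].
#' @return Integer percent vector.
#' @export
percent_round <- function(x) {
  as.integer(floor(x * 100 + 0.5))
}

# parts-per-million difference of mz values relative to ref
ppm_diff <- function(mz, ref) {
  1e6 * abs(mz - ref) / ref
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

# local RNG scope: run code with a given seed without disturbing caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}
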