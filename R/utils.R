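# Internal helpers shared across modules.

#' @keywords internal
#' @import stats
#' @importFrom utils modifyList
"_PACKAGE"

## Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
## caller's RNG afterwards. All stochastic functions in the package route
## their seeding through this, so user seeds never clobber the session RNG.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

## Round half away from zero (printed stimulus values are reported this way;
## base round() rounds half to even).
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Column means / sds for a subjects-by-variables matrix without the overhead
## of apply().
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt((colSums(x^2) - n * mu^2) / (n - 1))
}

stop_domain <- function(...) stop(..., call. = FALSE)
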