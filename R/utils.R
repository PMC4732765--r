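#' @importFrom rlang abort warn .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats optimize rnorm runif rpois rgeom rexp cor sd var
#' @importFrom utils head tail
NULL

# Run code with a private RNG stream, restoring the caller's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
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
  }
  force(code)
}

stop_invalid <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "hisatrace_invalid_argument")
}

check_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_invalid("`%s` must be > 0", name)
  if (nonneg && x < 0) stop_invalid("`%s` must be >= 0", name)
  invisible(x)
}
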