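#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package route their
#' randomness through explicit seeds via this helper.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
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
  # pin all three generator kinds: callers may run under contexts that pin
  # the pre-3.6 "Rounding" sample kind, which would silently change every
  # sample() draw inside seeded sections
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

mt_log <- function(..., verbose = getOption("moltitox.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[moltitox] ", ...)
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# polynomial rolling hash of a string, exact in double precision
hash_string <- function(s) {
  h <- 7
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  h
}
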