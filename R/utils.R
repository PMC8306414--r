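#' @keywords internal
"_PACKAGE"

#' @importFrom stats binomial coef glm lm pnorm pchisq qnorm rbinom rnorm
#'   runif sd setNames var
#' @importFrom utils read.table write.table
NULL

# Run code under a temporary RNG state so callers' streams are untouched.
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
    set.seed(seed)
  }
  force(code)
}

# Derive a stage seed from a root seed by a fixed offset, kept within the
# 32-bit integer range R requires of set.seed().
derive_seed <- function(root_seed, offset) {
  as.integer((as.numeric(root_seed) * 1000003 + offset) %% 2147483647L)
}

stop_abokit <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
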