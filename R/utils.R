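#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm pnorm qnorm pchisq pt rbinom rnorm runif optim
#'   optimize setNames complete.cases sd var cor quantile
#' @importFrom utils read.delim write.table head
NULL

# Seed the RNG for the calling operation and restore the previous state when
# the caller exits. All stochastic operations route their seed through this.
local_rng <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  withr::defer({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, envir = env)
  invisible(NULL)
}

# "chr1", "Chr1", "1" -> "1"; chromosome ids are compared as strings.
normalize_chrom <- function(x) sub("^[Cc][Hh][Rr]", "", as.character(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
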