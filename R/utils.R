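#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cor.test qchisq rnorm runif rpois rlnorm rmultinom
#'   t.test kmeans cmdscale cov sd setNames rgamma
#' @importFrom utils read.table write.table head
NULL

stop_usage <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# local RNG scope: run code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
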