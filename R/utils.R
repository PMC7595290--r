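#' @keywords internal
"_PACKAGE"

#' @useDynLib nerkascan, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import data.table
#' @importFrom stats cor kmeans median pchisq qchisq rbeta rbinom rpois runif
#'   sd var quantile complete.cases glm.fit binomial
#' @importFrom utils write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Median of the chi-square distribution with 1 df; divisor of the genomic
# inflation factor lambda = median(chi2) / CHI2_1_MEDIAN.
CHI2_1_MEDIAN <- 0.4549364

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (e.g. k-means
#' restarts) do not perturb the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
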