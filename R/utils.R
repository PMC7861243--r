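#' @useDynLib ontopop, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor.test rnorm rpois rnbinom runif wilcox.test
#' @importFrom utils head read.table write.table packageVersion
NULL

# Named condition constructor: every validation failure carries a distinct
# condition class ("ontopop_error_<name>") so callers can test for it.
stop_onto <- function(name, msg, call = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("ontopop_error_", name), "ontopop_error",
              "error", "condition"),
    list(message = msg, call = call)
  )
  stop(cond)
}

# Evaluate `code` with the global RNG set to `seed`, restoring the previous
# RNG state afterwards.  All randomised operations in the package route
# through this so that library calls never perturb a caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_onto("bad_seed", "rng seed must be a single non-missing number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() that never does the surprise "sample.int" expansion on length-1 x
sample_ids <- function(x, k) x[sample.int(length(x), k)]
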