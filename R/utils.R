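#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator set to `seed`, then
#' restores the previous RNG state so callers' random streams are unaffected.
#' With `seed = NULL` the code runs against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # initialise the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == trunc(x)
}

.stop_with_class <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ecscore_error")))
}

#' @noRd
.lesion_types <- c("he", "ma", "se", "ex")
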