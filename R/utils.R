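#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded generators do not
#' perturb the global stream. A `NULL` seed evaluates the expression under
#' the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("assistbci_config_error", "error")))
}

stop_parse <- function(...) {
  stop(errorCondition(paste0(...), class = c("assistbci_parse_error", "error")))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop_config(name, " must be a finite scalar in [", lower, ", ", upper, "]")
  }
  invisible(x)
}
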