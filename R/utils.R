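#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generators do
#' not perturb unrelated random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Derive a component-specific seed from a master seed
#'
#' Each stochastic component (layout, sequence, counts, qPCR, ...) draws from
#' its own stream so changing one knob does not reshuffle unrelated outputs.
#'
#' @param seed master integer seed.
#' @param component character tag naming the stream.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")
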