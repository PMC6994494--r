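#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm rnorm runif rpois rbinom quantile var aov t.test
#'   wilcox.test kruskal.test TukeyHSD p.adjust pchisq coef resid nls sd
#'   setNames complete.cases
#' @importFrom utils write.csv read.csv head tail
NULL

# Signal a structured error with a machine-readable condition class.
nb_stop <- function(code, msg) {
  cnd <- structure(
    class = c(code, "nbdyn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cnd)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Fold a coordinate into [0, limit] by specular reflection (vectorized).
reflect_into <- function(x, limit) {
  period <- 2 * limit
  x <- x %% period
  ifelse(x > limit, period - x, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
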