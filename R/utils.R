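# Internal helpers: classed error conditions, scoped RNG, numeric utilities.

.msErr <- function(type, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(paste0("methylscreen_", type, "_error"),
                                "methylscreen_error", "error", "condition")))
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# clamp away from {0,1} so the logit is finite
.clamp01 <- function(x, eps = 1e-6) pmin(pmax(x, eps), 1 - eps)

.isCount <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

.stages <- c("adenoma", "I", "II", "III")
.stageLevels <- c(.stages, "none")
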