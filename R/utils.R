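# Internal helpers shared across modules.

#' Derive a reproducible substream seed for a named generator component
#'
#' A single user-facing seed is expanded into per-component substreams by a
#' counter-based scheme: each component name maps to a fixed counter so that
#' adding a new generator never perturbs the draws of existing ones.
#'
#' @param seed integer master seed.
#' @param component character scalar naming the component.
#' @return an integer seed, strictly below 2^31.
#' @keywords internal
substream_seed <- function(seed, component) {
  stopifnot(is.character(component), length(component) == 1L)
  # small deterministic hash of the component name
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component))) %% 100003L
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_config(field, sprintf("must be a single integer >= %d", min))
  invisible(as.integer(x))
}

check_positive <- function(x, field) {
  if (length(x) != 1L || is.na(x) || x <= 0)
    stop_config(field, "must be a single positive number")
  invisible(as.numeric(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
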