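# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#' @noRd
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# a cheap deterministic sub-seed: keeps derived seeds inside 32-bit range
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(offset) %% 104729L
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# one canonical list of feature types; order matters for reporting
feature_types <- function() {
  c("demographics", "initial_dx", "labs", "prescriptions",
    "chart_events", "final_dx", "procedures")
}

# feature types that carry ontology annotations
annotated_feature_types <- function() {
  c("initial_dx", "labs", "prescriptions", "final_dx", "procedures")
}
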