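#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_eesnet <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "eesnet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

check_numeric_vector <- function(x, n = NULL, what = "vector",
                                 allow_na = FALSE) {
  if (!is.numeric(x)) {
    abort_eesnet(sprintf("%s must be numeric", what), "eesnet_shape_error")
  }
  if (!is.null(n) && length(x) != n) {
    abort_eesnet(
      sprintf("%s must have length %d (got %d)", what, n, length(x)),
      "eesnet_shape_error"
    )
  }
  if (!allow_na && anyNA(x)) {
    abort_eesnet(sprintf("%s contains NA/NaN", what), "eesnet_domain_error")
  }
  invisible(x)
}

# Run `expr` under a locally-seeded RNG without touching the caller's
# random state.  All stochastic entry points funnel through this.
with_local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))

format_num <- function(x) formatC(x, digits = 15, format = "g")

FORMAT_VERSION <- "1.0"

check_format_version <- function(version, what) {
  if (is.null(version)) {
    abort_eesnet(sprintf("%s has no format_version field", what),
                 "eesnet_format_error")
  }
  major <- strsplit(as.character(version), ".", fixed = TRUE)[[1]][1]
  if (!identical(major, strsplit(FORMAT_VERSION, ".", fixed = TRUE)[[1]][1])) {
    abort_eesnet(
      sprintf("%s format version %s not supported (reader is %s)",
              what, version, FORMAT_VERSION),
      "eesnet_format_error"
    )
  }
  invisible(TRUE)
}
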