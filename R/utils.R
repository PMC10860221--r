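#' @importFrom rlang .data %||%
#' @importFrom stats pchisq pnorm p.adjust setNames confint rpois rnorm
#'   rlnorm rbinom runif sd quantile as.formula logLik anova coef vcov
#' @importFrom utils packageVersion
NULL

#' Format a count ratio as a percentage
#'
#' All percentages reported by the pipeline (excluded-gene fractions,
#' HTGC frequencies, retention rates, functional-class shares) are the
#' plain ratio `100 * numerator / denominator` rounded half-up to a fixed
#' number of decimal places, so run summaries can be compared digit for
#' digit across runs.
#'
#' @param numerator,denominator Nonnegative counts; `denominator > 0`.
#' @param digits Decimal places to keep (default 1; quality-control
#'   fractions in run summaries use 2).
#' @return A numeric percentage in `[0, 100]`.
#' @examples
#' pct_of(248, 289) # 85.8
#' @export
pct_of <- function(numerator, denominator, digits = 1) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) {
    stop("pct_of(): denominator must be positive", call. = FALSE)
  }
  round2(100 * numerator / denominator, digits)
}

# round half away from zero, as printed statistics conventionally are
# (base round() is banker's rounding)
round2 <- function(x, digits = 0) {
  s <- sign(x)
  z <- abs(x) * 10^digits
  s * floor(z + 0.5 + 1e-9) / 10^digits
}

#' Hash a configuration object
#'
#' Stable md5 of the canonical JSON serialization; stamped into every
#' result table so outputs are traceable to the exact configuration.
#'
#' @param x Any serializable R object.
#' @return A 32-character hex string.
#' @export
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           force = TRUE)
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

# collect many validation failures and raise them together
abort_many <- function(errors, what) {
  if (length(errors) == 0) return(invisible(NULL))
  stop(sprintf("%s validation failed:\n%s", what,
               paste0("  - ", errors, collapse = "\n")), call. = FALSE)
}

# derive a substream seed from a master seed; keeps independent RNG
# streams per generated table so adding one never perturbs the others
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (as.integer(seed) %% 1000000L) * 1009L + stream_index(stream)
}

stream_index <- function(stream) {
  streams <- c(taxonomy = 1L, community = 2L, engraftment = 3L,
               transfer = 4L, background = 5L, retention = 6L,
               abundance = 7L, waafle = 8L, decoys = 9L, cog = 10L,
               quality = 11L)
  idx <- streams[[stream]]
  if (is.null(idx)) stop("unknown RNG stream: ", stream, call. = FALSE)
  idx
}

# evaluate code under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(substream_seed(seed, stream))
  force(code)
}
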