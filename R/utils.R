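#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Derive a reproducible child seed from a parent seed and a stage name
#'
#' One global seed is fanned out to every pipeline stage through a named
#' substream scheme, so that stages are individually reproducible and two
#' stages never share a random stream by accident. The result always lies in
#' `[1, 2^31 - 2]` and is therefore a valid argument to [set.seed()].
#'
#' @param seed integer parent seed.
#' @param name character stage label (e.g. `"generate_source"`).
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, "generate_source")
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  s <- (as.double(seed) * 48271 + h) %% 2147483646
  as.integer(s) + 1L
}

stop_field <- function(cond, field, msg) {
  if (!cond) stop(sprintf("invalid profile field '%s': %s", field, msg), call. = FALSE)
}

# last value per group key, respecting input row order for ties
is_last_in_group <- function(key) !duplicated(key, fromLast = TRUE)
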