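#' @keywords internal
"_PACKAGE"

## formatted stop/warning helpers
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive an independent sub-stream seed from a master seed
#'
#' All randomness in the scene generator flows from a single master seed;
#' independent components (sky texture, clutter, wind jitter, per-frame
#' draws) hash the master seed together with a stream label and the frame
#' index so that each sub-stream is reproducible on its own.
#'
#' @param seed integer master seed.
#' @param key character stream label.
#' @param index optional integer (e.g. frame index) mixed into the hash.
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, key, index = 0L) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(key)) h <- (h * 131 + code) %% 2147483647
  h <- (h * 131 + (as.double(index) %% 1000003)) %% 2147483647
  as.integer(h)
}

## evaluate expr with a local RNG state (restores caller's state afterwards)
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## check scalar numeric
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_prob <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1) stopf("'%s' must be a probability in [0,1]", name)
  invisible(x)
}
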