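# internal helpers: classed errors, seed substreams, numeric utilities

ss_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "socialsampler_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

ss_check <- function(ok, class, msg) {
  if (!isTRUE(ok)) ss_error(class, msg, call = sys.call(-2))
  invisible(TRUE)
}

#' Derive a reproducible substream seed
#'
#' Maps a root seed plus a key (any vector, coerced to character) to a
#' deterministic 31-bit integer seed via a multiplicative string hash. Used so
#' that every network, trial and command draws from its own named substream of
#' the single root seed.
#'
#' @param seed root integer seed.
#' @param key vector naming the substream, e.g. `c("network", 2, "trial", 1)`.
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
#' @examples
#' substream_seed(1, c("network", 1)) != substream_seed(1, c("network", 2))
substream_seed <- function(seed, key) {
  ss_check(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
           "config_error", "seed must be a single finite number")
  h <- (abs(as.double(seed)) %% 2147483646) + 1
  for (ch in utf8ToInt(paste(as.character(key), collapse = "/"))) {
    h <- (h * 69069 + ch) %% 2147483647
  }
  as.integer((h %% 2147483645) + 1)
}

# x * log(y) with the 0 * log(0) = 0 convention, vectorized
xlogy <- function(x, y) {
  out <- x * log(y)
  out[x == 0] <- 0
  out
}

is_binary <- function(x) all(x %in% c(0L, 1L))

`%||%` <- function(a, b) if (is.null(a)) b else a
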