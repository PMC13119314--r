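# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Derive a deterministic substream seed from a master seed and a stream name
#'
#' Every simulator draws its random numbers from a named substream of a single
#' master seed, so adding a new generator never perturbs the output of an
#' existing one. The mapping is a simple 31-bit polynomial hash of the stream
#' name folded into the master seed.
#'
#' @param seed Master seed (integer).
#' @param name Substream name (character scalar).
#' @return An integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  m <- 2147480009  # largest prime below 2^31 we fold into
  s <- as.double(seed %% m)
  for (code in utf8ToInt(name)) {
    s <- (s * 131 + code) %% m
  }
  as.integer(s %% (m - 1L) + 1L)
}

# Run code under a fixed seed without disturbing the caller's RNG state.
with_stream <- function(seed, name, code) {
  withr::with_seed(substream_seed(seed, name), code)
}

# stop() with sprintf formatting and no call in the message
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

reverse_complement <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# sample() that never triggers the length-1 surprise
sample_int <- function(n, size, replace = FALSE, prob = NULL) {
  sample.int(n, size = size, replace = replace, prob = prob)
}
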