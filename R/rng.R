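#' Derive a reproducible substream seed
#'
#' Hashes a master seed together with arbitrary labels (factor values,
#' replicate numbers, tick indices, ...) into a 31-bit integer seed, so each
#' named unit of work draws from its own reproducible stream regardless of
#' what else is run. Pure arithmetic (multiplicative string hash modulo the
#' Mersenne prime 2^31 - 1), identical across platforms.
#'
#' @param master Master seed (single integer).
#' @param ... Labels identifying the substream; coerced to character and
#'   concatenated with separators.
#' @return A single integer in \[0, 2^31 - 2\] suitable for [set.seed()].
#' @examples
#' derive_seed(1, "cell", 50, 3, "rep", 7)
#' @export
derive_seed <- function(master, ...) {
  if (!is.numeric(master) || length(master) != 1L || is.na(master))
    stop("configuration error: `master` seed must be a single integer",
         call. = FALSE)
  m <- 2147483647
  label <- paste(vapply(list(...), function(x)
    paste(as.character(x), collapse = "-"), character(1L)), collapse = "|")
  h <- (abs(as.numeric(master)) %% m) + 11
  for (code in utf8ToInt(label)) h <- (h * 31 + code) %% m
  # one extra mixing round so short labels do not map near the master
  h <- (h * 48271) %% m
  as.integer(h)
}
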