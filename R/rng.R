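#' Portable deterministic random number stream
#'
#' A minimal-standard multiplicative congruential generator
#' (Park-Miller, multiplier 16807, modulus 2^31 - 1). All fixture
#' generators in this package draw from this stream rather than R's
#' global generator, so that identical seeds yield byte-identical
#' fixtures on every platform: every intermediate product stays below
#' 2^53 and is therefore exact in double arithmetic.
#'
#' @param seed A non-negative integer seed.
#' @return A list of closures sharing one hidden state:
#'   \describe{
#'     \item{runif(n)}{`n` uniforms in (0, 1).}
#'     \item{rint(n, max)}{`n` integers uniform on `1..max`.}
#'     \item{sample(x, k)}{`k` elements of vector `x` drawn without
#'       replacement (Fisher-Yates).}
#'   }
#' @examples
#' r <- portable_rng(42)
#' r$runif(3)
#' r$rint(5, 10)
#' @export
portable_rng <- function(seed) {
  if (!is_count(seed)) abort_usage("seed must be a non-negative integer")
  m <- 2147483647
  state <- (as.numeric(seed) %% (m - 1)) + 1

  nxt <- function() {
    state <<- (16807 * state) %% m
    state
  }

  runif <- function(n = 1L) {
    vapply(seq_len(n), function(i) nxt() / m, numeric(1))
  }

  rint <- function(n, max) {
    if (max < 1) abort_usage("rint() needs max >= 1")
    vapply(seq_len(n), function(i) floor(nxt() / m * max) + 1, numeric(1))
  }

  sample <- function(x, k) {
    n <- length(x)
    if (k > n) abort_usage("cannot sample %d items from %d", k, n)
    for (i in seq_len(k)) {
      j <- i + floor(nxt() / m * (n - i + 1))
      tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
    }
    x[seq_len(k)]
  }

  list(runif = runif, rint = rint, sample = sample)
}
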