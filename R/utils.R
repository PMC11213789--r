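# Internal helpers: structured conditions, seeded evaluation, RNG streams,
# deterministic seed splitting.

abort_iq <- function(class, message, ...) {
  stop(structure(
    class = c(class, "iqrank_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

validation_error <- function(message, ...) abort_iq("iqrank_validation_error", message, ...)
protocol_error <- function(message, ...) abort_iq("iqrank_protocol_error", message, ...)
state_error <- function(message, ...) abort_iq("iqrank_state_error", message, ...)
alignment_error <- function(message, ...) abort_iq("iqrank_alignment_error", message, ...)
composition_error <- function(message, ...) abort_iq("iqrank_composition_error", message, ...)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed` and
#' restores the caller's RNG state afterwards, so seeded operations are pure
#' functions of their inputs and never disturb the session RNG.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

#' Create a resumable random-number stream
#'
#' A stream carries its own Mersenne-Twister state, advanced only by draws
#' made through [stream_eval()]. Two streams built from the same seed yield
#' identical draw sequences regardless of what happens to the session RNG,
#' which is how simulated observers stay reproducible.
#'
#' @param seed Integer seed.
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- with_seed(seed, get(".Random.seed", envir = globalenv()))
  class(e) <- "rng_stream"
  e
}

#' Draw from an RNG stream
#'
#' Evaluates `code` (typically `rnorm()`, `runif()`, `sample()` calls) using
#' the stream's private RNG state and stores the advanced state back in the
#' stream. The caller's RNG is untouched.
#'
#' @param stream An [rng_stream()].
#' @param code Expression performing random draws.
#' @return The value of `code`.
#' @export
stream_eval <- function(stream, code) {
  if (!inherits(stream, "rng_stream")) {
    validation_error("`stream` must be an rng_stream object")
  }
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  assign(".Random.seed", stream$state, envir = genv)
  on.exit({
    stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (is.null(old)) {
      rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  code
}

# Deterministic seed splitting: the i-th child seed of `master` is the i-th
# draw (without replacement) from 1..2^31-2 under `master`. Documented
# scheme; used everywhere a compound operation needs independent sub-seeds.
child_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max - 1L, n))
}

# Small integer hash used for per-comparison presentation-side flips.
# Operands are kept below 2^26 so double arithmetic stays exact.
mix_bits <- function(seed, k) {
  x <- (as.numeric(seed) %% 67108864) + 2971 * (as.numeric(k) %% 67108864)
  x <- (x * 2654435761) %% 2147483648
  x <- (x %/% 65536) + (x %% 65536) * 32768
  x %% 2147483648
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    validation_error(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
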