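# Deterministic stream splitting.
#
# Every randomized operation in the package takes an integer `seed` and is a
# pure function of (inputs, seed). Independent substreams for e.g. each
# (perturbation level, replicate) cell are derived with `substream_seed()`,
# so results do not depend on execution order or worker count.

#' Derive a substream seed
#'
#' Deterministically maps a base seed plus an index tuple to a new 31-bit
#' seed via a multiplicative congruential mix (Lehmer constants, modulus
#' 2^31 - 1). Used internally to give each (level, replicate, method) cell
#' its own independent RNG stream, which makes all stochastic results
#' invariant to scheduling and worker count.
#'
#' @param seed Integer base seed.
#' @param ... Integer indices identifying the substream (e.g. level index,
#'   replicate index).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, 3, 7)
substream_seed <- function(seed, ...) {
  idx <- as.double(unlist(list(...), use.names = FALSE))
  stopifnot(length(seed) == 1L, is.finite(seed))
  p <- 2147483647
  h <- (as.double(seed) %% p)
  for (v in c(length(idx), idx)) {
    h <- (h * 48271 + (v %% p) + 11) %% p
  }
  as.integer(h)
}

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit hash of a string (used to tie detection substreams to the
# method specification so identical specs reproduce identical streams).
string_seed <- function(x) {
  p <- 2147483647
  h <- 7
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% p
  as.integer(h)
}
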