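#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages of the pipeline draw their randomness from seeds
#' derived deterministically from one master seed, so that changing the seed
#' of one stage (e.g. the imaging simulator) never perturbs another stage.
#'
#' @param seed master seed (integer).
#' @param tag character tag naming the consumer stage.
#' @return an integer seed in [0, 2^31).
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}

## internal: stop with a consistent prefix
.fail <- function(...) stop(sprintf(...), call. = FALSE)

.assert <- function(cond, ...) if (!isTRUE(cond)) .fail(...)

## Pearson r on logs with a zero floor (half minimum nonzero), flagging floored
## entries; shared by composition comparisons.
.log_with_floor <- function(x) {
  x <- as.numeric(x)
  floored <- x <= 0
  if (any(floored)) {
    nz <- x[x > 0]
    if (!length(nz)) .fail("all fractions are zero; nothing to log-transform")
    x[floored] <- min(nz) / 2
  }
  list(log = log(x), floored = floored)
}

## median absolute deviation with the 1.4826 consistency constant
.mad <- function(x) stats::mad(x, constant = 1.4826)
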