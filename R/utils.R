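# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards. All stochastic operations route through this so
# one integer seed makes every generator reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a substream seed from a master seed
#'
#' Deterministically maps a master seed and a stream index to a new 32-bit
#' seed, so that each stochastic stage of a pipeline run draws from its own
#' reproducible substream.
#'
#' @param seed Integer master seed.
#' @param stream Integer stream index (>= 0).
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, 0)
#' derive_seed(1, 1)
derive_seed <- function(seed, stream = 0L) {
  stopifnot(is.numeric(seed), is.numeric(stream), stream >= 0)
  # Weyl-style mixing; constants are odd so consecutive streams decorrelate.
  m <- 2^31 - 1
  s <- (as.double(seed) %% m)
  as.integer((s * 2654435761 + as.double(stream) * 40503 + 12345) %% m)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
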