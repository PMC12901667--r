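#' @keywords internal
#' @useDynLib microdisp, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Ordered zone labels along the dispersal axis; Control is the isolated patch.
.zone_levels <- c("Start", "Corridor", "Target", "Control")

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Mixes a master integer seed with one or more string or integer tags into a
#' new seed, so that independent stages (plates, replicates, bursts) of a
#' pipeline consume independent, reproducible random streams.
#'
#' @param seed master integer seed.
#' @param ... tags (strings or integers) naming the sub-stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "plate", 3)
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483629 # prime below 2^31
  h <- as.double(seed %% m)
  for (tag in list(...)) {
    bytes <- if (is.character(tag)) utf8ToInt(tag) else as.integer(tag)
    for (b in bytes) h <- (h * 48271 + as.double(b) + 11) %% m
  }
  as.integer(h)
}

## Run `expr` under a temporary RNG state seeded with `seed`; restores the
## caller's RNG state afterwards so library code does not disturb user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
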