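#' Derive child seeds from a master seed
#'
#' Every stochastic routine in boutlaw takes a single integer seed and, when
#' it needs several independent random tasks (sweep cells, bootstrap
#' iterations, reference samples), expands it into child seeds with this
#' splitting scheme: the master seed initialises R's default RNG and `n`
#' child seeds are drawn as integers in `[1, 2^31 - 2]` without replacement.
#' The scheme is deterministic, so any cell or iteration of a large run can
#' be reproduced in isolation from its recorded child seed.
#'
#' @param seed integer master seed.
#' @param n number of child seeds to derive.
#' @return integer vector of `n` child seeds, each in `[1, 2147483646]`.
#' @export
#' @examples
#' derive_seeds(42, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), length(n) == 1L, n >= 0)
  if (n == 0) return(integer(0))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(2147483646L, as.integer(n), replace = FALSE)
}

# Snapshot/restore of .Random.seed so seed-splitting does not disturb the
# caller's RNG stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Set the RNG for a task if a seed is supplied; NULL means "continue the
# current stream".
set_task_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
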