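# Reproducible, order-independent random streams.
#
# Every unit of work (a cell type, a spatial barcode, a simulation stage) gets
# its own seed derived by hashing (base seed, unit identifier). Results are
# therefore independent of the order in which units are processed, and adding
# a unit never perturbs the others.

#' Derive a reproducible seed for a named unit of work
#'
#' Hashes a base seed together with a string identifier (FNV-1a, scrambled
#' through splitmix64) into a non-negative integer below 2^31, suitable for
#' [set.seed()] or for the internal classifier RNG.
#'
#' @param seed Base seed (integer-valued scalar).
#' @param id Character scalar naming the unit of work.
#' @return A double holding a non-negative integer < 2^31.
#' @export
#' @examples
#' derive_seed(1, "barcode-0001")
derive_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(id),
            length(id) == 1L)
  .derive_seed_cpp(as.double(seed), id)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
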