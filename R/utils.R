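## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do not
#' disturb the caller's RNG stream.
#' @noRd
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Keeps derived seeds inside 32-bit integer range so they remain valid
#' arguments to `set.seed()`.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483587L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(x, y) if (is.null(x)) y else x

## Checked matrix coercion: numeric matrix with row/col names required by the
## SOM and metaclustering layers.
as_data_matrix <- function(x, what = "matrix") {
  m <- as.matrix(x)
  if (!is.numeric(m)) stopf("%s must be numeric", what)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  m
}
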