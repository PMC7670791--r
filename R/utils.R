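# internal helpers shared across modules

#' @keywords internal
#' @noRd
with_seed <- function(seed, fn) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fn()
}

# deterministic per-item substream seed, kept inside 32-bit integer range
#' @noRd
substream_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
                as.double(index) * 9973 + 1) %% 2147483647)
}

# Shannon entropy of a count (or probability) vector, in bits; 0*log0 = 0
#' @noRd
entropy_bits <- function(counts) {
  s <- sum(counts)
  if (s <= 0) return(0)
  p <- counts / s
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
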