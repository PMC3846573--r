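# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed percentages in DGE
#' reports use conventional half-up rounding (93.435 -> 93.44).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values that are exactly .5 after
  # decimal representation error still round up
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage with half-up rounding to two decimals
#' @param num numerator
#' @param den denominator (> 0)
#' @return percentage in [0, 100], rounded half-up to 2 dp
#' @keywords internal
pct2 <- function(num, den) {
  if (any(den <= 0)) stop("percentage undefined: zero or negative denominator")
  round_half_up(num / den * 100, 2)
}

#' Evaluate an expression under a fixed RNG seed, restoring RNG state
#' @param seed integer seed
#' @param expr expression
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# derive a stream-specific 31-bit sub-seed from a master seed
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce a DNAStringSet (or similar) to character, preserving names;
# base as.character() would strip names from a character input
as_named_seqs <- function(x) {
  if (is.character(x)) return(x)
  as.character(x) # Biostrings method keeps names
}

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != floor(x))
    stop(sprintf("'%s' must be a single non-negative integer", name))
}
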