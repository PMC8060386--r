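#' Discretize a VOI to 256 gray levels
#'
#' Fixed-bin-count quantization over the VOI's own intensity range:
#' `level = floor((x - min) / (max - min) * 256)`, with the maximum mapped
#' to level 255. A constant VOI (max == min) maps entirely to level 0.
#' The result has bin width 1; coarser quantizations are produced from it
#' with [rebin()].
#'
#' @param voi a [Voi-class].
#' @return A [QuantizedVoi-class] with 256 levels and bin width 1.
#' @export
discretize <- function(voi) {
  x <- voi@intensities
  if (!length(x)) stopf("cannot discretize an empty VOI")
  rng <- max(x) - min(x)
  if (rng == 0) {
    lev <- integer(length(x))
  } else {
    lev <- as.integer(floor((x - min(x)) / rng * N_GRAY_LEVELS))
    lev[lev == N_GRAY_LEVELS] <- N_GRAY_LEVELS - 1L
  }
  new("QuantizedVoi", voi, levels = lev, nLevels = N_GRAY_LEVELS,
      binWidth = 1L)
}

#' Rebin a 256-level quantization to a coarser bin width
#'
#' Merges adjacent gray levels by floor division: `new level = old level %/% W`,
#' giving `ceiling(256 / W)` levels. `W = 1` is the identity.
#'
#' @param q a [QuantizedVoi-class] at bin width 1.
#' @param W bin width, one of 1, 2, 8, 16, 32, 64, 128.
#' @return A [QuantizedVoi-class] at bin width `W`.
#' @export
rebin <- function(q, W) {
  if (!(length(W) == 1L && W %in% ALLOWED_BIN_WIDTHS))
    stopf("bin width must be one of {%s}",
          paste(ALLOWED_BIN_WIDTHS, collapse = ","))
  if (q@binWidth != 1L)
    stopf("rebin expects a bin-width-1 quantization, got width %d", q@binWidth)
  W <- as.integer(W)
  if (W == 1L) return(q)
  new("QuantizedVoi", as(q, "Voi"), levels = q@levels %/% W,
      nLevels = as.integer(ceiling(N_GRAY_LEVELS / W)), binWidth = W)
}
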