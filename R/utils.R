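#' @importFrom stats cor kmeans median pt quantile rnorm runif sd setNames
#'   t.test var
#' @importFrom utils read.delim write.table packageVersion
NULL

# Polynomial string hash modulo the Mersenne prime 2^31 - 1; used for config
# hashes in manifests and for deriving per-subject simulation seeds.
# Arithmetic in double stays exact (products < 2^53).
strHash <- function(s) {
  h <- 0
  for (b in as.integer(charToRaw(enc2utf8(s))))
    h <- (h * 131 + b) %% 2147483647
  h
}

configHash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "")
  sprintf("%08x", strHash(s))
}

petLog <- function(stage, msg, ..., verbose = TRUE) {
  if (verbose)
    message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
  invisible(NULL)
}

# entropy helper with the 0 * log(0) := 0 convention, base 2
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
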