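#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif rpois rbinom rexp quantile sd var median
#'   aov kruskal.test shapiro.test bartlett.test t.test pt spline approx
#'   p.adjust complete.cases
#' @importFrom utils head tail read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal of a real vector, from which the
#' instantaneous phase (`Arg`) and amplitude envelope (`Mod`) are read off.
#' Standard construction: zero the negative frequencies of the DFT and double
#' the positive ones.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) stopf("analytic_signal needs at least 2 samples")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# indices of strict local maxima; plateau centres count once
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  # treat flat steps by carrying the previous sign
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1L) s[i] <- s[i - 1L]
  which(diff(s) < 0) + 1L
}

# derive a child seed from a base seed and stream index, staying below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435761) %% 2147483647) + 1L
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# positive-part truncation of normal draws (redraw-free clamp at a floor)
rnorm_trunc <- function(n, mean, sd, lower) {
  pmax(rnorm(n, mean, sd), lower)
}

# centred rolling mean via cumsum, edges shrink to the available window
roll_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
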