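#' @keywords internal
"_PACKAGE"

## Gaussian FWHM <-> sigma; 2*sqrt(2*log(2)) = 2.3548
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

`%||%` <- function(a, b) if (is.null(a)) b else a

## rotate a 2D vector by +90 degrees (x right, y down image convention)
perp2 <- function(v) c(-v[2], v[1])

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector cannot be normalized")
  v / n
}

## centered moving mean, window k (odd), shrinking at the edges so the
## first/last values average over the available samples only
rolling_mean <- function(x, k) {
  stopifnot(k >= 1, k %% 2 == 1)
  if (k == 1) return(x)
  n <- length(x)
  h <- (k - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

## sample SEM (sd / sqrt(n)); NA for n < 2
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Significance stars as used in figure legends
#'
#' Maps p-values to the conventional annotation: `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
signif_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
    ifelse(p < 0.001, "***",
      ifelse(p < 0.01, "**",
        ifelse(p < 0.05, "*", "ns"))))
}
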