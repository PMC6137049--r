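#' Speech rate in words per second
#'
#' Word count divided by duration, rounded half-up to two decimals (the
#' convention used for descriptive stimulus statistics).
#'
#' @param word_count number of words (>= 0).
#' @param duration duration in seconds (> 0).
#' @return words per second, rounded to 2 decimals.
#' @examples
#' speech_rate(1384, 486)  # 2.85
#' speech_rate(1810, 481)  # 3.76
#' @export
speech_rate <- function(word_count, duration) {
  if (any(duration <= 0)) stop("duration must be positive", call. = FALSE)
  floor(word_count / duration * 100 + 0.5) / 100
}

#' Vowel-space triangle area
#'
#' Shoelace area of the triangle spanned by the three corner vowels
#' /i/, /u/ and /a/ in (F1, F2) formant space, in Hz^2. Larger areas
#' indicate hyperarticulated vowels, as in infant-directed speech.
#' Degenerate (collinear) points give area 0.
#'
#' @param corner_vowels 3 x 2 numeric matrix (rows = vowels, columns =
#'   F1, F2 in Hz), or a list of three (F1, F2) pairs.
#' @return area in Hz^2.
#' @examples
#' vowel_triangle_area(rbind(c(0, 0), c(2, 0), c(0, 2)))  # 2
#' @export
vowel_triangle_area <- function(corner_vowels) {
  m <- if (is.list(corner_vowels)) do.call(rbind, corner_vowels)
       else as.matrix(corner_vowels)
  stopifnot(nrow(m) == 3, ncol(m) == 2)
  x <- m[, 1]; y <- m[, 2]
  abs(x[1] * (y[2] - y[3]) + x[2] * (y[3] - y[1]) +
        x[3] * (y[1] - y[2])) / 2
}
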