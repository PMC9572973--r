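#' Convert an RGB colour to a hue angle
#'
#' Computes the hue angle of an RGB triple as the two-argument arctangent of
#' \eqn{\sqrt{3}(G - B)} over \eqn{2R - G - B}, expressed in degrees with 360
#' added when negative, so the result lies in \[0, 360). This is the standard
#' hexagonal hue projection: pure red maps to 0 deg, pure green to 120 deg and
#' pure blue to 240 deg. Saturation and lightness are deliberately discarded;
#' the hue alone is the colour descriptor used for band comparison.
#'
#' Achromatic colours (R = G = B) have no defined hue. Returning 0 would
#' silently match red-hued standards, so these raise an error of class
#' `hptlc_achromatic_error` instead.
#'
#' @param red,green,blue Integer channel values in \[0, 255].
#' @return Hue angle in degrees, a numeric scalar in \[0, 360).
#' @examples
#' rgb_to_hue(255, 0, 0) # 0
#' rgb_to_hue(0, 255, 0) # 120
#' @export
rgb_to_hue <- function(red, green, blue) {
  for (ch in list(red, green, blue)) {
    if (!is.numeric(ch) || length(ch) != 1L || is.na(ch) || ch < 0 || ch > 255) {
      stop("RGB channels must be single values in [0, 255]", call. = FALSE)
    }
  }
  if (red == green && green == blue) {
    stop(structure(
      class = c("hptlc_achromatic_error", "error", "condition"),
      list(message = "hue undefined for grey (R = G = B)", call = sys.call(-1))
    ))
  }
  h <- 180 / pi * atan2(sqrt(3) * (green - blue), 2 * red - green - blue)
  if (h < 0) h <- h + 360
  h %% 360
}

#' The twelve colour families tiling the hue circle
#'
#' Twelve contiguous 30-degree bins partition \[0, 360): Red starts at 0,
#' Orange at 30, and so on through Scarlet at 330. Bins are half-open
#' \[lower, lower + 30), so e.g. 29.995 is still Red.
#'
#' @return A data frame with columns `name`, `lower`, `upper`.
#' @export
hue_families <- function() {
  nm <- c("Red", "Orange", "Yellow", "YellowGreen", "Green", "Turquoise",
          "CyanBlue", "Blue", "Violet", "Purple", "Magenta", "Scarlet")
  data.frame(name = nm, lower = seq(0, 330, by = 30),
             upper = seq(30, 360, by = 30), stringsAsFactors = FALSE)
}

#' Assign a hue angle to its colour family
#'
#' @param hue Hue angle(s) in degrees, each in \[0, 360).
#' @return Character vector of family names.
#' @examples
#' hue_family(134) # "Green"
#' hue_family(215) # "Blue"
#' @export
hue_family <- function(hue) {
  if (any(!is.finite(hue)) || any(hue < 0) || any(hue >= 360)) {
    stop("hue must lie in [0, 360)", call. = FALSE)
  }
  hue_families()$name[floor(hue / 30) + 1L]
}

#' Distance between two hue angles
#'
#' With `wrap = TRUE` (the default) the distance is measured around the colour
#' circle, `min(|a - b|, 360 - |a - b|)`, so it never exceeds 180 degrees and
#' hues straddling the 0/360 boundary (scarlet vs. orange) compare as close.
#' `wrap = FALSE` gives the plain absolute difference, retained for
#' sensitivity analyses.
#'
#' @param a,b Hue angles in degrees, in \[0, 360). Vectorised; recycled.
#' @param wrap Compare circularly (default `TRUE`).
#' @return Distance(s) in degrees.
#' @examples
#' hue_distance(36, 345) # 51, not 309
#' @export
hue_distance <- function(a, b, wrap = TRUE) {
  if (any(!is.finite(c(a, b))) || any(c(a, b) < 0) || any(c(a, b) >= 360)) {
    stop("hues must lie in [0, 360)", call. = FALSE)
  }
  d <- abs(a - b)
  if (wrap) pmin(d, 360 - d) else d
}
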