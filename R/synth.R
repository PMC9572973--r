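# Synthetic fixtures: Gaussian-peak spectra and tolerance-jittered band
# observations, so every matching and scoring path is exercisable without
# instrument data. The Gaussian shape is a deliberately simple smooth
# unimodal stand-in for absorbance bands; the scoring contracts under test
# do not depend on the peak shape.

#' Generate a synthetic spectrum as a sum of Gaussian peaks
#'
#' Evaluates `sum_i height_i * exp(-(wl - centre_i)^2 / (2 width_i^2))` on a
#' regular wavelength grid and adds seeded Gaussian noise. Deterministic for
#' a fixed seed.
#'
#' @param peaks List of `c(centre, height, width)` triples (nm, AU, nm), or a
#'   3-column matrix with one row per peak.
#' @param grid `c(low, high, step)` in nm.
#' @param noise_sd Standard deviation of additive Gaussian noise, AU
#'   (default 0).
#' @param seed Integer seed for the noise (required when `noise_sd > 0`).
#' @inheritParams band_spectrum
#' @return A [band_spectrum()].
#' @examples
#' s <- make_spectrum(list(c(350, 1, 20)), grid = c(250, 500, 1))
#' s$wavelength[which.max(s$intensity)] # 350
#' @export
make_spectrum <- function(peaks, grid = c(250, 500, 1), noise_sd = 0,
                          seed = NULL, modality = c("UV-Vis", "fluorescence"),
                          state = c("pre", "NP-PEG", "VSA")) {
  if (is.matrix(peaks)) peaks <- lapply(seq_len(nrow(peaks)), function(i) peaks[i, ])
  if (length(peaks) == 0) stop("need at least one peak", call. = FALSE)
  if (length(grid) != 3 || grid[3] <= 0 || grid[1] >= grid[2]) {
    stop("grid must be c(low, high, step) with low < high and step > 0",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  wl <- seq(grid[1], grid[2], by = grid[3])
  y <- rep(0, length(wl))
  for (p in peaks) {
    if (length(p) != 3 || p[2] <= 0 || p[3] <= 0) {
      stop("each peak must be c(centre, height > 0, width > 0)", call. = FALSE)
    }
    y <- y + p[2] * exp(-(wl - p[1])^2 / (2 * p[3]^2))
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0", call. = FALSE)
    y <- y + withr::with_seed(seed, rnorm(length(wl), 0, noise_sd))
  }
  band_spectrum(wl, y, modality = match.arg(modality), state = match.arg(state))
}

#' Perturb a library standard into a synthetic band observation
#'
#' Emulates re-measuring a known standard on a fresh plate: every attribute
#' the given view filters on is shifted by a uniform draw within
#' `fraction` of its filtering tolerance (hue shifts wrap around the colour
#' circle). With `fraction < 1` every perturbation stays inside its
#' tolerance, so the source standard must survive its own cascade - the
#' synthetic analogue of a spiked positive control.
#'
#' @param entry One-row slice of an `hptlc_library` (or a list with the same
#'   fields).
#' @param view_label Which database view the band is destined for.
#' @param fraction Fraction of each tolerance to jitter within, in \[0, 1).
#' @param seed Integer seed; draws are deterministic given it.
#' @param thresholds The tolerances defining the jitter scale.
#' @return A [band_observation()].
#' @export
jitter_band <- function(entry, view_label, fraction = 0.4, seed = 1,
                        thresholds = hptlc_thresholds()) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)", call. = FALSE)
  if (is.data.frame(entry)) {
    stopifnot(nrow(entry) == 1)
    entry <- as.list(entry)
    entry$uv_pre <- entry$uv_pre[[1]]
    entry$uv_np <- entry$uv_np[[1]]
  }
  a_view <- view_label %in% c("1A", "2A")
  rf <- if (view_label %in% c("1A", "1B")) entry$rf_mpa else entry$rf_mpb
  withr::with_seed(seed, {
    jit <- function(x, tol) x + runif(1, -1, 1) * fraction * tol
    jit_hue <- function(x, tol) jit(x, tol) %% 360
    args <- list(
      rf = min(1, max(0, jit(rf, thresholds$rf_tol))),
      hue_dev254 = jit_hue(entry$hue_dev254, thresholds$hue_tol),
      hue_dev366 = jit_hue(entry$hue_dev366, thresholds$hue_tol),
      fl_pre_max = jit(entry$fl_pre_max, thresholds$lambda_tol),
      fl_pre_min = jit(entry$fl_pre_min, thresholds$lambda_tol),
      uv_pre = sort(vapply(entry$uv_pre, jit, numeric(1),
                           tol = thresholds$lambda_tol))
    )
    if (a_view) {
      args$hue_np366 <- jit_hue(entry$hue_np366, thresholds$hue_tol)
      args$fl_np_max <- jit(entry$fl_np_max, thresholds$lambda_tol)
      args$uv_np_max <- jit(entry$uv_np[1], thresholds$uv_post_tol)
    } else {
      args$hue_vsa366 <- jit_hue(entry$hue_vsa366, thresholds$hue_tol)
      args$hue_vsa_white <- jit_hue(entry$hue_vsa_white, thresholds$hue_tol)
      args$fl_vs_max <- jit(entry$fl_vs_max, thresholds$lambda_tol)
      if (!is.na(entry$uv_vs_max)) {
        args$uv_vs_max <- jit(entry$uv_vs_max, thresholds$uv_post_tol)
      }
    }
    do.call(band_observation, args)
  })
}
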