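# Independent oracles and shared fixtures. The oracles deliberately avoid the
# package's code paths: the cascade oracle evaluates the conjunction of
# predicates per candidate with explicit loops, and the overlay oracle
# recomputes Pearson r from raw sums.

validation_fixture <- function() {
  yaml::read_yaml(system.file("extdata", "validation_bands.yaml",
                              package = "hptlcID"))
}

band_from_list <- function(x) {
  do.call(band_observation, lapply(x, function(v) as.numeric(unlist(v))))
}

# Conjunction oracle: a candidate survives iff it passes every applied stage,
# evaluated directly from the band and the raw entry values.
oracle_survivors <- function(band, view, thresholds = hptlc_thresholds(),
                             stages = stage_sequence(view$label)) {
  e <- view$entries
  circ <- function(a, b) {
    d <- abs(a - b)
    if (thresholds$wrap_hue) min(d, 360 - d) else d
  }
  ok <- logical(nrow(e))
  for (i in seq_len(nrow(e))) {
    pass <- TRUE
    for (st in stages) {
      p <- switch(st,
        rf = !is.null(band$rf) &&
          abs(band$rf - e$rf[i]) <= thresholds$rf_tol,
        hue_dev254 = ,
        hue_dev366 = ,
        hue_np366 = ,
        hue_vsa366 = ,
        hue_vsa_white = {
          q <- band[[st]]
          if (is.null(q)) NA else circ(q, e[[st]][i]) <= thresholds$hue_tol
        },
        fl_pre_max = ,
        fl_pre_min = {
          q <- band[[st]]
          if (is.null(q)) NA else abs(q - e[[st]][i]) <= thresholds$lambda_tol
        },
        uv_pre_lambda = if (is.null(band$uv_pre)) NA else
          abs(band$uv_pre[1] - e$uv_pre[[i]][1]) <= thresholds$lambda_tol,
        uv_pre_peaks = if (is.null(band$uv_pre)) NA else
          length(band$uv_pre) == length(e$uv_pre[[i]]) &&
            all(abs(band$uv_pre - e$uv_pre[[i]]) <= thresholds$lambda_tol),
        fl_np_max = if (is.null(band$fl_np_max)) NA else
          abs(band$fl_np_max - e$fl_np_max[i]) <= thresholds$lambda_tol,
        uv_np_max = if (is.null(band$uv_np_max)) NA else
          abs(band$uv_np_max - e$uv_np[[i]][1]) <= thresholds$uv_post_tol,
        fl_vs_max = if (is.null(band$fl_vs_max)) NA else
          abs(band$fl_vs_max - e$fl_vs_max[i]) <= thresholds$lambda_tol,
        uv_vs_max = if (is.null(band$uv_vs_max)) NA else
          !is.na(e$uv_vs_max[i]) &&
            abs(band$uv_vs_max - e$uv_vs_max[i]) <= thresholds$uv_post_tol
      )
      if (is.na(p)) next # band value absent: stage skipped
      if (!p) { pass <- FALSE; break }
    }
    ok[i] <- pass
  }
  e$code[ok]
}

# Direct-summation overlay oracle: clip, normalise by windowed max, pair
# point-by-point on the (shared) grid, Pearson via raw sums.
oracle_overlay <- function(u_wl, u_y, s_wl, s_y, window, band = 0.125) {
  uk <- u_wl >= window[1] & u_wl <= window[2]
  sk <- s_wl >= window[1] & s_wl <= window[2]
  u_wl <- u_wl[uk]; u_y <- u_y[uk] / max(u_y[uk])
  s_wl <- s_wl[sk]; s_y <- s_y[sk] / max(s_y[sk])
  # interpolate standard at unknown wavelengths (manual linear interpolation)
  sy_at <- vapply(u_wl, function(w) {
    if (w <= s_wl[1]) return(s_y[1])
    if (w >= s_wl[length(s_wl)]) return(s_y[length(s_y)])
    j <- max(which(s_wl <= w))
    if (s_wl[j] == w) return(s_y[j])
    s_y[j] + (s_y[j + 1] - s_y[j]) * (w - s_wl[j]) / (s_wl[j + 1] - s_wl[j])
  }, numeric(1))
  n <- length(u_wl)
  sx <- sum(u_y); sy <- sum(sy_at)
  sxx <- sum(u_y^2); syy <- sum(sy_at^2); sxy <- sum(u_y * sy_at)
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(r = r, pct = 100 * sum(abs(u_y - sy_at) <= band) / n, n = n)
}

# A random-but-valid band for a view, drawn uniformly over plausible ranges.
random_band <- function(view_label, seed) {
  withr::with_seed(seed, {
    n_peaks <- sample(1:3, 1)
    args <- list(
      rf = runif(1, 0, 0.8),
      hue_dev254 = runif(1, 0, 360),
      hue_dev366 = runif(1, 0, 360),
      fl_pre_max = runif(1, 210, 260),
      fl_pre_min = runif(1, 230, 280),
      uv_pre = sort(runif(n_peaks, 240, 500))
    )
    if (view_label %in% c("1A", "2A")) {
      args$hue_np366 <- runif(1, 0, 360)
      args$fl_np_max <- runif(1, 215, 260)
      args$uv_np_max <- runif(1, 250, 500)
    } else {
      args$hue_vsa366 <- runif(1, 0, 360)
      args$hue_vsa_white <- runif(1, 0, 360)
      args$fl_vs_max <- runif(1, 230, 270)
      args$uv_vs_max <- runif(1, 240, 540)
    }
    do.call(band_observation, args)
  })
}
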