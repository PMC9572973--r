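test_that("interval and peak-list predicates are inclusive at the boundary", {
  expect_true(passes_interval(276, 261, 15))  # exactly at tolerance
  expect_true(passes_interval(258, 243, 15))
  expect_false(passes_interval(239, 223, 15)) # 16 nm out
  expect_true(passes_interval(180, 120, 60, circular = TRUE))
  expect_true(passes_interval(36, 345, 60, circular = TRUE))  # wraps: 51 deg
  expect_false(passes_interval(36, 345, 60, circular = FALSE))
  expect_false(passes_uv_peaks(276, c(261, 364), 15)) # peak-count mismatch
  expect_true(passes_uv_peaks(c(269, 369), c(269, 371), 15))
  expect_true(passes_uv_peaks(276, 267, 15))
})

test_that("stage sequences match the two derivatisation layouts", {
  expect_equal(stage_sequence("1A"),
               c("rf", "hue_dev254", "hue_dev366", "hue_np366", "fl_pre_max",
                 "fl_pre_min", "uv_pre_lambda", "uv_pre_peaks", "fl_np_max",
                 "uv_np_max"))
  expect_length(stage_sequence("1B"), 11)
  expect_true(all(c("hue_vsa366", "hue_vsa_white", "fl_vs_max", "uv_vs_max")
                  %in% stage_sequence("2B")))
  expect_equal(stage_sequence("2A"), stage_sequence("1A"))
  expect_error(stage_sequence("9Z"), "unknown view label")
})

test_that("the spiked syringic-acid band reproduces its recorded NP-PEG cascade", {
  fx <- validation_fixture()$compound_a$mpa_np
  band <- band_from_list(fx$band)
  view <- select_view(hptlc_library(), fx$view, codes = unlist(fx$rf_candidates))
  trace <- run_cascade(band, view,
                       stages = setdiff(stage_sequence("1A"), "rf"))
  expect_equal(trace$n, c(42L, 40L, 31L, 31L, 25L, 11L, 6L, 5L, 5L))
  # 2,3,4-trihydroxybenzoic, eudesmic, methyl syringate, syringic, m-coumaric
  expect_setequal(final_matches(trace), c(36, 43, 48, 58, 67))
  # survivor sets are nested along the cascade
  surv <- lapply(strsplit(trace$survivors, ","), as.integer)
  for (i in 2:length(surv)) expect_true(all(surv[[i]] %in% surv[[i - 1]]))
  expect_true(all(diff(trace$n) <= 0))
})

test_that("the same band against the VSA view narrows to the syringate pair", {
  fx <- validation_fixture()$compound_a$mpa_vsa
  band <- band_from_list(fx$band)
  view <- select_view(hptlc_library(), fx$view, codes = unlist(fx$rf_candidates))
  trace <- run_cascade(band, view,
                       stages = setdiff(stage_sequence("1B"), "rf"))
  expect_setequal(final_matches(trace), c(48, 58)) # methyl syringate, syringic acid
})

test_that("a two-peak query eliminates one- and three-peak candidates", {
  fx <- validation_fixture()$compound_b$mpa_np
  band <- band_from_list(fx$band)
  view <- select_view(hptlc_library(), fx$view)
  trace <- run_cascade(band, view)
  # isorhamnetin and kaempferol both carry (261/269, 364/371) maxima
  peaks_row <- trace[trace$stage == "uv_pre_peaks", ]
  expect_setequal(as.integer(strsplit(peaks_row$survivors, ",")[[1]]),
                  c(12, 14))
})

test_that("every standard survives its own cascade in every view", {
  lib <- hptlc_library()
  for (lab in c("1A", "1B", "2A", "2B")) {
    view <- select_view(lib, lab)
    for (i in seq_len(nrow(lib))) {
      band <- jitter_band(lib[i, ], lab, fraction = 0, seed = 1)
      expect_true(lib$code[i] %in% final_matches(run_cascade(band, view)),
                  label = sprintf("self-match code %d in view %s", i, lab))
    }
  }
})

test_that("final survivors equal the brute-force conjunction oracle", {
  lib <- hptlc_library()
  views <- lapply(c("1A", "1B", "2A", "2B"), select_view, library = lib)
  names(views) <- c("1A", "1B", "2A", "2B")
  for (seed in 1:60) {
    lab <- c("1A", "1B", "2A", "2B")[(seed %% 4) + 1]
    band <- random_band(lab, seed)
    got <- final_matches(run_cascade(band, views[[lab]]))
    want <- oracle_survivors(band, views[[lab]])
    expect_equal(got, want, label = sprintf("seed %d view %s", seed, lab))
  }
})

test_that("permuting stages changes the trace but not the final set", {
  fx <- validation_fixture()$compound_a$mpa_np
  band <- band_from_list(fx$band)
  view <- select_view(hptlc_library(), fx$view, codes = unlist(fx$rf_candidates))
  stages <- setdiff(stage_sequence("1A"), "rf")
  base <- final_matches(run_cascade(band, view, stages = stages))
  withr::with_seed(11, {
    for (i in 1:5) {
      perm <- sample(stages)
      expect_setequal(final_matches(run_cascade(band, view, stages = perm)),
                      base)
    }
  })
})

test_that("perturbations within half of each tolerance are always recovered", {
  lib <- hptlc_library()
  views <- lapply(c("1A", "1B", "2A", "2B"), select_view, library = lib)
  names(views) <- c("1A", "1B", "2A", "2B")
  withr::with_seed(99, idx <- sample(107, 12))
  for (i in idx) {
    for (lab in c("1A", "2B")) {
      for (seed in 1:5) {
        band <- jitter_band(lib[i, ], lab, fraction = 0.45, seed = seed)
        expect_true(lib$code[i] %in% final_matches(run_cascade(band, views[[lab]])),
                    label = sprintf("jitter recovery code %d view %s seed %d",
                                    i, lab, seed))
      }
    }
  }
})

test_that("missing band attributes skip stages; missing rf is an error", {
  lib <- hptlc_library()
  view <- select_view(lib, "1A")
  band <- band_observation(rf = 0.634, hue_dev254 = 138)
  w <- capture_warnings(trace <- run_cascade(band, view))
  expect_length(w, 8) # one per unobserved stage attribute
  expect_true(all(grepl("skipped", w)))
  expect_equal(trace$stage, c("rf", "hue_dev254"))
  no_rf <- band_observation(hue_dev254 = 138)
  expect_error(suppressWarnings(run_cascade(no_rf, view)), "no Rf value")
})

test_that("zero tolerances with perturbed values eliminate everyone", {
  lib <- hptlc_library()
  view <- select_view(lib, "1A")
  entry <- lib[48, ]
  band <- band_observation(
    rf = entry$rf_mpa + 0.001, hue_dev254 = entry$hue_dev254 + 0.001,
    hue_dev366 = entry$hue_dev366 + 0.001, hue_np366 = entry$hue_np366 + 0.001,
    fl_pre_max = entry$fl_pre_max + 0.001, fl_pre_min = entry$fl_pre_min + 0.001,
    uv_pre = entry$uv_pre[[1]] + 0.001, fl_np_max = entry$fl_np_max + 0.001,
    uv_np_max = entry$uv_np[[1]][1] + 0.001)
  zero <- hptlc_thresholds(rf_tol = 0, hue_tol = 0, lambda_tol = 0,
                           uv_post_tol = 0)
  expect_length(final_matches(run_cascade(band, view, thresholds = zero)), 0)
})

test_that("band files round-trip through YAML", {
  b <- band_observation(rf = 0.608, hue_dev254 = 139.3, hue_dev366 = 180,
                        hue_np366 = 209.2, fl_pre_max = 225, fl_pre_min = 258,
                        uv_pre = 276, fl_np_max = 239, uv_np_max = 288)
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(Filter(Negate(is.null), unclass(b)), f)
  b2 <- read_band(f)
  expect_equal(b2, b)
  writeLines("rf: 0.5\nbogus_key: 1", f)
  expect_error(read_band(f), "bogus_key")
})
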