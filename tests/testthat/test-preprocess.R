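test_that("WHOLE takes the first n_points unchanged and checks lengths", {
  p <- clean_params(n_strides = 26, seed = 2)  # ~2756 samples
  tr <- prepared_recording(p)
  expect_gte(recording_length(tr$recording), 2200)
  w <- make_whole(tr$recording, "copap", 2200)
  expect_identical(length(w$values), 2200L)
  expect_identical(w$values, tr$recording$copap[1:2200])
  n <- recording_length(tr$recording)
  full <- make_whole(tr$recording, "vgrf", n)
  expect_identical(full$values, tr$recording$vgrf)
  expect_error(make_whole(tr$recording, "copap", 0),
               class = "gaitsampen_length_error")
  err <- tryCatch(make_whole(tr$recording, "copap", n + 1), error = identity)
  expect_s3_class(err, "gaitsampen_length_error")
  expect_match(conditionMessage(err), as.character(n))
  expect_match(conditionMessage(err), as.character(n + 1))
})

test_that("SEGM resamples every cycle to the target grid", {
  p <- gait_params(n_strides = 13, seed = 8)
  tr <- prepared_recording(p)
  s <- segment_resample(tr$recording, tr$segmentation, "copap", 100, 8)
  expect_identical(length(s$values), 800L)
  expect_identical(s$type_tag, "SEGM")
  expect_error(
    segment_resample(tr$recording, tr$segmentation, "copap", 100, 50),
    class = "gaitsampen_too_few_cycles")
})

test_that("resampling is exact on already-conforming and linear cycles", {
  # cycle already exactly 100 samples long: returned unchanged
  vals <- sin(seq(0, 2 * pi, length.out = 300))
  rec <- gait_recording(100, vals, vals, abs(vals) + 1)
  seg <- stride_segmentation(c(1L, 101L, 201L, 301L), 100)
  s <- segment_resample(rec, seg, "copap", 100, 3)
  expect_equal(s$values[1:100], vals[1:100], tolerance = 1e-9)
  # a 73-point linear ramp stays an exact line on the 100-point grid
  ramp <- seq(2, 10, length.out = 73)
  rec2 <- gait_recording(100, c(ramp, ramp), c(ramp, ramp),
                         rep(1, 146))
  seg2 <- stride_segmentation(c(1L, 74L, 147L), 100)
  s2 <- segment_resample(rec2, seg2, "copap", 100, 1)
  expect_equal(s2$values, seq(2, 10, length.out = 100), tolerance = 1e-9)
})

test_that("NORM rescales every cycle exactly to [0, 1] and is affine-invariant", {
  p <- gait_params(n_strides = 10, seed = 12)
  tr <- prepared_recording(p)
  s <- segment_resample(tr$recording, tr$segmentation, "copap", 100)
  nrm <- normalize_spatial(s)
  m <- matrix(nrm$values, ncol = 100, byrow = TRUE)
  expect_equal(unname(apply(m, 1, min)), rep(0, nrow(m)))
  expect_equal(unname(apply(m, 1, max)), rep(1, nrow(m)))
  # positive affine transform of the input leaves the output unchanged
  s_aff <- s
  s_aff$values <- 3.7 * s$values - 11
  expect_equal(normalize_spatial(s_aff)$values, nrm$values, tolerance = 1e-12)
  # degenerate (constant) cycle is reported with its index
  s_bad <- s
  s_bad$values[101:200] <- 5
  err <- tryCatch(normalize_spatial(s_bad), error = identity)
  expect_s3_class(err, "gaitsampen_degenerate_cycle")
  expect_match(conditionMessage(err), "cycle 2")
})

test_that("the vGRF admits neither spatial normalisation nor zeroing", {
  p <- gait_params(n_strides = 8, seed = 13)
  tr <- prepared_recording(p)
  sv <- segment_resample(tr$recording, tr$segmentation, "vgrf", 100)
  expect_error(normalize_spatial(sv), class = "gaitsampen_parameter_error")
  sa <- segment_resample(tr$recording, tr$segmentation, "copap", 100)
  expect_error(zero_cycles(sa, sv), class = "gaitsampen_parameter_error")
})

test_that("ZERO translates cycles to (0,0) and preserves first differences", {
  p <- gait_params(n_strides = 10, seed = 14, drift_rate = 3)
  tr <- prepared_recording(p)
  sa <- segment_resample(tr$recording, tr$segmentation, "copap", 100)
  sm <- segment_resample(tr$recording, tr$segmentation, "copml", 100)
  z <- zero_cycles(sa, sm)
  for (sig in z) {
    m <- matrix(sig$values, ncol = 100, byrow = TRUE)
    expect_identical(unname(m[, 1]), rep(0, nrow(m)))
  }
  # within-cycle first differences unchanged to 1e-12
  for (pair in list(c("copap", 1), c("copml", 2))) {
    before <- matrix(list(sa, sm)[[as.integer(pair[2])]]$values,
                     ncol = 100, byrow = TRUE)
    after <- matrix(z[[pair[1]]]$values, ncol = 100, byrow = TRUE)
    expect_equal(t(diff(t(after))), t(diff(t(before))), tolerance = 1e-12)
  }
  # mismatched cycle structure is a structure error
  sm_short <- segment_resample(tr$recording, tr$segmentation, "copml", 100,
                               n_cycles(tr$segmentation) - 1)
  expect_error(zero_cycles(sa, sm_short), class = "gaitsampen_structure_error")
})

test_that("zeroing collapses pure linear drift: all cycles become identical", {
  p <- clean_params(n_strides = 10, drift_rate = 5, seed = 15)
  rec <- generate_recording(p)
  seg <- stride_segmentation(rec$true_boundaries, 100)
  sa <- segment_resample(rec, seg, "copap", 100)
  sm <- segment_resample(rec, seg, "copml", 100)
  z <- zero_cycles(sa, sm)
  m <- matrix(z$copap$values, ncol = 100, byrow = TRUE)
  for (k in 2:nrow(m)) expect_equal(m[k, ], m[1, ], tolerance = 1e-9)
})

test_that("zeroing removes linear drift from the entropy's point of view", {
  # with equal-duration cycles, zeroed cycles of a drifted periodic signal
  # differ from the undrifted ones only by one and the same within-cycle
  # ramp, so both stay exactly periodic and their SampEn agree
  base <- clean_params(n_strides = 12, seed = 16)
  drifted <- base
  drifted$drift_rate <- 4
  zeroed <- function(params) {
    rec <- generate_recording(params)
    seg <- stride_segmentation(rec$true_boundaries, params$sampling_rate)
    sa <- segment_resample(rec, seg, "copap", 100)
    sm <- segment_resample(rec, seg, "copml", 100)
    zero_cycles(sa, sm)$copap
  }
  z_base <- zeroed(base)
  z_drift <- zeroed(drifted)
  diff_cycles <- matrix(z_drift$values - z_base$values, ncol = 100,
                        byrow = TRUE)
  for (k in 2:nrow(diff_cycles)) {
    expect_equal(diff_cycles[k, ], diff_cycles[1, ], tolerance = 1e-9)
  }
  # the residual within-cycle ramp is the only footprint drift leaves after
  # zeroing, so the entropy shift it causes is far smaller than the one the
  # un-zeroed segmented signal suffers
  e <- function(sig) sample_entropy(sig, m = 2, r = 0.5)$value
  rec_b <- generate_recording(base)
  rec_d <- generate_recording(drifted)
  seg_b <- stride_segmentation(rec_b$true_boundaries, 100)
  seg_d <- stride_segmentation(rec_d$true_boundaries, 100)
  segm_b <- segment_resample(rec_b, seg_b, "copap", 100)
  segm_d <- segment_resample(rec_d, seg_d, "copap", 100)
  expect_lt(abs(e(z_drift) - e(z_base)),
            abs(e(segm_d) - e(segm_b)))
})
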