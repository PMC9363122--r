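test_that("bin centers anchor at midpoints and rescale to the earliest bin", {
  a <- aging_dataset(data.frame(low = c(20, 30), high = c(30, 40),
                                mean_bmd = c(1.00, 0.95)))
  anchors <- bin_centers(a)
  expect_equal(anchors$age, c(25, 35))
  expect_equal(anchors$bmd_rel, c(1.00, 0.95))

  ## absolute-scale input rescales to 1 at the earliest bin
  a2 <- aging_dataset(data.frame(low = c(20, 30, 40),
                                 high = c(30, 40, 50),
                                 mean_bmd = c(0.88, 0.86, 0.82)))
  expect_equal(bin_centers(a2)$bmd_rel[1], 1)

  ## open-ended last bin centered with the preceding bin's width
  a3 <- aging_dataset(data.frame(low = c(60, 70, 80),
                                 high = c(70, 80, NA),
                                 mean_bmd = c(0.8, 0.75, 0.7)))
  anchors3 <- bin_centers(a3)
  expect_equal(anchors3$age[3], 85)
  expect_equal(attr(anchors3, "open_ended_width"), 10)

  expect_error(aging_dataset(data.frame(low = c(20, 25), high = c(30, 35),
                                        mean_bmd = c(1, 1))),
               "non-overlapping")
})

test_that("the hybrid merge rescales treatment BMD onto the aging curve", {
  anchors <- tibble::tibble(age = c(55, 65, 75),
                            bmd_rel = c(0.95, 0.90, 0.85))
  trt <- treatment_dataset("demo", baseline_age_mean = 65.4,
                           bmd = data.frame(time = c(0, 1, 2),
                                            value = c(1.00, 1.04, 1.06)))
  h <- build_hybrid(anchors, trt)
  expect_equal(h$treatment_start_age, 65)
  expect_equal(h$treatment$bmd_rel, c(0.900, 0.936, 0.954))
  expect_equal(h$treatment$age, c(65, 66, 67))

  ## rounding rule: 66.6 -> 67
  trt2 <- treatment_dataset("demo2", baseline_age_mean = 66.6,
                            bmd = data.frame(time = 0, value = 1))
  expect_equal(build_hybrid(anchors, trt2)$treatment_start_age, 67)

  ## already consistent series is left unchanged (idempotence)
  trt3 <- treatment_dataset("demo3", baseline_age_mean = 65,
                            bmd = data.frame(time = c(0, 1),
                                             value = c(0.90, 0.91)))
  h3 <- build_hybrid(anchors, trt3)
  expect_equal(h3$scale_factor, 1)
  expect_equal(h3$treatment$bmd_rel, c(0.90, 0.91))

  ## no extrapolation outside the anchor range
  trt4 <- treatment_dataset("demo4", baseline_age_mean = 80,
                            bmd = data.frame(time = 0, value = 1))
  expect_error(build_hybrid(anchors, trt4), "extrapolate")
})

test_that("raw BTM series are normalized to fractional baseline changes", {
  anchors <- tibble::tibble(age = c(55, 65, 75),
                            bmd_rel = c(0.95, 0.90, 0.85))
  trt <- treatment_dataset(
    "btm_raw", baseline_age_mean = 65,
    bmd = data.frame(time = c(0, 1), value = c(1, 1.02)),
    btm = data.frame(marker = "ctx", time = c(0, 0.5, 1),
                     value = c(0.40, 0.10, 0.20)),
    btm_normalized = FALSE)
  h <- build_hybrid(anchors, trt)
  expect_equal(h$btm$change, c(0, -0.75, -0.5))
  expect_equal(h$btm$age, c(65, 65.5, 66))
})

test_that("dataset files round trip losslessly through the directory dialect", {
  dir <- withr::local_tempdir()
  aging <- aging_dataset(data.frame(low = seq(20, 80, 10),
                                    high = c(seq(30, 80, 10), NA),
                                    mean_bmd = seq(1, 0.7, length.out = 7)))
  write_aging_dataset(aging, dir)
  trt <- treatment_dataset(
    "rt", baseline_age_mean = 65,
    bmd = data.frame(time = c(0, 0.5), value = c(1, 1.01)),
    btm = data.frame(marker = "ctx", time = c(0, 0.5),
                     value = c(0, -0.6)),
    regimen = deno_regimen("1yr"), n_subjects = 30L)
  write_treatment_dataset(trt, dir, role = "validation")

  coll <- load_study_collection(dir)
  expect_equal(coll$aging$bins$mean_bmd, aging$bins$mean_bmd)
  expect_named(coll$validation, "rt")
  expect_length(coll$calibration, 0)
  h <- coll$validation$rt
  expect_equal(h$treatment_start_age, 65)
  expect_equal(nrow(h$btm), 2)
  ## hybrid invariant: baseline equals the interpolated aging anchor
  anchors <- bin_centers(aging)
  expect_equal(h$treatment$bmd_rel[1],
               stats::approx(anchors$age, anchors$bmd_rel, xout = 65)$y)
})
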