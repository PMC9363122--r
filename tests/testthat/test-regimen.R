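test_that("block expansion places boluses at the clinical schedule", {
  r <- make_block_regimen(
    data.frame(drug_id = "denosumab", dose = 60, interval = "6mo",
               duration = "1yr"), start_age = 67)
  expect_equal(r$time, c(67, 67.5))
  expect_equal(r$dose, c(60, 60))

  r52 <- make_block_regimen(
    data.frame(drug_id = "alendronate", dose = 70, interval = "1w",
               duration = "1yr"), start_age = 67)
  expect_equal(nrow(r52), 52)
  expect_equal(r52$time[1], 67)
  expect_true(all(r52$time < 68))

  expect_equal(nrow(make_block_regimen(list())), 0)
})

test_that("sequential blocks concatenate; explicit starts run in parallel", {
  seq2 <- make_block_regimen(tibble::tibble(
    drug_id = c("alendronate", "denosumab"), dose = c(70, 60),
    interval = c("1w", "6mo"), duration = c("1yr", "1yr")), start_age = 65)
  b <- regimen_blocks(seq2)
  expect_equal(b$start, c(65, 66))
  expect_equal(b$end, c(66, 67))

  expect_message(
    par2 <- make_block_regimen(tibble::tibble(
      drug_id = c("teriparatide", "denosumab"), dose = c(0.02, 60),
      interval = c("1mo", "6mo"), duration = c("1yr", "1yr"),
      start = c(65, 65))),
    "parallel")
  expect_equal(regimen_blocks(par2)$start, c(65, 65))
})

test_that("durations parse with d/w/mo/yr units", {
  expect_equal(parse_duration(c("1w", "6mo", "1yr", "70d")),
               c(1 / 52, 0.5, 1, 70 / 365))
  expect_equal(parse_duration(2.5), 2.5)
  expect_error(parse_duration("6 fortnights"), "duration")
})

test_that("regimen files round trip through the block metadata", {
  r <- make_block_regimen(tibble::tibble(
    drug_id = c("alendronate", "romosozumab", "denosumab"),
    dose = c(70, 140, 60), interval = c("1w", "1mo", "6mo"),
    duration = c("1yr", "1yr", "1yr")), start_age = 67)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_regimen(r, path)
  r2 <- read_regimen(path)
  expect_equal(r2$time, r$time)
  expect_equal(r2$dose, r$dose)
  expect_equal(r2$drug_id, r$drug_id)
})

test_that("unknown drugs and degenerate blocks are rejected", {
  expect_error(make_block_regimen(
    data.frame(drug_id = "aspirin", dose = 100, interval = "1w",
               duration = "1yr")), "unknown drug_id")
  expect_error(make_block_regimen(
    data.frame(drug_id = "denosumab", dose = -5, interval = "6mo",
               duration = "1yr")), "positive")
})
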