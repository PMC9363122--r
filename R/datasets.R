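#' Aging BMD dataset in age bins
#'
#' Population-average BMD reported in (typically 10-year) age bins, as in
#' cross-sectional reference surveys. The final bin may be open-ended
#' (`high = NA`, "80 and older").
#'
#' @param bins A data frame with columns `low`, `high` (years; `high` may be
#'   `NA` for the last, open-ended bin) and `mean_bmd` (absolute or
#'   relative).
#' @param cohort Cohort label.
#' @return An `osteo_aging` object.
#' @export
aging_dataset <- function(bins, cohort = "unspecified") {
  bins <- tibble::as_tibble(bins)
  stopifnot(all(c("low", "high", "mean_bmd") %in% names(bins)),
            nrow(bins) >= 2)
  if (anyNA(bins$low) || anyNA(bins$high[-nrow(bins)])) {
    stop("only the last bin may be open-ended", call. = FALSE)
  }
  closed_high <- ifelse(is.na(bins$high), Inf, bins$high)
  if (is.unsorted(bins$low, strictly = TRUE) ||
      any(bins$low[-1] < closed_high[-nrow(bins)])) {
    stop("age bins must be ascending and non-overlapping", call. = FALSE)
  }
  structure(list(bins = bins, cohort = cohort), class = "osteo_aging")
}

#' Bin-center BMD anchors of an aging dataset
#'
#' Places each bin's mean BMD at the bin's center age and rescales the
#' anchor series to its value in the earliest bin (which therefore becomes
#' 1). An open-ended last bin is centered assuming the same width as the
#' preceding bin; this convention is recorded in the result's
#' `open_ended_width` attribute.
#'
#' @param aging An `osteo_aging` dataset.
#' @return Tibble with columns `age` (bin centers) and `bmd_rel`
#'   (relative to the earliest bin).
#' @examples
#' a <- aging_dataset(data.frame(low = c(20, 30), high = c(30, 40),
#'                               mean_bmd = c(1.00, 0.95)))
#' bin_centers(a) # anchors at 25 and 35; values 1.00, 0.95
#' @export
bin_centers <- function(aging) {
  stopifnot(inherits(aging, "osteo_aging"))
  b <- aging$bins
  width <- b$high - b$low
  open_width <- NA_real_
  if (is.na(b$high[nrow(b)])) {
    open_width <- width[nrow(b) - 1]
    width[nrow(b)] <- open_width
  }
  centers <- b$low + width / 2
  out <- tibble::tibble(age = centers, bmd_rel = b$mean_bmd / b$mean_bmd[1])
  attr(out, "open_ended_width") <- open_width
  out
}

#' Clinical treatment dataset
#'
#' A digitised study-average series: relative (or absolute) total-hip BMD at
#' study times since treatment start, plus zero or more bone-turnover-marker
#' series. The first BMD time point must be the baseline visit (time 0).
#'
#' @param label Study label.
#' @param baseline_age_mean Mean age of the study population at baseline
#'   (years).
#' @param bmd A data frame with columns `time` (years since treatment
#'   start) and `value`.
#' @param btm Optional data frame with columns `marker` (`"ctx"`, `"p1np"`,
#'   `"bsap"`), `time` and `value`; `value` is either a raw concentration
#'   (`btm_normalized = FALSE`) or already a fractional change from baseline
#'   (`TRUE`).
#' @param regimen The study's `osteo_regimen` (dose event ages may use any
#'   origin; only relative timing matters until the hybrid merge), or
#'   `NULL`.
#' @param n_subjects Number of subjects.
#' @param btm_normalized Whether `btm$value` is already a fractional
#'   baseline change.
#' @return An `osteo_treatment` object.
#' @export
treatment_dataset <- function(label, baseline_age_mean, bmd, btm = NULL,
                              regimen = NULL, n_subjects = NA_integer_,
                              btm_normalized = TRUE) {
  bmd <- tibble::as_tibble(bmd)
  stopifnot(all(c("time", "value") %in% names(bmd)), nrow(bmd) >= 1)
  if (abs(bmd$time[1]) > 1e-9) {
    stop("first BMD time point must be the baseline visit (time 0)",
         call. = FALSE)
  }
  if (!is.null(btm)) {
    btm <- tibble::as_tibble(btm)
    stopifnot(all(c("marker", "time", "value") %in% names(btm)))
  }
  structure(list(label = label, baseline_age_mean = baseline_age_mean,
                 bmd = bmd, btm = btm, regimen = regimen,
                 n_subjects = n_subjects, btm_normalized = btm_normalized),
            class = "osteo_treatment")
}

#' Merge an aging and a treatment dataset into a hybrid dataset
#'
#' Implements the hybrid aging/treatment construction: the treatment start
#' is placed at the study population's mean baseline age rounded to full
#' years; the treatment BMD series is rescaled so its baseline equals the
#' linearly interpolated aging-anchor BMD at that age; treatment times
#' become ages; raw BTM series are normalized to fractional changes from
#' their baseline value. Baseline ages outside the aging anchor range are
#' refused (no extrapolation).
#'
#' @param aging An `osteo_aging` dataset (or a precomputed anchor tibble
#'   from [bin_centers()]).
#' @param treatment An `osteo_treatment` dataset.
#' @return An `osteo_hybrid` object: list with `aging_anchors` (tibble
#'   `age`, `bmd_rel`), `treatment` (tibble `age`, `bmd_rel`), `btm`
#'   (tibble `marker`, `age`, `change` or `NULL`), `treatment_start_age`,
#'   `scale_factor`, `regimen`, `label`, `n_subjects`.
#' @export
build_hybrid <- function(aging, treatment) {
  stopifnot(inherits(treatment, "osteo_treatment"))
  anchors <- if (inherits(aging, "osteo_aging")) bin_centers(aging) else
    tibble::as_tibble(aging)
  stopifnot(all(c("age", "bmd_rel") %in% names(anchors)))

  start_age <- round(treatment$baseline_age_mean)
  if (start_age < min(anchors$age) || start_age > max(anchors$age)) {
    stop(sprintf(
      "treatment start age %d outside aging anchor range [%g, %g]; refusing to extrapolate",
      start_age, min(anchors$age), max(anchors$age)), call. = FALSE)
  }
  anchor_bmd <- stats::approx(anchors$age, anchors$bmd_rel,
                              xout = start_age)$y
  scale <- anchor_bmd / treatment$bmd$value[1]
  trt <- tibble::tibble(age = start_age + treatment$bmd$time,
                        bmd_rel = treatment$bmd$value * scale)

  btm <- NULL
  if (!is.null(treatment$btm)) {
    btm <- treatment$btm
    if (!treatment$btm_normalized) {
      btm <- dplyr::group_by(btm, .data$marker)
      btm <- dplyr::mutate(btm, change = {
        base <- .data$value[which.min(.data$time)]
        if (base == 0) stop("zero BTM baseline value; cannot normalize",
                            call. = FALSE)
        .data$value / base - 1
      })
      btm <- dplyr::ungroup(btm)
    } else {
      btm$change <- btm$value
    }
    btm <- tibble::tibble(marker = btm$marker,
                          age = start_age + btm$time,
                          change = btm$change)
  }

  structure(list(aging_anchors = anchors, treatment = trt, btm = btm,
                 treatment_start_age = start_age, scale_factor = scale,
                 regimen = treatment$regimen, label = treatment$label,
                 n_subjects = treatment$n_subjects),
            class = "osteo_hybrid")
}

#' @export
print.osteo_hybrid <- function(x, ...) {
  cat("<osteo_hybrid> ", x$label, ": treatment start age ",
      x$treatment_start_age, ", ", nrow(x$treatment), " BMD points",
      if (!is.null(x$btm)) paste0(", ", nrow(x$btm), " BTM points"), "\n",
      sep = "")
  invisible(x)
}

## ---- file I/O ---------------------------------------------------------

#' Write and read dataset files
#'
#' On-disk dialect: UTF-8 comma-delimited tables with a header row, one file
#' per series, plus a JSON metadata sidecar. A treatment dataset `label`
#' under directory `dir` consists of `label_bmd.csv` (`time,value`),
#' optionally `label_btm.csv` (`marker,time,value`), optionally
#' `label_regimen.yaml`, and `label.json` (baseline age, N, role,
#' btm_normalized). An aging dataset is `aging.csv` (`low,high,mean_bmd`)
#' plus `aging.json` (cohort).
#'
#' @param treatment An `osteo_treatment`.
#' @param aging An `osteo_aging`.
#' @param dir Directory (created if missing).
#' @param role `"calibration"` or `"validation"` (recorded in metadata).
#' @return The dataset label (invisibly) for writers; dataset objects for
#'   readers.
#' @export
write_treatment_dataset <- function(treatment, dir, role = "calibration") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lb <- treatment$label
  readr::write_csv(treatment$bmd, file.path(dir, paste0(lb, "_bmd.csv")))
  if (!is.null(treatment$btm)) {
    readr::write_csv(treatment$btm[c("marker", "time", "value")],
                     file.path(dir, paste0(lb, "_btm.csv")))
  }
  if (!is.null(treatment$regimen)) {
    write_regimen(treatment$regimen,
                  file.path(dir, paste0(lb, "_regimen.yaml")))
  }
  meta <- list(label = lb, baseline_age_mean = treatment$baseline_age_mean,
               n_subjects = treatment$n_subjects, role = role,
               btm_normalized = treatment$btm_normalized,
               has_btm = !is.null(treatment$btm),
               has_regimen = !is.null(treatment$regimen))
  jsonlite::write_json(meta, file.path(dir, paste0(lb, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(lb)
}

#' @rdname write_treatment_dataset
#' @export
read_treatment_dataset <- function(dir, label) {
  meta <- jsonlite::read_json(file.path(dir, paste0(label, ".json")),
                              simplifyVector = TRUE)
  bmd <- readr::read_csv(file.path(dir, paste0(label, "_bmd.csv")),
                         show_col_types = FALSE)
  btm <- NULL
  if (isTRUE(meta$has_btm)) {
    btm <- readr::read_csv(file.path(dir, paste0(label, "_btm.csv")),
                           show_col_types = FALSE)
  }
  regimen <- NULL
  if (isTRUE(meta$has_regimen)) {
    regimen <- read_regimen(file.path(dir, paste0(label, "_regimen.yaml")))
  }
  treatment_dataset(label = meta$label,
                    baseline_age_mean = meta$baseline_age_mean,
                    bmd = bmd, btm = btm, regimen = regimen,
                    n_subjects = meta$n_subjects,
                    btm_normalized = isTRUE(meta$btm_normalized))
}

#' @rdname write_treatment_dataset
#' @export
write_aging_dataset <- function(aging, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(aging$bins, file.path(dir, "aging.csv"))
  jsonlite::write_json(list(cohort = aging$cohort),
                       file.path(dir, "aging.json"), auto_unbox = TRUE)
  invisible("aging")
}

#' @rdname write_treatment_dataset
#' @export
read_aging_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "aging.json"),
                              simplifyVector = TRUE)
  bins <- readr::read_csv(file.path(dir, "aging.csv"),
                          show_col_types = FALSE)
  aging_dataset(bins, cohort = meta$cohort)
}

#' Load a study collection from a directory tree
#'
#' Assembles the full calibration/validation collection: reads the aging
#' dataset and every treatment dataset (identified by its `<label>.json`
#' sidecar) under `dir`, builds the hybrid dataset for each, and splits them
#' by the `role` recorded in the metadata.
#'
#' @param dir Directory containing `aging.csv`/`aging.json` and treatment
#'   dataset files.
#' @return List with `aging` (`osteo_aging`), `calibration` and
#'   `validation` (named lists of `osteo_hybrid`).
#' @export
load_study_collection <- function(dir) {
  aging <- read_aging_dataset(dir)
  sidecars <- list.files(dir, pattern = "\\.json$", full.names = FALSE)
  sidecars <- setdiff(sidecars, "aging.json")
  labels <- sub("\\.json$", "", sidecars)
  out <- list(aging = aging, calibration = list(), validation = list())
  for (lb in labels) {
    meta <- jsonlite::read_json(file.path(dir, paste0(lb, ".json")),
                                simplifyVector = TRUE)
    trt <- read_treatment_dataset(dir, lb)
    hyb <- build_hybrid(aging, trt)
    role <- if (identical(meta$role, "validation")) "validation" else
      "calibration"
    out[[role]][[lb]] <- hyb
  }
  out
}
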