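#' Supported drugs and their classes
#'
#' The five medications the simulator models, grouped in four mechanism
#' classes: RANKL antibody (denosumab), sclerostin antibodies (romosozumab,
#' blosozumab), bisphosphonate (alendronate) and PTH analog (teriparatide,
#' anabolic intermittent regime only).
#'
#' @return A tibble with columns `drug_id`, `drug_class`, `letter` (the
#'   single-letter label used for sequence experiments), `ka`, `ke` (names of
#'   the absorption/elimination rate parameters) and `bioavail` (name of the
#'   bioavailability parameter or `NA` for full availability).
#' @export
drug_specs <- function() {
  tibble::tibble(
    drug_id = c("denosumab", "romosozumab", "blosozumab", "teriparatide",
                "alendronate"),
    drug_class = c("rankl_antibody", "sclerostin_antibody",
                   "sclerostin_antibody", "pth_analog", "bisphosphonate"),
    letter = c("D", "R", "B", "T", "A"),
    ka = c("dmab_ka", "romo_ka", "blos_ka", "teri_ka", "aln_ka"),
    ke = c("dmab_ke", "romo_ke", "blos_ke", "teri_ke", "aln_ke"),
    bioavail = c(NA, NA, NA, NA, "aln_bioavail")
  )
}

drug_ids <- function() drug_specs()$drug_id

check_drug_id <- function(drug_id) {
  bad <- setdiff(drug_id, drug_ids())
  if (length(bad) > 0) {
    stop("unknown drug_id: ", paste(bad, collapse = ", "),
         " (known: ", paste(drug_ids(), collapse = ", "), ")", call. = FALSE)
  }
  invisible(drug_id)
}

#' Parse a duration string
#'
#' Durations in regimen descriptions accept the units `d` (days, 1/365 yr),
#' `w` (weeks, 1/52 yr), `mo` (months, 1/12 yr) and `yr` (years). A bare
#' number is taken as years.
#'
#' @param x Character vector like `"1w"`, `"6mo"`, `"70d"`, `"1yr"`, or
#'   numeric (years).
#' @return Duration(s) in years.
#' @examples
#' parse_duration(c("1w", "6mo", "1yr"))
#' @export
parse_duration <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^\\s*([0-9.]+)\\s*(d|w|mo|yr)?\\s*$", x))
  vapply(m, function(g) {
    if (length(g) == 0 || g[1] == "") {
      stop("cannot parse duration: expected e.g. '1w', '6mo', '1yr'",
           call. = FALSE)
    }
    val <- as.numeric(g[2])
    unit <- if (g[3] == "" || is.na(g[3])) "yr" else g[3]
    val * switch(unit, d = 1 / 365, w = 1 / 52, mo = 1 / 12, yr = 1)
  }, numeric(1))
}

#' Build a regimen from treatment blocks
#'
#' Expands a list of treatment blocks into a regimen: a time-sorted tibble of
#' bolus dose events. Each block administers one drug at a fixed dose and
#' dosing interval for a fixed duration; events are placed at the block start
#' and every interval thereafter, strictly before the block end, so e.g.
#' 70 mg weekly for one year yields 52 events. Blocks without an explicit
#' `start` run back-to-back after the previous block; an explicit `start`
#' allows parallel administration (overlaps are permitted and reported with
#' a message).
#'
#' @param blocks A data frame (or list of lists) with columns/fields
#'   `drug_id`, `dose` (mg per administration), `interval` and `duration`
#'   (numbers in years or strings like `"1w"`, `"6mo"`), and optionally
#'   `start` (age in years; `NA` means "after previous block").
#' @param start_age Age in years at which the first block starts.
#' @return An `osteo_regimen` tibble with columns `drug_id`, `time` (age,
#'   years), `dose` (mg) and `block` (label), carrying a `blocks` attribute
#'   with the block metadata (`label`, `drug_id`, `start`, `end`, `dose`,
#'   `interval`).
#' @examples
#' make_block_regimen(
#'   data.frame(drug_id = "denosumab", dose = 60,
#'              interval = "6mo", duration = "1yr"),
#'   start_age = 67
#' )
#' @export
make_block_regimen <- function(blocks, start_age = 67) {
  if (is.null(blocks) || (is.data.frame(blocks) && nrow(blocks) == 0) ||
      (is.list(blocks) && !is.data.frame(blocks) && length(blocks) == 0)) {
    return(empty_regimen())
  }
  if (!is.data.frame(blocks)) {
    blocks <- dplyr::bind_rows(lapply(blocks, tibble::as_tibble))
  }
  blocks <- tibble::as_tibble(blocks)
  stopifnot(all(c("drug_id", "dose", "interval", "duration") %in%
                  names(blocks)))
  check_drug_id(blocks$drug_id)
  if (!"start" %in% names(blocks)) blocks$start <- NA_real_
  if (!"label" %in% names(blocks)) blocks$label <- NA_character_
  interval <- parse_duration(blocks$interval)
  duration <- parse_duration(blocks$duration)
  if (any(interval <= 0) || any(duration <= 0)) {
    stop("block intervals and durations must be positive", call. = FALSE)
  }
  if (any(blocks$dose <= 0)) stop("doses must be positive", call. = FALSE)

  starts <- ends <- numeric(nrow(blocks))
  cursor <- start_age
  for (i in seq_len(nrow(blocks))) {
    starts[i] <- if (is.na(blocks$start[i])) cursor else blocks$start[i]
    ends[i] <- starts[i] + duration[i]
    cursor <- max(cursor, ends[i])
  }
  labels <- ifelse(is.na(blocks$label),
                   paste0(blocks$drug_id, "_", seq_len(nrow(blocks))),
                   blocks$label)
  if (nrow(blocks) > 1) {
    ord <- order(starts)
    overlap <- any(starts[ord][-1] < ends[ord][-length(ends)] - 1e-9)
    if (overlap) message("regimen blocks overlap: parallel administration")
  }

  events <- purrr::map_dfr(seq_len(nrow(blocks)), function(i) {
    n_doses <- ceiling(duration[i] / interval[i] - 1e-9)
    times <- starts[i] + (seq_len(n_doses) - 1) * interval[i]
    times <- times[times < ends[i] - 1e-9]
    tibble::tibble(drug_id = blocks$drug_id[i], time = times,
                   dose = blocks$dose[i], block = labels[i])
  })
  events <- dplyr::arrange(events, .data$time, .data$drug_id)
  meta <- tibble::tibble(label = labels, drug_id = blocks$drug_id,
                         start = starts, end = ends, dose = blocks$dose,
                         interval = interval)
  new_regimen(events, meta)
}

new_regimen <- function(events, blocks_meta) {
  stopifnot(all(c("drug_id", "time", "dose", "block") %in% names(events)))
  out <- tibble::as_tibble(events)
  attr(out, "blocks") <- blocks_meta
  class(out) <- c("osteo_regimen", class(out))
  out
}

#' An empty regimen (no treatment)
#' @return An `osteo_regimen` with zero dose events.
#' @export
empty_regimen <- function() {
  new_regimen(tibble::tibble(drug_id = character(), time = numeric(),
                             dose = numeric(), block = character()),
              tibble::tibble(label = character(), drug_id = character(),
                             start = numeric(), end = numeric(),
                             dose = numeric(), interval = numeric()))
}

#' Block metadata of a regimen
#' @param regimen An `osteo_regimen`.
#' @return The `blocks` attribute tibble (`label`, `drug_id`, `start`,
#'   `end`, `dose`, `interval`).
#' @export
regimen_blocks <- function(regimen) {
  attr(regimen, "blocks")
}

#' Treatment start and end of a regimen
#' @param regimen An `osteo_regimen`.
#' @return Numeric length-2 vector `c(start, end)` in years of age, or
#'   `c(NA, NA)` for an empty regimen.
#' @export
regimen_span <- function(regimen) {
  b <- regimen_blocks(regimen)
  if (is.null(b) || nrow(b) == 0) return(c(NA_real_, NA_real_))
  c(min(b$start), max(b$end))
}

#' Read and write regimen files
#'
#' Regimens are stored as structured text (YAML): a list of blocks with
#' fields `drug`, `dose_mg`, `every`, `for` and optional `start` (an age in
#' years or the string `"after previous"`). Durations accept units
#' d / w / mo / yr.
#'
#' @param path File path.
#' @param regimen An `osteo_regimen` (written as its block metadata).
#' @param start_age Used when the first block has no explicit start.
#' @return `read_regimen()`: an `osteo_regimen`; `write_regimen()`: `path`,
#'   invisibly.
#' @export
read_regimen <- function(path, start_age = 67) {
  spec <- yaml::read_yaml(path)
  blocks <- purrr::map_dfr(spec$blocks, function(b) {
    start <- b$start
    if (is.null(start) || identical(start, "after previous")) {
      start <- NA_real_
    }
    tibble::tibble(drug_id = b$drug, dose = b$dose_mg,
                   interval = as.character(b$every),
                   duration = as.character(b$`for`),
                   start = as.numeric(start),
                   label = b$label %||% NA_character_)
  })
  if (!is.null(spec$start_age)) start_age <- spec$start_age
  make_block_regimen(blocks, start_age = start_age)
}

#' @rdname read_regimen
#' @export
write_regimen <- function(regimen, path) {
  b <- regimen_blocks(regimen)
  spec <- list(blocks = purrr::map(seq_len(nrow(b)), function(i) {
    list(label = b$label[i], drug = b$drug_id[i], dose_mg = b$dose[i],
         every = b$interval[i], `for` = b$end[i] - b$start[i],
         start = b$start[i])
  }))
  yaml::write_yaml(spec, path, precision = 15)
  invisible(path)
}

#' @export
print.osteo_regimen <- function(x, ...) {
  b <- regimen_blocks(x)
  cat("<osteo_regimen> ", nrow(x), " dose events, ",
      if (is.null(b)) 0L else nrow(b), " blocks\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
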