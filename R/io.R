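#' Read / write an observed trial as long-format CSV
#'
#' The on-disk format is `subject_id,period,arm,outcome` with 1-based integer
#' periods, `arm` in {T, C} and an empty cell for a missing outcome. UTF-8,
#' comma-separated.
#'
#' @param path File path.
#' @return `read_trial_csv()` returns an `rrd_trial` tibble;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "rrd_io_error")
  }
  need <- c("subject_id", "period", "arm", "outcome")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header[seq_along(need)], need)) {
    rlang::abort("header must be subject_id,period,arm,outcome",
                 class = "rrd_parse_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      period = readr::col_integer(),
      arm = readr::col_character(),
      outcome = readr::col_double()
    )
  )
  bad <- which(!raw$arm %in% c("T", "C"))
  if (length(bad)) {
    rlang::abort(sprintf("malformed arm value '%s' on data line %d",
                         raw$arm[bad[1L]], bad[1L]),
                 class = "rrd_parse_error")
  }
  as_rrd_trial(raw)
}

#' @rdname read_trial_csv
#' @param trial An `rrd_trial` tibble.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "rrd_trial"))
  readr::write_csv(tibble::as_tibble(trial), path, na = "")
  invisible(path)
}

#' Write an allocation schedule as CSV
#'
#' Serializes to `subject_id,period,arm` with `arm` in {T, C}.
#'
#' @param schedule A [build_schedule()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "rrd_schedule"))
  tibble::as_tibble(schedule) |>
    dplyr::mutate(arm = ifelse(.data$treated == 1L, "T", "C")) |>
    dplyr::select("subject_id", "period", "arm") |>
    readr::write_csv(path)
  invisible(path)
}

#' Read / write survey responses as CSV
#'
#' Format: `respondent_id,q1,q2,q3,q4,q5` with `q1` in {A, B} and items
#' scored 1..5 (`q4`/`q5` on the administered reversed scale).
#'
#' @param path File path.
#' @return `read_survey_csv()` returns a validated tibble.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "rrd_io_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      q1 = readr::col_character(),
      .default = readr::col_integer()
    )
  )
  need <- c("respondent_id", "q1", "q2", "q3", "q4", "q5")
  if (!all(need %in% names(raw))) {
    rlang::abort("header must be respondent_id,q1,q2,q3,q4,q5",
                 class = "rrd_parse_error")
  }
  if (!all(raw$q1 %in% c("A", "B"))) {
    rlang::abort("q1 must be 'A' or 'B'", class = "rrd_parse_error")
  }
  for (q in c("q2", "q3", "q4", "q5")) {
    if (any(is.na(raw[[q]]) | raw[[q]] < 1 | raw[[q]] > 5)) {
      rlang::abort(sprintf("%s has scores outside 1..5", q),
                   class = "rrd_parse_error")
    }
  }
  raw
}

#' @rdname read_survey_csv
#' @param data A survey tibble.
#' @export
write_survey_csv <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}
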