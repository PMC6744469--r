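#' Read and write SpO2 traces and event annotations as CSV
#'
#' The record dialect is two columns, `time_s,spo2`, with empty cells for
#' invalid samples; the sampling rate is recovered from the median time step.
#' The annotation dialect is `kind,onset_s,duration_s` — the same dialect the
#' simulator emits and the detector writes, so detector output can be
#' round-tripped as an annotation.
#'
#' @param record An [spo2_record()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers return an
#'   [spo2_record()] or an annotation tibble.
#' @export
write_spo2_csv <- function(record, path) {
  stopifnot(inherits(record, "spo2_record"))
  readr::write_csv(spo2_tbl(record), path, na = "")
  invisible(path)
}

#' @rdname write_spo2_csv
#' @export
read_spo2_csv <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), spo2 = readr::col_double()
  ), na = c("", "NA"))
  dt <- median(diff(tb$time_s))
  spo2_record(tb$spo2, fs = 1 / dt)
}

#' @rdname write_spo2_csv
#' @param events Annotation tibble (`kind`, `onset_s`, `duration_s`).
#' @export
write_events_csv <- function(events, path) {
  events <- validate_annotation(events)
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_spo2_csv
#' @export
read_events_csv <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    kind = readr::col_character(),
    onset_s = readr::col_double(),
    duration_s = readr::col_double()
  ))
  validate_annotation(tb)
}

#' Write an epoch set as a columnar text file
#'
#' One header line, one row per epoch: `record_id`, `epoch_start_s`,
#' `valid`, optional targets, then the 300 saturation samples `s1..s300`.
#'
#' @param epoch_set An `epoch_set`.
#' @param path File path.
#' @param record_id Identifier stored with every row.
#' @return `path`, invisibly.
#' @export
write_epochs_csv <- function(epoch_set, path, record_id = "record") {
  stopifnot(inherits(epoch_set, "epoch_set"))
  tb <- tibble::tibble(
    record_id = record_id,
    epoch_start_s = epoch_set$epoch_start_s,
    valid = epoch_set$valid_mask
  )
  if (!is.null(epoch_set$target_ahi)) tb$target_ahi <- epoch_set$target_ahi
  if (!is.null(epoch_set$target_odi)) tb$target_odi <- epoch_set$target_odi
  mat <- tibble::as_tibble(epoch_set$epochs, .name_repair = "minimal")
  names(mat) <- sprintf("s%d", seq_len(ncol(mat)))
  readr::write_csv(dplyr::bind_cols(tb, mat), path)
  invisible(path)
}

write_manifest_json <- function(profiles, path, extra = list()) {
  doc <- c(list(schema = "oxinet-cohort/1",
                n = nrow(profiles),
                profiles = profiles),
           extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_manifest_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "oxinet-cohort/1")) {
    abort("Not an oxinet cohort manifest.")
  }
  profiles <- tibble::as_tibble(doc$profiles)
  profiles$severity <- factor(profiles$severity, levels = severity_levels(),
                              ordered = TRUE)
  doc$profiles <- profiles
  doc
}

#' Write an evaluation report to JSON, text and per-patient CSV
#'
#' @param evaluation An `osa_evaluation` from [evaluate_estimates()].
#' @param stem Output path stem; writes `<stem>.json`, `<stem>.txt` and
#'   `<stem>_patients.csv`.
#' @return The JSON path, invisibly.
#' @export
write_report <- function(evaluation, stem) {
  stopifnot(inherits(evaluation, "osa_evaluation"))
  conf <- evaluation$confusion
  doc <- list(
    schema = "oxinet-report/1",
    index = evaluation$index,
    errors = as.list(evaluation$errors),
    accuracy = evaluation$accuracy,
    n_misclassified = evaluation$n_misclassified,
    misclassified_errors = if (!is.null(evaluation$misclassified_errors)) {
      as.list(evaluation$misclassified_errors)
    },
    confusion = list(
      labels = rownames(conf),
      orientation = "rows = reference, columns = estimate",
      counts = unname(apply(conf, 1, as.integer, simplify = FALSE))
    ),
    icc = as.list(evaluation$icc)
  )
  jsonlite::write_json(doc, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  writeLines(format_evaluation_text(evaluation), paste0(stem, ".txt"))
  pat <- evaluation$estimates
  readr::write_csv(
    pat[, c("patient_id", "reference", "estimate", "ref_class", "est_class")],
    paste0(stem, "_patients.csv")
  )
  invisible(paste0(stem, ".json"))
}
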