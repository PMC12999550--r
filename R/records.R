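#' Observed subject records
#'
#' An observed record is one row per subject with the follow-up time actually
#' observed (`followup_time`, years), the event indicator (`event`, 1 = event,
#' 0 = censored), a left-truncation (delayed entry) time (`truncation_time`,
#' 0 means none), and the treatment arm (`"I"` intervention, `"C"` control).
#' A truncated subject enters the risk set alive, so its follow-up must
#' strictly exceed its truncation time.
#'
#' @param followup_time non-negative follow-up times in years.
#' @param event 0/1 event indicators.
#' @param truncation_time non-negative delayed-entry times (default 0).
#' @param arm character vector of `"I"`/`"C"` labels.
#' @param entry_time optional calendar enrollment times (kept for interim
#'   bookkeeping, not used by the estimators).
#' @param id optional subject identifiers.
#' @return A `data.frame` of observed records.
#' @export
observed_records <- function(followup_time, event, truncation_time = 0,
                             arm, entry_time = NA_real_, id = NULL) {
  n <- length(followup_time)
  truncation_time <- rep_len(truncation_time, n)
  entry_time <- rep_len(entry_time, n)
  if (is.null(id)) id <- seq_len(n)
  rec <- data.frame(
    id = id,
    entry_time = as.numeric(entry_time),
    followup_time = as.numeric(followup_time),
    event = as.integer(event),
    truncation_time = as.numeric(truncation_time),
    arm = as.character(arm),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
  rec
}

validate_records <- function(rec) {
  if (nrow(rec) == 0L) stop("no records")
  if (any(rec$followup_time < 0)) stop("negative follow-up time")
  if (!all(rec$event %in% c(0L, 1L))) stop("event must be 0/1")
  if (any(rec$truncation_time < 0)) stop("negative truncation time")
  bad <- rec$truncation_time > 0 & rec$followup_time <= rec$truncation_time
  if (any(bad)) stop("invalid truncation")
  if (!all(rec$arm %in% c("I", "C"))) stop("arm must be 'I' or 'C'")
  invisible(rec)
}

#' Stage-wise dataset container
#'
#' Bundles observed records for one analysis stage with the stage label and
#' the sample-size bookkeeping used by the combination test: `n1` (stage-1
#' accrual), `n2` (newly recruited stage-2 patients) and `n_pipeline`
#' (stage-1 patients whose follow-up continued past the interim analysis).
#'
#' @param records a data.frame of observed records (see [observed_records()]).
#' @param stage one of `"interim"`, `"stage1"`, `"stage2"`, `"all"`.
#' @param n1,n2,n_pipeline integer bookkeeping counts.
#' @return An object of class `stage_data`.
#' @export
stage_data <- function(records, stage = c("interim", "stage1", "stage2", "all"),
                       n1 = NA_integer_, n2 = NA_integer_,
                       n_pipeline = NA_integer_) {
  stage <- match.arg(stage)
  validate_records(records)
  structure(
    list(stage = stage, records = records,
         n1 = as.integer(n1), n2 = as.integer(n2),
         n_pipeline = as.integer(n_pipeline)),
    class = "stage_data"
  )
}

#' @export
print.stage_data <- function(x, ...) {
  cat(sprintf("Stage data [%s]: %d records (%d I / %d C), %d events\n",
              x$stage, nrow(x$records),
              sum(x$records$arm == "I"), sum(x$records$arm == "C"),
              sum(x$records$event)))
  if (!is.na(x$n_pipeline))
    cat(sprintf("  n1 = %d, n2 = %d, pipeline patients = %d\n",
                x$n1, x$n2, x$n_pipeline))
  invisible(x)
}

as_records <- function(data) {
  if (inherits(data, "stage_data")) data$records else data
}

#' Read and write subject-level files
#'
#' Subject-level data are exchanged as tab-delimited text with columns
#' `id`, `entry_time`, `followup_time`, `event`, `truncation_time`, `arm`
#' (times in years, `event` in 0/1, `arm` in I/C).
#'
#' @param path file path.
#' @return `read_subjects()` returns a validated records data.frame.
#' @export
read_subjects <- function(path) {
  rec <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  need <- c("id", "entry_time", "followup_time", "event",
            "truncation_time", "arm")
  miss <- setdiff(need, names(rec))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  rec$event <- as.integer(rec$event)
  validate_records(rec[, need])
}

#' @param records records data.frame to write.
#' @rdname read_subjects
#' @export
write_subjects <- function(records, path) {
  records <- as_records(records)
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value configuration file
#'
#' Scenario and design files are flat `key = value` (or `key: value`) text;
#' numeric values are converted, everything else is kept as character.
#'
#' @param path file path.
#' @return A named list.
#' @export
read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("malformed line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' @param x named list of scalar values to write.
#' @rdname read_keyvalue
#' @export
write_keyvalue <- function(x, path) {
  fmt <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  writeLines(paste(names(x), fmt, sep = " = "), path)
  invisible(path)
}
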