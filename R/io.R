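# Plain-text CSV dialect for recordings and label tables.
#
# A recording file is:
#   # fs=<Hz> channel=<BPW|PPG> subject=<id> session=<M0|M1>
#   time_s,amplitude
#   0.000,2.1034
#   ...

#' Write a pulse recording to CSV
#'
#' @param rec a `pulse_recording`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g channel=%s subject=%s session=%s",
                     rec$fs, rec$channel, rec$subject_id, rec$session), con)
  writeLines("time_s,amplitude", con)
  t <- (seq_along(rec$samples) - 1L) / rec$fs
  writeLines(sprintf("%.6f,%.8g", t, rec$samples), con)
  invisible(path)
}

#' Read a pulse recording from CSV
#'
#' @param path file written by [write_recording()] (or any two-column
#'   time/amplitude CSV with the `# fs=...` header line).
#' @return A `pulse_recording`.
#' @export
read_recording <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    abort_pv("pulsevar_invalid_parameter",
             "missing '# fs=... channel=...' header in %s", path)
  }
  get_field <- function(key, default = NA_character_) {
    m <- regmatches(header, regexec(paste0(key, "=([^ ]+)"), header))[[1]]
    if (length(m) == 2L) m[2] else default
  }
  fs <- as.numeric(get_field("fs"))
  if (!is.finite(fs)) {
    abort_pv("pulsevar_invalid_parameter", "header of %s lacks a numeric fs", path)
  }
  dat <- utils::read.csv(path, comment.char = "#")
  pulse_recording(dat$amplitude, fs,
                  channel = get_field("channel", "BPW"),
                  subject_id = get_field("subject", "S1"),
                  session = get_field("session", "M0"))
}

#' Write a cohort to a directory
#'
#' One `<subject>_<session>.csv` per recording plus `labels.csv`
#' (subject, group, cv_flag, subgroup_AB).
#'
#' @param cohort a `pulse_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort$recordings)) {
    write_recording(cohort$recordings[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing recording CSVs and `labels.csv`.
#' @return A `pulse_cohort` (without simulation ground truth).
#' @export
read_cohort <- function(dir) {
  labels <- utils::read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), "labels.csv")
  recordings <- lapply(file.path(dir, files), read_recording)
  names(recordings) <- sub("\\.csv$", "", files)
  structure(list(recordings = recordings, labels = labels),
            class = "pulse_cohort")
}
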