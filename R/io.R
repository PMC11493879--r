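#' Construct a waveform recording
#'
#' A recording is a uniformly sampled arterial pressure trace with patient
#' identity and timing metadata.  Admission to the analysis pipeline
#' additionally requires at least `min_duration_s` (default 180 s) of data;
#' that rule is enforced by [read_waveform()] and [select_segment()], not by
#' the constructor, so that synthetic fragments can be built freely in
#' tests.
#'
#' @param pressure numeric vector of pressures (mmHg).
#' @param sample_rate sampling rate in Hz (default 200).
#' @param patient_id opaque identifier.
#' @param start_offset time of the first sample (s).
#' @return An object of class `"bp_recording"`.
#' @export
bp_recording <- function(pressure, sample_rate = 200, patient_id = "anon",
                         start_offset = 0) {
  stopifnot(is.numeric(pressure), length(pressure) > 1, sample_rate > 0)
  if (anyNA(pressure) || any(!is.finite(pressure))) {
    stop("pressure contains non-finite values")
  }
  structure(
    list(patient_id = as.character(patient_id),
         sample_rate = as.numeric(sample_rate),
         pressure = as.numeric(pressure),
         start_offset = as.numeric(start_offset)),
    class = "bp_recording")
}

#' @export
print.bp_recording <- function(x, ...) {
  cat(sprintf("<bp_recording> %s: %.1f s at %g Hz, pressure %.0f-%.0f mmHg\n",
              x$patient_id, recording_duration(x), x$sample_rate,
              min(x$pressure), max(x$pressure)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a `bp_recording`.
#' @return Duration (s).
#' @export
recording_duration <- function(rec) length(rec$pressure) / rec$sample_rate

#' Read a waveform file
#'
#' Reads the canonical two-column waveform dialect: a CSV with header
#' `time_s,pressure_mmHg`, `.` decimal separator and LF line endings.  The
#' file must be uniformly sampled; nothing is resampled.
#'
#' @param path path to the waveform CSV.
#' @param expected_rate expected sampling rate (Hz); the observed rate may
#'   deviate by at most 0.5 percent.
#' @param min_duration_s admission rule: recordings shorter than this are
#'   rejected (default 180 s, i.e. the 3-minute minimum).
#' @param patient_id identifier to attach; defaults to the file stem.
#' @return A [bp_recording()].
#' @export
read_waveform <- function(path, expected_rate = 200, min_duration_s = 180,
                          patient_id = NULL) {
  if (!file.exists(path)) stop("waveform file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = ",")
  if (ncol(dt) != 2 || !identical(names(dt), c("time_s", "pressure_mmHg"))) {
    stop("malformed waveform file (expected header time_s,pressure_mmHg): ",
         path)
  }
  tm <- dt[[1]]; pr <- dt[[2]]
  if (!is.numeric(tm) || !is.numeric(pr) || anyNA(tm) || anyNA(pr)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tm))) |
                   !is.finite(suppressWarnings(as.numeric(pr))))[1]
    stop(sprintf("parse error in %s at data line %d", path,
                 if (is.na(bad)) 1L else bad))
  }
  dtm <- diff(tm)
  nonmono <- which(dtm <= 0)
  if (length(nonmono)) {
    stop(sprintf("parse error in %s at data line %d: timestamps not strictly increasing",
                 path, nonmono[1] + 1L))
  }
  step <- stats::median(dtm)
  if (any(abs(dtm - step) > 1e-6)) {
    stop("non-uniform sampling in ", path,
         " (spacing deviates by more than 1e-6 s)")
  }
  rate <- 1 / step
  if (abs(rate - expected_rate) / expected_rate > 0.005) {
    stop(sprintf("sample-rate mismatch in %s: observed %.3f Hz, expected %g Hz",
                 path, rate, expected_rate))
  }
  dur <- length(pr) / expected_rate
  if (dur < min_duration_s) {
    stop(sprintf(
      "recording %s is %.1f s long; admission requires at least %g s (3-minute rule)",
      path, dur, min_duration_s))
  }
  if (is.null(patient_id)) {
    patient_id <- sub("\\.[^.]*$", "", basename(path))
  }
  bp_recording(pr, sample_rate = expected_rate, patient_id = patient_id,
               start_offset = tm[1])
}

#' Write a waveform file
#'
#' Inverse of [read_waveform()]: writes the two-column CSV dialect.
#'
#' @param rec a [bp_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(rec, path) {
  stopifnot(inherits(rec, "bp_recording"))
  tm <- rec$start_offset + (seq_along(rec$pressure) - 1) / rec$sample_rate
  data.table::fwrite(
    data.table::data.table(time_s = round(tm, 6),
                           pressure_mmHg = round(rec$pressure, 6)),
    path, eol = "\n")
  invisible(path)
}

.valid_labels <- c("AoS", "noAoS")

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `patient_id, waveform_path, age, sex,
#' height_cm, weight_kg, label`.  Waveform paths are resolved relative to
#' the manifest's directory.  Labels must be `AoS` or `noAoS`; sex must be
#' `female` or `male`.
#'
#' @param path manifest path.
#' @param check_files verify that every referenced waveform file exists.
#' @return A `data.frame` with one row per patient, the resolved
#'   `waveform_path`, and a derived `bsa` column (Du Bois).
#' @export
read_cohort_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  need <- c("patient_id", "waveform_path", "age", "sex", "height_cm",
            "weight_kg", "label")
  df <- data.table::fread(path, colClasses = list(character = c(
    "patient_id", "waveform_path", "sex", "label")))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[need]
  if (nrow(df) == 0) {
    warning("empty cohort manifest: ", path)
    df$bsa <- numeric(0)
    return(df)
  }
  bad_lab <- setdiff(unique(df$label), .valid_labels)
  if (length(bad_lab)) {
    stop("unknown label token(s) ", paste(sQuote(bad_lab), collapse = ", "),
         "; allowed: ", paste(.valid_labels, collapse = ", "))
  }
  bad_sex <- setdiff(unique(df$sex), c("female", "male"))
  if (length(bad_sex)) {
    stop("unknown sex token(s) ", paste(sQuote(bad_sex), collapse = ", "),
         "; allowed: female, male")
  }
  if (any(df$age <= 0)) stop("manifest contains non-positive ages")
  df$waveform_path <- ifelse(
    grepl("^(/|[A-Za-z]:)", df$waveform_path), df$waveform_path,
    file.path(dirname(path), df$waveform_path))
  if (check_files) {
    miss <- df$waveform_path[!file.exists(df$waveform_path)]
    if (length(miss)) stop("missing waveform file(s): ",
                           paste(miss, collapse = ", "))
  }
  df$bsa <- bsa_du_bois(df$height_cm, df$weight_kg)
  df
}

#' Write a cohort manifest
#' @param meta data.frame with the manifest columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_manifest <- function(meta, path) {
  need <- c("patient_id", "waveform_path", "age", "sex", "height_cm",
            "weight_kg", "label")
  stopifnot(all(need %in% names(meta)))
  data.table::fwrite(meta[need], path, eol = "\n")
  invisible(path)
}

#' Write a per-recording feature table
#'
#' One row per recording: `patient_id`, `age`, `label`, then the 135
#' summary columns in the canonical order ([feature_column_names()]).
#' Values are written with 12 significant digits so that
#' `read_feature_table(write_feature_table(x))` round-trips exactly at that
#' representation.
#'
#' @param summaries list of [feature_summary()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(summaries, path) {
  if (length(summaries) == 0) {
    hdr <- c("patient_id", "age", "label", feature_column_names())
    writeLines(paste(hdr, collapse = ","), path)
    return(invisible(path))
  }
  cols <- feature_column_names()
  rows <- lapply(summaries, function(s) {
    stopifnot(inherits(s, "feature_summary"))
    if (!identical(names(s$values), cols)) {
      stop("schema error: summary for ", s$patient_id,
           " does not have the canonical 135 summary columns")
    }
    c(list(patient_id = s$patient_id, age = s$age, label = s$label),
      as.list(signif(s$values, 12)))
  })
  dt <- data.table::rbindlist(rows)
  data.table::fwrite(dt, path, eol = "\n", scipen = 50)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path feature-table path.
#' @return A list of [feature_summary()] objects (age-adjusted flag is
#'   taken from the writing convention: tables written by the pipeline hold
#'   age-adjusted values; see `adjusted`).
#' @param adjusted whether the stored values are age-adjusted.
#' @export
read_feature_table <- function(path, adjusted = TRUE) {
  df <- as.data.frame(data.table::fread(path, colClasses = list(
    character = c("patient_id", "label"))))
  cols <- feature_column_names()
  if (!identical(names(df), c("patient_id", "age", "label", cols))) {
    stop("schema error: ", path, " is not a canonical feature table")
  }
  lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, cols])
    names(v) <- cols
    feature_summary(values = v, patient_id = df$patient_id[i],
                    age = df$age[i], label = df$label[i],
                    age_adjusted = adjusted)
  })
}
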