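#' Reading and writing the pipeline's tabular formats
#'
#' Cohorts live on disk as one directory per participant holding UTF-8 CSV
#' tables with ISO-8601 local timestamps (no DST; the synthetic clock is
#' civil local time): `actigraphy.csv` (timestamp, blue, white, activity,
#' off_wrist), `temperature_<k>.csv` (timestamp, value, site, side),
#' `sleep.csv` (onset, offset, in_lab), `urine.csv` (start, end, volume,
#' concentration) and optionally `melatonin.csv` (timestamp, concentration).
#' Timestamps are converted to minutes since midnight of the earliest date in
#' the file set on loading; writing reverses the conversion, so a write/read
#' round trip reproduces all values.
#'
#' @name io_and_config
NULL

ISO_EPOCH <- "2026-01-05"  # day 0 used when serializing synthetic cohorts

minutes_to_iso <- function(t, epoch = ISO_EPOCH) {
  format(as.POSIXct(paste(epoch, "00:00:00"), tz = "UTC") + round(t * 60),
         "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

iso_to_minutes <- function(s, origin) {
  tt <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  bad <- which(is.na(tt) & !is.na(s))
  if (length(bad))
    stop("malformed timestamp at row ", bad[1], ": '", s[bad[1]], "'")
  as.numeric(difftime(tt, origin, units = "mins"))
}

sites_vocab <- c("shoulder", "sternum", "wrist", "thigh", "calf", "ankle",
                 "foot")

# write.csv prints doubles at 15 significant digits, which does not round-trip;
# serialize numeric columns at 17 digits so write/read reproduces values
# bit-exactly.
write_csv_exact <- function(df, path) {
  for (nm in names(df))
    if (is.double(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         sprintf("%.17g", df[[nm]]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# sort by timestamp and keep the last record of any duplicated timestamp
dedupe_sorted <- function(df, time_col, what) {
  df <- df[order(df[[time_col]]), , drop = FALSE]
  dup <- duplicated(df[[time_col]], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate timestamp(s) in ", what,
            ": last record kept")
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' Write a cohort to a directory of CSV tables
#'
#' @param cohort list of participant records (see [gen_cohort()])
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort) {
    pd <- file.path(dir, p$id)
    dir.create(pd, showWarnings = FALSE)
    act <- p$epochs
    act$timestamp <- minutes_to_iso(act$timestamp)
    write_csv_exact(act, file.path(pd, "actigraphy.csv"))
    for (k in seq_along(p$temperature)) {
      tp <- p$temperature[[k]]
      tp$timestamp <- minutes_to_iso(tp$timestamp)
      write_csv_exact(tp, file.path(pd, sprintf("temperature_%02d.csv", k)))
    }
    sl <- p$sleep
    sl$onset <- minutes_to_iso(sl$onset); sl$offset <- minutes_to_iso(sl$offset)
    write_csv_exact(sl, file.path(pd, "sleep.csv"))
    ur <- p$urine
    ur$start <- minutes_to_iso(ur$start); ur$end <- minutes_to_iso(ur$end)
    write_csv_exact(ur, file.path(pd, "urine.csv"))
    if (!is.null(p$melatonin)) {
      ml <- p$melatonin
      ml$timestamp <- minutes_to_iso(ml$timestamp)
      write_csv_exact(ml, file.path(pd, "melatonin.csv"))
    }
    meta <- list(id = p$id, schedule_type = p$schedule_type)
    if (!is.null(p$in_lab)) {
      meta$in_lab_start <- minutes_to_iso(p$in_lab$start)
      meta$in_lab_end <- minutes_to_iso(p$in_lab$end)
    }
    jsonlite::write_json(meta, file.path(pd, "meta.json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a cohort from a directory of CSV tables
#'
#' All series are loaded, sorted on timestamp and de-duplicated (last record
#' kept, with a warning); missing values are flagged, never dropped.
#' Malformed timestamps raise a parse error naming the row; site labels
#' outside the closed vocabulary raise a schema error.
#'
#' @param dir cohort directory (one subdirectory per participant)
#' @param config a [run_config()] (reserved for dialect options)
#' @return list of participant records
#' @export
read_cohort <- function(dir, config = run_config()) {
  pdirs <- list.dirs(dir, recursive = FALSE)
  if (length(pdirs) == 0) stop("no participant directories under ", dir)
  origin <- as.POSIXct(paste(ISO_EPOCH, "00:00:00"), tz = "UTC")
  cohort <- list()
  for (pd in pdirs) {
    rd <- function(f) utils::read.csv(file.path(pd, f),
                                      stringsAsFactors = FALSE)
    act <- rd("actigraphy.csv")
    act$timestamp <- iso_to_minutes(act$timestamp, origin)
    act <- dedupe_sorted(act, "timestamp", "actigraphy")
    act$off_wrist <- as.logical(act$off_wrist)
    tfiles <- sort(list.files(pd, "^temperature_.*\\.csv$"))
    temps <- lapply(tfiles, function(f) {
      tp <- rd(f)
      if (any(!tp$site %in% sites_vocab))
        stop("unknown site label in ", f, ": ",
             paste(unique(setdiff(tp$site, sites_vocab)), collapse = ", "))
      tp$timestamp <- iso_to_minutes(tp$timestamp, origin)
      dedupe_sorted(tp, "timestamp", f)
    })
    sl <- rd("sleep.csv")
    sl$onset <- iso_to_minutes(sl$onset, origin)
    sl$offset <- iso_to_minutes(sl$offset, origin)
    sl$in_lab <- as.logical(sl$in_lab)
    ur <- rd("urine.csv")
    ur$start <- iso_to_minutes(ur$start, origin)
    ur$end <- iso_to_minutes(ur$end, origin)
    mel <- if (file.exists(file.path(pd, "melatonin.csv"))) {
      ml <- rd("melatonin.csv")
      ml$timestamp <- iso_to_minutes(ml$timestamp, origin)
      dedupe_sorted(ml, "timestamp", "melatonin")
    } else NULL
    meta <- jsonlite::read_json(file.path(pd, "meta.json"))
    in_lab <- if (!is.null(meta$in_lab_start)) {
      data.frame(start = iso_to_minutes(meta$in_lab_start, origin),
                 end = iso_to_minutes(meta$in_lab_end, origin))
    } else NULL
    cohort[[meta$id]] <- structure(
      list(id = meta$id, true_acrophase = NA_real_,
           schedule_type = meta$schedule_type,
           sleep = sl, epochs = act, temperature = temps,
           melatonin = mel, urine = ur, in_lab = in_lab),
      class = "sim_participant")
  }
  cohort
}

#' Write per-participant phase estimates and the summary table
#'
#' @param estimates data.frame with one row per participant (id, measured,
#'   predicted, error_min, method)
#' @param summary one-row summary data.frame from [summarize_errors()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_results <- function(estimates, summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (NROW(estimates) == 0)
    warning("empty estimate set: writing header-only output")
  utils::write.csv(estimates, file.path(dir, "phase_estimates.csv"),
                   row.names = FALSE)
  utils::write.csv(summary, file.path(dir, "error_summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
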