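#' False-positive-rate reference lines
#'
#' Daily reference lines below which detections are treated as consistent
#' with detector false positives: the chorus line at 3% of the day's files
#' (4.32 files for a complete 144-file day, printed as 4.3) and the pulse
#' line at 575 pulses per day (the 1% pulse-FPR equivalent, carried as a
#' configured constant).
#'
#' @param n_files_per_day nominal complete-day file count
#' @param chorus_fpr chorus false positive rate
#' @param pulse_line_per_day pulses/day at the 1% pulse FPR
#' @return list with `chorus_line_files_per_day`, `pulse_line_per_day`,
#'   `n_files_per_day`, `chorus_fpr`
#' @export
fpr_reference <- function(n_files_per_day = 144, chorus_fpr = 0.03,
                          pulse_line_per_day = 575) {
  list(chorus_line_files_per_day = chorus_fpr * n_files_per_day,
       pulse_line_per_day = pulse_line_per_day,
       n_files_per_day = n_files_per_day, chorus_fpr = chorus_fpr)
}

#' Daily acoustic presence per site
#'
#' Aggregates per-file chorus decisions and pulse detections into the daily
#' presence series: counts and percentages of chorus-counted files per band,
#' pulse counts, and data-gap flags. Files are assigned to the UTC day
#' containing their start time; a complete day holds 144 ten-minute files.
#'
#' @param decisions data.frame from [decide_chorus()] plus a `date` column
#'   (or `file_date` mapping supplied via `calendar`)
#' @param pulses data.frame of pulse detections with `file_id` (may be empty)
#' @param calendar data.frame `file_id`, `date` (Date) mapping every file to
#'   its UTC day; days in `seq(min(date), max(date))` with no files are
#'   reported as gaps
#' @param site_id site label for the output
#' @return data.frame, one row per day x band: site_id, date, band, n_files,
#'   n_counted, pct, n_pulses, data_gap
#' @export
aggregate_daily <- function(decisions, pulses, calendar, site_id = "site") {
  if (anyDuplicated(calendar$file_id)) {
    stop("duplicate file ids in calendar: ",
         calendar$file_id[duplicated(calendar$file_id)][1])
  }
  calendar$date <- as.Date(calendar$date)
  all_days <- seq(min(calendar$date), max(calendar$date), by = "day")
  n_files_by_day <- table(factor(as.character(calendar$date),
                                 levels = as.character(all_days)))
  bands <- unique(decisions$band)
  day_of <- stats::setNames(calendar$date, calendar$file_id)
  out <- list()
  for (band in bands) {
    d <- decisions[decisions$band == band, , drop = FALSE]
    counted_day <- table(factor(as.character(day_of[d$file_id[d$counted]]),
                                levels = as.character(all_days)))
    for (i in seq_along(all_days)) {
      nf <- as.integer(n_files_by_day[i])
      nc <- as.integer(counted_day[i])
      out[[length(out) + 1L]] <- data.frame(
        site_id = site_id, date = all_days[i], band = band,
        n_files = nf, n_counted = nc,
        pct = if (nf > 0) 100 * nc / nf else NA_real_,
        data_gap = nf == 0, stringsAsFactors = FALSE)
    }
  }
  daily <- do.call(rbind, out)
  np_day <- if (nrow(pulses)) {
    table(factor(as.character(day_of[pulses$file_id]),
                 levels = as.character(all_days)))
  } else {
    table(factor(character(), levels = as.character(all_days)))
  }
  daily$n_pulses <- as.integer(np_day[as.character(daily$date)])
  daily
}

#' Three-day centred running mean
#'
#' The smoothing used for the daily presence timelines. Endpoints use the
#' two available neighbours; `NA`s (data gaps) break the window, so days
#' adjacent to a gap average only their observed neighbours, and gap days
#' stay `NA` rather than being interpolated.
#'
#' @param x numeric series indexed by consecutive days
#' @return smoothed series, same length
#' @export
running_mean3 <- function(x) {
  n <- length(x)
  if (n == 0) return(x)
  prev <- c(NA, x[-n]); nxt <- c(x[-1], NA)
  m <- cbind(prev, x, nxt)
  out <- rowMeans(m, na.rm = TRUE)
  out[is.na(x)] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

#' Flag isolated above-line days for manual review
#'
#' Operationalises the revision of "outlier days": a day is flagged when its
#' chorus-counted file count exceeds the 3% FPR line (or its pulse count
#' exceeds the 1% line) while both calendar neighbours are at or below the
#' line — a temporal exception, as opposed to a sustained presence period,
#' which is never flagged.
#'
#' @param daily data.frame from [aggregate_daily()] (one band at a time for
#'   chorus flags) ordered by date
#' @param refs a [fpr_reference()]
#' @param what `"chorus"` (uses `n_counted`) or `"pulses"` (uses `n_pulses`)
#' @return data.frame of flagged rows with a `reason` column
#' @export
flag_outlier_days <- function(daily, refs = fpr_reference(),
                              what = c("chorus", "pulses")) {
  what <- match.arg(what)
  daily <- daily[order(daily$date), , drop = FALSE]
  v <- if (what == "chorus") daily$n_counted else daily$n_pulses
  line <- if (what == "chorus") refs$chorus_line_files_per_day else refs$pulse_line_per_day
  above <- !is.na(v) & v > line
  prev <- c(FALSE, above[-length(above)])
  nxt <- c(above[-1], FALSE)
  flagged <- above & !prev & !nxt
  out <- daily[flagged, , drop = FALSE]
  if (nrow(out)) {
    out$reason <- sprintf("isolated %s exceedance (%d > %.2f/day)", what,
                          v[flagged], line)
  } else {
    out$reason <- character(0)
  }
  out
}

#' Site-level mean chorus SNR
#'
#' Mean of the per-file band SNR over counted (above-threshold) files per
#' band and site; files below the detection threshold (the 3% FPR operating
#' point) are neglected. Returns the undefined sentinel `NA` for site/band
#' combinations with no qualifying files.
#'
#' @param decisions data.frame from [decide_chorus()] with `site_id` and
#'   `snr_db` columns (join [chorus_metrics()] output as needed)
#' @return data.frame: site_id, band, n_files, mean_snr_db
#' @export
site_mean_snr <- function(decisions) {
  need <- c("site_id", "band", "snr_db", "counted")
  miss <- setdiff(need, names(decisions))
  if (length(miss)) stop("decisions missing columns: ", paste(miss, collapse = ", "))
  keys <- unique(decisions[, c("site_id", "band")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- decisions[decisions$site_id == keys$site_id[i] &
                   decisions$band == keys$band[i] & decisions$counted, ,
                   drop = FALSE]
    data.frame(site_id = keys$site_id[i], band = keys$band[i],
               n_files = nrow(d),
               mean_snr_db = if (nrow(d)) mean(d$snr_db) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
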