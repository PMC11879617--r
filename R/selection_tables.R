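#' Read and write selection tables
#'
#' Tab-separated selection tables in the dialect used by standard
#' bioacoustic viewers: columns `Selection`, `Begin Time (s)`,
#' `End Time (s)`, `Low Freq (Hz)`, `High Freq (Hz)` and an `Annotation`
#' column. Used for ground-truth exchange and for exporting detections so
#' they can be cross-checked visually.
#'
#' @param path file path
#' @return data.frame with columns `selection`, `begin_s`, `end_s`,
#'   `low_hz`, `high_hz`, `annotation`
#' @export
read_selection_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Begin Time (s)", "End Time (s)", "Low Freq (Hz)", "High Freq (Hz)")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("selection table missing columns: ",
                         paste(miss, collapse = ", "))
  data.frame(
    selection = if ("Selection" %in% names(df)) df$Selection else seq_len(nrow(df)),
    begin_s = df[["Begin Time (s)"]], end_s = df[["End Time (s)"]],
    low_hz = df[["Low Freq (Hz)"]], high_hz = df[["High Freq (Hz)"]],
    annotation = if ("Annotation" %in% names(df)) df$Annotation else "",
    stringsAsFactors = FALSE)
}

#' @rdname read_selection_table
#' @param selections data.frame as returned by [read_selection_table()]
#' @export
write_selection_table <- function(selections, path) {
  n <- length(selections$selection)
  out <- data.frame(
    Selection = selections$selection,
    View = rep("Spectrogram 1", n), Channel = rep(1L, n),
    check.names = FALSE, stringsAsFactors = FALSE)
  out[["Begin Time (s)"]] <- selections$begin_s
  out[["End Time (s)"]] <- selections$end_s
  out[["Low Freq (Hz)"]] <- selections$low_hz
  out[["High Freq (Hz)"]] <- selections$high_hz
  out[["Annotation"]] <- selections$annotation
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Scene truth records -> selection-table rows (one per synthesised signal)
truth_to_selections <- function(truth) {
  if (nrow(truth) == 0) {
    return(data.frame(selection = integer(), begin_s = numeric(),
                      end_s = numeric(), low_hz = numeric(),
                      high_hz = numeric(), annotation = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    selection = seq_len(nrow(truth)),
    begin_s = truth$t_begin_s, end_s = truth$t_end_s,
    low_hz = truth$f_low_hz, high_hz = truth$f_high_hz,
    annotation = paste0(truth$signal_type, ":", truth$file_id),
    stringsAsFactors = FALSE)
}
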