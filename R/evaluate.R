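#' Score detections against scene ground truth
#'
#' Two evaluation tasks mirror the reference protocol: `chorus_per_file`
#' scores chorus presence/absence per file and band; `pulse_timestamped`
#' matches individual detections to truth pulses greedily (nearest in time,
#' one-to-one) within a tolerance, so no truth event is ever double
#' counted. Unmatched detections are false positives; the pulse FPR is
#' expressed per 0.5 s analysis window.
#'
#' @param detections for pulses: data.frame with `file_id`, `t_begin_s`,
#'   `t_end_s`; for chorus: [decide_chorus()] output
#' @param truth scene truth from [render_scene()]
#' @param tolerance_s pulse matching tolerance on the onset time (`> 0`)
#' @param n_files,file_duration_s scene extent for rate denominators
#' @param band chorus band to score (chorus task)
#' @param task which task to score
#' @return list: task, tpr, fpr, n_true, n_detected, n_matched
#' @export
evaluate_detections <- function(detections, truth,
                                task = c("pulse_timestamped", "chorus_per_file"),
                                tolerance_s = 0.5, n_files = NULL,
                                file_duration_s = 600, band = "lfc") {
  task <- match.arg(task)
  if (tolerance_s <= 0) stop("tolerance must be positive")
  if (task == "chorus_per_file") {
    truth_type <- paste0(band, "_chorus")
    pos_files <- unique(truth$file_id[truth$signal_type == truth_type])
    dec <- detections[detections$band == band, , drop = FALSE]
    det_files <- unique(dec$file_id[dec$counted])
    all_files <- unique(dec$file_id)
    neg_files <- setdiff(all_files, pos_files)
    n_matched <- length(intersect(det_files, pos_files))
    fp <- length(intersect(det_files, neg_files))
    return(list(task = task,
                tpr = if (length(pos_files)) n_matched / length(pos_files) else NA_real_,
                fpr = if (length(neg_files)) fp / length(neg_files) else NA_real_,
                n_true = length(pos_files), n_detected = length(det_files),
                n_matched = n_matched))
  }
  tp_truth <- truth[truth$signal_type == "pulse", , drop = FALSE]
  n_true <- nrow(tp_truth)
  n_det <- nrow(detections)
  n_matched <- 0L
  for (fid in unique(c(tp_truth$file_id, detections$file_id))) {
    tt <- tp_truth$t_begin_s[tp_truth$file_id == fid]
    dd <- detections$t_begin_s[detections$file_id == fid]
    if (!length(tt) || !length(dd)) next
    # greedy nearest-in-time one-to-one matching
    pairs <- expand.grid(ti = seq_along(tt), di = seq_along(dd))
    pairs$dt <- abs(tt[pairs$ti] - dd[pairs$di])
    pairs <- pairs[pairs$dt <= tolerance_s, , drop = FALSE]
    pairs <- pairs[order(pairs$dt), , drop = FALSE]
    used_t <- logical(length(tt)); used_d <- logical(length(dd))
    for (k in seq_len(nrow(pairs))) {
      ti <- pairs$ti[k]; di <- pairs$di[k]
      if (!used_t[ti] && !used_d[di]) {
        used_t[ti] <- TRUE; used_d[di] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  fp <- n_det - n_matched
  if (is.null(n_files)) n_files <- length(unique(truth$file_id))
  n_windows <- max(1, n_files) * file_duration_s / 0.5
  list(task = task,
       tpr = if (n_true) n_matched / n_true else NA_real_,
       fpr = fp / n_windows,
       n_true = n_true, n_detected = n_det, n_matched = n_matched)
}
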