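## Recording I/O: plain-text, diff-able, lossless.
##
## A recording <stem> is three files:
##   <stem>.eeg.tsv    samples x channels matrix, header row of channel names
##   <stem>.events.tsv event sidecar (onset_sample, key_id, round, trial, is_target)
##   <stem>.meta.json  sampling rate, epoch length, per-trial targets

#' Write an EEG recording to plain-text files
#'
#' @param rec an [eeg_recording()].
#' @param stem path stem; three files `<stem>.eeg.tsv`, `<stem>.events.tsv`,
#'   `<stem>.meta.json` are written.
#' @return `stem`, invisibly.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, stem) {
  if (!inherits(rec, "eeg_recording")) stop_config("rec must be an eeg_recording")
  # %.17g round-trips IEEE doubles exactly; fwrite's 15 digits would not
  chr <- matrix(sprintf("%.17g", t(rec$data)), ncol(rec$data), nrow(rec$data))
  mat <- data.table::as.data.table(chr)
  data.table::setnames(mat, rec$channel_names)
  data.table::fwrite(mat, paste0(stem, ".eeg.tsv"), sep = "\t", quote = FALSE)
  ev <- rec$events
  if (!"is_target" %in% names(ev)) ev$is_target <- rep(NA, nrow(ev))
  data.table::fwrite(ev, paste0(stem, ".events.tsv"), sep = "\t")
  jsonlite::write_json(
    list(fs = rec$fs, t_epoch = rec$t_epoch, targets = rec$targets),
    paste0(stem, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read an EEG recording written by [write_recording()]
#'
#' Round-trips the signal matrix and events losslessly. Malformed sidecars
#' raise a parse error naming the offending line and field.
#'
#' @param stem path stem used at write time.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(stem) {
  eeg_path <- paste0(stem, ".eeg.tsv")
  ev_path <- paste0(stem, ".events.tsv")
  meta_path <- paste0(stem, ".meta.json")
  for (p in c(eeg_path, ev_path, meta_path)) {
    if (!file.exists(p)) stop_parse("missing file: ", p)
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  mat <- tryCatch(suppressWarnings(data.table::fread(eeg_path, sep = "\t")),
                  error = function(e) stop_parse(eeg_path, ": ", conditionMessage(e)))
  data <- t(as.matrix(mat))
  storage.mode(data) <- "double"
  ev <- tryCatch(suppressWarnings(data.table::fread(ev_path, sep = "\t")),
                 error = function(e) stop_parse(ev_path, ": ", conditionMessage(e)))
  n_lines <- length(readLines(ev_path, warn = FALSE))
  if (nrow(ev) != n_lines - 1L) {
    stop_parse(ev_path, ": line ", n_lines,
               " is truncated or malformed (parsed ", nrow(ev), " of ",
               n_lines - 1L, " event rows)")
  }
  need <- c("onset_sample", "key_id", "round", "trial")
  missing_cols <- setdiff(need, names(ev))
  if (length(missing_cols)) {
    stop_parse(ev_path, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  for (col in need) {
    bad <- which(!is.finite(as.numeric(ev[[col]])))
    if (length(bad)) {
      stop_parse(ev_path, ": line ", bad[1] + 1L, ", field '", col,
                 "' is not a finite number")
    }
  }
  ev <- as.data.frame(ev)
  ev$is_target <- NULL  # recomputed from targets by the constructor
  eeg_recording(data, meta$fs, ev, targets = meta$targets %||% integer(),
                t_epoch = meta$t_epoch)
}
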