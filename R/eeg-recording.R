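# Minimal container for multi-channel EEG: a channels-by-samples matrix with
# labels, sampling rate, and session metadata.

#' Construct an EEG recording
#'
#' @param data Channels-by-samples numeric matrix (microvolts). Row names,
#'   if present, must match `labels`.
#' @param rate Sampling rate in Hz.
#' @param labels Ordered channel names (unique).
#' @param eog_label Name of the electrooculogram channel (must be present).
#' @param participant_id Participant identifier.
#' @param session Session number (1 or 2).
#' @param reference Reference scheme the data are in, `"FCz"` (online) or
#'   `"common_average"`.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, rate, labels = rownames(data),
                          eog_label = "EOG", participant_id = NA_character_,
                          session = 1L, reference = "FCz") {
  stopifnot(is.matrix(data), rate > 0)
  if (is.null(labels)) stop("channel labels are required", call. = FALSE)
  if (anyDuplicated(labels)) stop("channel labels must be unique", call. = FALSE)
  if (length(labels) != nrow(data))
    stop("length(labels) must equal nrow(data)", call. = FALSE)
  if (!eog_label %in% labels)
    stop("EOG channel '", eog_label, "' not among labels", call. = FALSE)
  reference <- match.arg(reference, c("FCz", "common_average"))
  rownames(data) <- labels
  structure(
    list(data = data, rate = rate, labels = labels, eog_label = eog_label,
         participant_id = participant_id, session = as.integer(session),
         reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording: %d channels x %d samples at %g Hz (%.1f s), session %d, ref %s>\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate, x$session,
    x$reference))
  invisible(x)
}
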