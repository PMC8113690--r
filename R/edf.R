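# Minimal European Data Format (EDF) writer/reader for interchange of the
# synthetic recordings. Implements the 16-bit integer EDF core (fixed-field
# ASCII header, 1-s data records); no installed R package provides EDF I/O.

edf_pad <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Stores the channels as 16-bit integers scaled per channel to the data's
#' physical range, in 1-second data records. A trailing partial second is
#' dropped. A JSON sidecar with the non-signal metadata (participant,
#' session, reference, EOG label) is written next to the file.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path (`.edf`); the sidecar gets the extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  spr <- round(rec$rate)                # samples per record (1-s records)
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF record", call. = FALSE)
  dat <- rec$data[, seq_len(n_rec * spr), drop = FALSE]

  pmin_ <- apply(dat, 1, min); pmax_ <- apply(dat, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),             # local patient id (anonymous)
    edf_pad("Startdate X X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad("1", 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width),
                     collapse = ""), con, eos = NULL)
  field(rec$labels, 16)
  field(rep("", ns), 80)                # transducer
  field(rep("uV", ns), 8)
  field(formatC(pmin_, digits = 6, format = "g"), 8)
  field(formatC(pmax_, digits = 6, format = "g"), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                # prefiltering
  field(rep(spr, ns), 8)
  field(rep("", ns), 32)

  # re-read the stored (truncated) physical limits so the round trip is exact
  pmin_s <- as.numeric(formatC(pmin_, digits = 6, format = "g"))
  pmax_s <- as.numeric(formatC(pmax_, digits = 6, format = "g"))
  gain <- (dmax - dmin) / (pmax_s - pmin_s)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    block <- round((dat[, cols, drop = FALSE] - pmin_s) * gain + dmin)
    block <- pmin(pmax(block, dmin), dmax)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  meta <- list(labels = rec$labels, rate = rec$rate,
               eog_label = rec$eog_label, participant_id = rec$participant_id,
               session = rec$session, reference = rec$reference)
  jsonlite::write_json(meta, sub("\\.edf$", ".json", path),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a 16-bit EDF file written by [write_edf()] (or any EDF with a
#' uniform sampling rate across signals). If the JSON sidecar is present
#' its metadata (EOG label, participant, session, reference) is restored.
#'
#' @param path Path to the `.edf` file.
#' @return An `eeg_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0")
    stop("malformed EDF file (bad version field): ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  n_hdr <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (any(is.na(c(n_hdr, n_rec, dur, ns))) || ns < 1)
    stop("malformed EDF header: ", path, call. = FALSE)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8)); rdv(32)
  if (length(unique(spr)) != 1)
    stop("EDF with heterogeneous sampling rates is not supported: ", path,
         call. = FALSE)
  spr1 <- spr[1]
  raw_ <- readBin(con, integer(), n = ns * spr1 * n_rec, size = 2,
                  signed = TRUE, endian = "little")
  if (length(raw_) < ns * spr1 * n_rec)
    stop("malformed EDF file (truncated data): ", path, call. = FALSE)
  data <- matrix(0, nrow = ns, ncol = spr1 * n_rec)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    off <- (r - 1) * ns * spr1
    block <- matrix(raw_[(off + 1):(off + ns * spr1)], nrow = spr1)
    data[, ((r - 1) * spr1 + 1):(r * spr1)] <-
      t(block) * gain + (pmin_ - dmin * gain)
  }
  rownames(data) <- labels
  side <- sub("\\.edf$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  eog <- meta$eog_label %||% (if ("EOG" %in% labels) "EOG" else
    stop("no EOG channel label in ", path,
         "; provide the JSON sidecar or name a channel 'EOG'",
         call. = FALSE))
  eeg_recording(data, rate = spr1 / dur, labels = labels, eog_label = eog,
                participant_id = meta$participant_id %||% NA_character_,
                session = meta$session %||% 1L,
                reference = meta$reference %||% "FCz")
}
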