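#' Read an EEG segment from EDF or CSV
#'
#' CSV files are samples x channels with a header of channel labels and a JSON
#' sidecar (`<file>.json`) holding the sampling rate, as written by
#' [write_eeg_csv()]. EDF files are standard 16-bit European Data Format, as
#' written by [write_eeg_edf()]. Labels are normalised to upper case.
#'
#' @param path file path.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @return An [eeg_segment()] in microvolts.
#' @export
read_eeg <- function(path, format = c("auto", "edf", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") read_eeg_csv(path) else read_eeg_edf(path)
}

#' Write an EEG segment to CSV (with a JSON sidecar)
#'
#' Samples are written row-wise with 17 significant digits, so the numeric
#' round trip through [read_eeg()] is bit-exact. The sampling rate and band
#' tag go to `<path>.json`.
#'
#' @param seg an [eeg_segment()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(seg, path) {
  stopifnot(inherits(seg, "eeg_segment"))
  m <- t(seg$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(seg$channel_labels, collapse = ","), con)
  body <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(body, con)
  jsonlite::write_json(list(sample_rate = seg$sample_rate, band = seg$band,
                            unit = "uV"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_eeg_csv <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop(sprintf("missing sampling-rate sidecar: %s", sidecar))
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sample_rate)) stop("sidecar does not name sample_rate")
  tab <- utils::read.csv(path, check.names = FALSE)
  data <- t(as.matrix(tab))
  check_read_values(data)
  eeg_segment(data, meta$sample_rate, colnames(tab),
              band = if (is.null(meta$band)) "raw" else meta$band)
}

check_read_values <- function(data) {
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite sample in channel %d at sample %d",
                 bad[1L], bad[2L]))
  }
  invisible(TRUE)
}

# ---- Minimal EDF (16-bit, continuous) writer / reader -----------------------
# Fixed-format header: 256 bytes global + 256 bytes per signal; data records
# of sample_rate samples per signal, little-endian int16 scaled between the
# per-signal physical min/max.

edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                      flag = "-")

# Format a number into at most `width` ASCII chars (EDF numeric fields).
edf_num <- function(x, width = 8L) {
  for (d in seq(7L, 1L)) {
    s <- sprintf("%.*g", d, x)
    if (nchar(s) <= width) return(s)
  }
  stop("cannot format numeric EDF field")
}

#' Write an EEG segment to EDF
#'
#' Standard 16-bit EDF with one data record per second and physical units of
#' microvolts. Quantization error is at most one step of the 16-bit scaling
#' between the recorded physical minimum and maximum.
#'
#' @param seg an [eeg_segment()]; `sample_rate` must be a whole number and the
#'   duration a whole number of seconds.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(seg, path) {
  stopifnot(inherits(seg, "eeg_segment"))
  fs <- seg$sample_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(seg$data)
  n_rec <- ncol(seg$data) / fs
  if (abs(n_rec - round(n_rec)) > 1e-9)
    stop("EDF export needs a whole number of 1-s records")
  n_rec <- as.integer(round(n_rec))
  pmin <- apply(seg$data, 1L, min)
  pmax <- apply(seg$data, 1L, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  # scale against the values as they appear in the header, so the round trip
  # is bounded by one quantization step
  pmin_str <- vapply(pmin, edf_num, "")
  pmax_str <- vapply(pmax, edf_num, "")
  pmin <- as.numeric(pmin_str)
  pmax <- as.numeric(pmax_str)
  pmax[pmax - pmin < 1e-12] <- pmin[pmax - pmin < 1e-12] + 1
  dmin <- -32768
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
                "01.01.00", "00.00.00",
                edf_pad(256 * (ns + 1L), 8), edf_pad("", 44),
                edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(seg$channel_labels, 16)         # label
  field(rep("", ns), 80)                # transducer
  field(rep("uV", ns), 8)               # physical dimension
  field(pmin_str, 8)
  field(pmax_str, 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                # prefiltering
  field(rep(fs, ns), 8)                 # samples per record
  field(rep("", ns), 32)                # reserved
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (s in seq_len(ns)) {
      dig <- round((seg$data[s, idx] - pmin[s]) / scale[s]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

read_eeg_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("unreadable EDF header")
  sig <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- sig(16); sig(80); sig(8)
  pmin <- as.numeric(sig(8)); pmax <- as.numeric(sig(8))
  dmin <- as.numeric(sig(8)); dmax <- as.numeric(sig(8))
  sig(80)
  spr <- as.integer(sig(8))
  sig(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate only")
  fs <- spr[1L] / rec_dur
  if (!is.finite(fs) || fs <= 0) stop("EDF header does not yield a sampling rate")
  if (anyDuplicated(toupper(labels))) stop("duplicate channel labels in EDF")
  data <- matrix(0, ns, n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      phys <- pmin[s] + (dig - dmin[s]) * (pmax[s] - pmin[s]) /
        (dmax[s] - dmin[s])
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <- phys
    }
  }
  check_read_values(data)
  eeg_segment(data, fs, labels, band = "raw")
}
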