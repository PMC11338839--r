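# Minimal EDF/EDF+ I/O: 16-bit little-endian data records, fixed-width ASCII
# header, optional "EDF Annotations" signal carrying TALs. Covers continuous
# (EDF+C) single- or multi-signal files; no discontinuous (EDF+D) support.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

edf_num <- function(x, width) {
  s <- format(x, trim = TRUE, scientific = FALSE, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_field(s, width)
}

#' Read an EDF/EDF+ file
#'
#' Parses the fixed-width header, decodes every ordinary signal to physical
#' units (microvolts for EEG channels), and extracts EDF+ timestamped
#' annotations when an "EDF Annotations" signal is present.
#'
#' @param path Path to an `.edf` file.
#' @return A list with `signals` (named list; each has `samples`, `fs`,
#'   `label`), `annotations` (data.frame with `onset`, `duration`, `label`,
#'   or NULL), and `header` fields.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  version <- trimws(rd(8)); patient <- trimws(rd(80)); recid <- trimws(rd(80))
  startdate <- trimws(rd(8)); starttime <- trimws(rd(8))
  header_bytes <- as.integer(rd(8)); reserved <- trimws(rd(44))
  n_records <- as.integer(rd(8)); record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header")
  fld <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- trimws(fld(16)); transducer <- fld(80); phys_dim <- trimws(fld(8))
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80); spr <- as.integer(fld(8)); rd(32 * ns)

  per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = n_records * per_rec, size = 2,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_records * per_rec)
    stop("EDF data truncated: expected ", n_records * per_rec,
         " samples, got ", length(raw))
  offsets <- c(0, cumsum(spr))
  is_ann <- labels == "EDF Annotations"
  signals <- list(); ann_raw <- raw(0)
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(offsets[i] + seq_len(spr[i]), (seq_len(n_records) - 1) * per_rec, `+`))
    dig <- raw[idx]
    if (is_ann[i]) {
      b <- writeBin(as.integer(dig), raw(), size = 2, endian = "little")
      ann_raw <- c(ann_raw, b)
      next
    }
    gain <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    phys <- phys_min[i] + (dig - dig_min[i]) * gain
    signals[[labels[i]]] <- list(samples = phys, fs = spr[i] / record_dur,
                                 label = labels[i], phys_dim = phys_dim[i])
  }
  annotations <- if (length(ann_raw)) parse_edf_tals(ann_raw) else NULL
  list(signals = signals, annotations = annotations,
       header = list(version = version, patient = patient, recording = recid,
                     startdate = startdate, starttime = starttime,
                     reserved = reserved, n_records = n_records,
                     record_duration = record_dur))
}

# TAL stream: "+onset[\x15duration]\x14label\x14...\x14\x00"; empty-label TALs
# are record keep-alive timestamps and are dropped.
parse_edf_tals <- function(bytes) {
  nul <- which(bytes == as.raw(0))
  starts <- c(1L, nul + 1L); ends <- c(nul - 1L, length(bytes))
  chunks <- character(0)
  for (k in seq_along(starts))
    if (starts[k] <= ends[k])
      chunks <- c(chunks, rawToChar(bytes[starts[k]:ends[k]]))
  out <- list()
  for (tal in chunks) {
    if (!nzchar(tal)) next
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    head_parts <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(head_parts[1]))
    dur <- if (length(head_parts) > 1L) suppressWarnings(as.numeric(head_parts[2])) else 0
    labs <- parts[-1]
    labs <- labs[nzchar(labs)]
    for (lab in labs)
      out[[length(out) + 1L]] <- data.frame(onset = onset, duration = dur,
                                            label = lab, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

select_edf_signal <- function(edf, channel) {
  sigs <- edf$signals
  if (!length(sigs)) stop("EDF file has no data signals")
  if (is.character(channel)) {
    if (!channel %in% names(sigs))
      stop("channel '", channel, "' not found; available: ",
           paste(names(sigs), collapse = ", "))
    return(sigs[[channel]])
  }
  channel <- as.integer(channel)
  if (channel < 1L || channel > length(sigs))
    stop("channel index out of range (file has ", length(sigs), " signals)")
  sigs[[channel]]
}

#' Write a recording to EDF (EDF+C when annotations are given)
#'
#' One data signal quantized to 16 bits over its observed physical range;
#' the recording's test window is stored as `test_start` / `test_end`
#' annotations when `annotations = TRUE`. Recordings are padded with zeros
#' to a whole number of 1 s data records.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path.
#' @param label Signal label (default "EEG Fp1").
#' @param annotations If TRUE, write an EDF+ annotations signal carrying the
#'   test window.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, label = "EEG Fp1", annotations = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- rec$samples
  n_records <- as.integer(ceiling(length(x) / fs))
  x <- c(x, numeric(n_records * fs - length(x)))
  pmin_ <- min(x); pmax_ <- max(x)
  if (pmax_ - pmin_ < 1e-12) pmax_ <- pmin_ + 1
  dmin <- -32768L; dmax <- 32767L
  dig <- as.integer(round(dmin + (x - pmin_) * (dmax - dmin) / (pmax_ - pmin_)))

  ann_spr <- 32L  # 64 bytes per record for TALs
  ns <- if (annotations) 2L else 1L
  header_bytes <- 256L + 256L * ns

  con <- file(path, "wb")
  on.exit(close(con))
  wch <- function(s) writeChar(s, con, nchar(s, type = "bytes"), eos = NULL)
  wch(edf_field("0", 8)); wch(edf_field("X X X X", 80)); wch(edf_field("Startdate X X X X", 80))
  wch(edf_field("01.01.00", 8)); wch(edf_field("00.00.00", 8))
  wch(edf_num(header_bytes, 8))
  wch(edf_field(if (annotations) "EDF+C" else "", 44))
  wch(edf_num(n_records, 8)); wch(edf_num(1, 8)); wch(edf_num(ns, 4))

  labs <- c(label, if (annotations) "EDF Annotations")
  for (l in labs) wch(edf_field(l, 16))
  for (l in labs) wch(edf_field("", 80))
  wch(edf_field("uV", 8)); if (annotations) wch(edf_field("", 8))
  pm <- function(v) wch(edf_num(signif(v, 7), 8))
  pm(pmin_); if (annotations) pm(-1)
  pm(pmax_); if (annotations) pm(1)
  wch(edf_num(dmin, 8)); if (annotations) wch(edf_num(dmin, 8))
  wch(edf_num(dmax, 8)); if (annotations) wch(edf_num(dmax, 8))
  for (l in labs) wch(edf_field("", 80))
  wch(edf_num(fs, 8)); if (annotations) wch(edf_num(ann_spr, 8))
  for (l in labs) wch(edf_field("", 32))

  tal_bytes <- function(rec_i) {
    b <- c(charToRaw(sprintf("+%d\x14\x14", rec_i - 1L)), as.raw(0))
    if (rec_i == 1L) {
      tw <- rec$test_window
      for (tal in c(sprintf("+%s\x14test_start\x14", format(tw[1], scientific = FALSE)),
                    sprintf("+%s\x14test_end\x14", format(tw[2], scientific = FALSE))))
        b <- c(b, charToRaw(tal), as.raw(0))
    }
    if (length(b) > 2L * ann_spr) stop("annotation block overflow")
    c(b, raw(2L * ann_spr - length(b)))
  }
  for (r in seq_len(n_records)) {
    writeBin(dig[((r - 1L) * fs + 1L):(r * fs)], con, size = 2, endian = "little")
    if (annotations) writeBin(tal_bytes(r), con)
  }
  invisible(path)
}

# Quantization step of the EDF encoding for a recording (round-trip error bound).
edf_quantization_step <- function(rec) {
  rng <- range(rec$samples)
  max(diff(rng), 1e-12) / 65535
}
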