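## Minimal EDF (European Data Format) codec.
##
## Implements the 16-bit EDF layout directly: a 256-byte fixed header,
## 256 bytes of per-signal header fields, and data records of little-endian
## two's-complement samples with linear physical/digital scaling. Only the
## subset needed for multichannel EEG matrices is supported: equal sampling
## rate across signals, no annotations, no discontinuous records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "fg", width = 1, digits = 8)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

write_edf <- function(rec, path) {
  data <- rec$data
  ns <- nrow(data)
  n_samp <- ncol(data)
  # one data record holding the full signal keeps the layout trivial
  dur <- n_samp / rec$fs
  pmin <- apply(data, 1, min); pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),                     # version
    edf_pad("X X X X", 80),              # patient id
    edf_pad("Startdate X X X X", 80),    # recording id
    edf_pad("01.01.00", 8),              # start date
    edf_pad("00.00.00", 8),              # start time
    edf_pad(256 + ns * 256, 8),          # header bytes
    edf_pad("", 44),                     # reserved
    edf_pad(1, 8),                       # number of data records
    edf_num(dur, 8),                     # record duration (s)
    edf_pad(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, character(1), width = width),
                    collapse = ""),
              con, eos = NULL)
  }
  nfield <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_num, character(1), width = width),
                    collapse = ""),
              con, eos = NULL)
  }
  field(rec$channel_labels, 16)          # label
  field(rep("", ns), 80)                 # transducer
  field(rep("uV", ns), 8)                # physical dimension
  nfield(pmin, 8); nfield(pmax, 8)       # physical min/max
  nfield(rep(dmin, ns), 8); nfield(rep(dmax, ns), 8)
  field(rep("", ns), 80)                 # prefiltering
  nfield(rep(n_samp, ns), 8)             # samples per record
  field(rep("", ns), 32)                 # reserved

  scale <- (dmax - dmin) / (pmax - pmin)
  for (i in seq_len(ns)) {
    dig <- round((data[i, ] - pmin[i]) * scale[i] + dmin)
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    if (length(s) == 0) stop_tinnpac("truncated EDF header: ", path)
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header byte count (recomputed)
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop_tinnpac("EDF parse error (signal count): ", path)
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  nsamp <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(round(nsamp / dur, 6))) != 1) {
    stop_tinnpac("EDF signals with differing sampling rates are not supported: ",
                 path)
  }
  fs <- nsamp[1] / dur
  data <- matrix(0, ns, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(dig) != nsamp[i]) stop_tinnpac("truncated EDF data: ", path)
      phys <- (dig - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) + pmin[i]
      data[i, (r - 1) * nsamp[i] + seq_len(nsamp[i])] <- phys
    }
  }
  recording(data, fs = fs, channel_labels = labels)
}
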