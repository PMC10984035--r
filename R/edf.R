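# Minimal EDF (European Data Format) codec: 256-byte fixed header,
# 256 bytes per signal, 16-bit little-endian samples, one data record per
# second. Covers exactly what the telemetry export needs; not a general
# EDF+ implementation (no annotations, no discontinuous records).

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = 1)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  .edf_pad(s, width)
}

# channels: list of list(label, unit, data, samples_per_record)
.edf_write <- function(path, channels, start_time, n_records,
                       patient = "X", recording = "X") {
  con <- file(path, "wb")
  on.exit(close(con))
  ns <- length(channels)
  st <- as.POSIXlt(start_time, tz = "UTC")
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(patient, 80),
    .edf_pad(recording, 80),
    .edf_pad(format(st, "%d.%m.%y"), 8),
    .edf_pad(format(st, "%H.%M.%S"), 8),
    .edf_pad(256L * (ns + 1L), 8),
    .edf_pad("", 44),
    .edf_pad(n_records, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)

  phys_min <- phys_max <- numeric(ns)
  for (i in seq_len(ns)) {
    rng <- max(abs(channels[[i]]$data), 1e-9)
    phys_max[i] <- rng
    phys_min[i] <- -rng
  }
  field <- function(f, width)
    writeChar(paste(vapply(seq_len(ns), f, character(1)), collapse = ""),
              con, eos = NULL)
  field(function(i) .edf_pad(channels[[i]]$label, 16), 16)
  field(function(i) .edf_pad("", 80), 80)
  field(function(i) .edf_pad(channels[[i]]$unit, 8), 8)
  field(function(i) .edf_num(phys_min[i], 8), 8)
  field(function(i) .edf_num(phys_max[i], 8), 8)
  field(function(i) .edf_pad(-32768L, 8), 8)
  field(function(i) .edf_pad(32767L, 8), 8)
  field(function(i) .edf_pad("", 80), 80)
  field(function(i) .edf_pad(channels[[i]]$samples_per_record, 8), 8)
  field(function(i) .edf_pad("", 32), 32)

  # digitize: dig = round((x - pmin) / (pmax - pmin) * 65535 - 32768)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- channels[[i]]$data
    d <- round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }
  spr <- vapply(channels, `[[`, integer(1), "samples_per_record")
  # interleave per record without an R-level loop over records
  idx <- vector("list", ns)
  for (i in seq_len(ns))
    idx[[i]] <- rep(seq_len(n_records), each = spr[i])
  ord <- order(unlist(idx), rep(seq_len(ns), times = spr * n_records))
  writeBin(unlist(dig)[ord], con, size = 2L, endian = "little")
  invisible(path)
}

.edf_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    s <- readChar(con, width, useBytes = TRUE)
    trimws(s)
  }
  rd(8) # version
  patient <- rd(80)
  recording <- rd(80)
  date <- rd(8)
  time <- rd(8)
  rd(8) # header bytes
  rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), character(1))
  labels <- fields(16)
  fields(80)
  units <- fields(8)
  pmin <- as.numeric(fields(8))
  pmax <- as.numeric(fields(8))
  dmin <- as.numeric(fields(8))
  dmax <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)

  raw <- readBin(con, "integer", n = sum(spr) * n_records, size = 2L,
                 signed = TRUE, endian = "little")
  sig_of_sample <- rep(rep(seq_len(ns), times = spr), times = n_records)
  data <- vector("list", ns)
  for (i in seq_len(ns)) {
    d <- raw[sig_of_sample == i]
    data[[i]] <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
  }
  start_time <- tryCatch(
    format(as.POSIXct(paste(date, time), format = "%d.%m.%y %H.%M.%S",
                      tz = "UTC")),
    error = function(e) NA_character_)
  list(patient = patient, recording = recording, start_time = start_time,
       n_records = n_records, record_duration = record_dur,
       labels = labels, units = units, rates = spr / record_dur,
       data = data)
}
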