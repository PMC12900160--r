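# EDF (European Data Format) 16-bit reader/writer.
#
# The classic EDF layout: a 256-byte fixed header, one 256-byte header block
# per signal, then data records of interleaved little-endian int16 samples.
# Only the plain-EDF subset needed for two-channel SpO2/FP0 recordings is
# supported (no EDF+ annotations).

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

# Pick a record duration (seconds) giving an integer number of samples per
# record for every channel.
edf_record_duration <- function(rates) {
  for (dur in c(1, 2, 5, 10)) {
    if (all(abs(rates * dur - round(rates * dur)) < 1e-9)) return(dur)
  }
  stop("cannot represent sampling rates ", paste(rates, collapse = ", "),
       " with an integral EDF record; use rates commensurate with 10 s")
}

#' Write traces of one patient to an EDF file
#'
#' Signals are quantized to 16 bits over a per-channel physical range
#' (SpO2 is stored over 0--100 %, airflow over a symmetric range covering the
#' data). Recordings whose duration is not a whole number of data records are
#' padded by repeating the final sample.
#'
#' @param traces List of [psg_trace()] objects belonging to one patient.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(traces, path) {
  if (inherits(traces, "psg_trace")) traces <- list(traces)
  lapply(traces, stopifnot_trace)
  ids <- unique(vapply(traces, function(t) t$patient_id, ""))
  if (length(ids) != 1L) stop("all traces in one EDF file must share a patient_id")
  rates <- vapply(traces, function(t) t$rate, 0)
  rec_dur <- edf_record_duration(rates)
  spr <- as.integer(round(rates * rec_dur))
  n_rec <- max(ceiling(vapply(traces, function(t) length(t$samples), 0) / spr))

  phys <- lapply(traces, function(t) {
    x <- t$samples[is.finite(t$samples)]
    if (t$channel == "SpO2" && length(x) && min(x) >= 0 && max(x) <= 100) {
      c(0, 100)
    } else {
      m <- if (length(x)) max(abs(x)) else 1
      m <- max(m * 1.05, 1e-6)
      c(-m, m)
    }
  })

  con <- file(path, "wb")
  on.exit(close(con))
  ns <- length(traces)
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad(ids, 80L),
    edf_pad("synthetic PSG", 80L),
    edf_pad("01.01.00", 8L),
    edf_pad("00.00.00", 8L),
    edf_pad(256L * (ns + 1L), 8L),
    edf_pad("", 44L),
    edf_pad(n_rec, 8L),
    edf_num(rec_dur, 8L),
    edf_pad(ns, 4L)
  )
  field <- function(f) paste0(vapply(seq_len(ns), f, ""), collapse = "")
  hdr <- paste0(
    hdr,
    field(function(i) edf_pad(traces[[i]]$channel, 16L)),
    field(function(i) edf_pad("", 80L)),
    field(function(i) edf_pad(if (traces[[i]]$channel == "SpO2") "%" else "au", 8L)),
    field(function(i) edf_num(phys[[i]][1], 8L)),
    field(function(i) edf_num(phys[[i]][2], 8L)),
    field(function(i) edf_pad(-32768L, 8L)),
    field(function(i) edf_pad(32767L, 8L)),
    field(function(i) edf_pad("", 80L)),
    field(function(i) edf_pad(spr[i], 8L)),
    field(function(i) edf_pad("", 32L))
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  digitized <- lapply(seq_len(ns), function(i) {
    x <- traces[[i]]$samples
    need <- n_rec * spr[i]
    if (length(x) < need) x <- c(x, rep(x[length(x)], need - length(x)))
    # masked samples are stored at the physical minimum
    x[!is.finite(x)] <- phys[[i]][1]
    p <- phys[[i]]
    d <- round((x - p[1]) / (p[2] - p[1]) * 65535 - 32768)
    as.integer(pmin(pmax(d, -32768), 32767))
  })
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(digitized[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into per-channel traces
#'
#' @param path EDF file path.
#' @param channels Channel names that must be present; an absent requested
#'   channel is an error. Channels outside this set are ignored with a message.
#' @return Named list of [psg_trace()] objects, one per requested channel.
#' @export
read_edf <- function(path, channels = c("SpO2", "FP0")) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) {
    s <- readChar(con, n, useBytes = TRUE)
    if (length(s) == 0L || nchar(s, type = "bytes") < n)
      stop("malformed EDF: truncated header in ", path)
    trimws(s)
  }
  rd(8L)                       # version
  patient_id <- rd(80L)
  rd(80L); rd(8L); rd(8L); rd(8L); rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))
  if (is.na(ns) || ns < 1L || is.na(n_rec) || n_rec < 1L)
    stop("malformed EDF: bad record/signal counts in ", path)
  getf <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- getf(16L); getf(80L); getf(8L)
  pmin_ <- as.numeric(getf(8L)); pmax_ <- as.numeric(getf(8L))
  dmin <- as.numeric(getf(8L)); dmax <- as.numeric(getf(8L))
  getf(80L)
  spr <- as.integer(getf(8L)); getf(32L)

  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < n_rec * sum(spr))
    stop("malformed EDF: truncated data records in ", path)

  missing <- setdiff(channels, labels)
  if (length(missing))
    stop("EDF file ", path, " lacks required channel(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(labels, channels)
  if (length(extra))
    message("read_edf: ignoring channel(s) ", paste(extra, collapse = ", "))

  offs <- c(0L, cumsum(spr))
  rec_len <- sum(spr)
  out <- list()
  for (ch in channels) {
    i <- match(ch, labels)
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]), (seq_len(n_rec) - 1L) * rec_len, `+`))
    d <- raw[idx]
    x <- (d + 32768) / 65535 * (pmax_[i] - pmin_[i]) + pmin_[i]
    out[[ch]] <- psg_trace(patient_id, ch, spr[i] / rec_dur, x)
  }
  out
}
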