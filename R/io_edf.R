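# Minimal EDF (European Data Format) support: continuous recordings,
# integer-Hz channels, 1-s data records, 16-bit samples. Sufficient for
# monitor-style exports; EDF+ annotations are not interpreted. Invalid
# samples are stored at the digital minimum (-32768), a common sentinel
# convention, and restored to the validity mask on read.

edf_labels <- c(resp = "Resp effort", spo2 = "SpO2", hr = "HR", ecg = "ECG")
edf_dims <- c(resp = "au", spo2 = "%", hr = "bpm", ecg = "mV")

pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Channels are scaled to 16-bit integers over their observed physical
#' range; invalid samples are stored at the digital-minimum sentinel and
#' recovered as invalid by [read_edf()]. Channel sampling rates must be
#' whole Hz (one EDF data record per second).
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  chs <- rec$channels
  ns <- length(chs)
  rates <- vapply(chs, `[[`, numeric(1), "rate")
  if (any(rates != round(rates))) {
    stop("write_edf: channel rates must be integer Hz", call. = FALSE)
  }
  n_rec <- max(ceiling(vapply(chs, function(ch)
    length(ch$values) / ch$rate, numeric(1))))

  scale <- lapply(chs, function(ch) {
    v <- ch$values[ch$valid]
    if (length(v) == 0L) v <- 0
    pmin_ <- min(v); pmax_ <- max(v)
    if (pmax_ <= pmin_) pmax_ <- pmin_ + 1
    list(pmin = pmin_, pmax = pmax_)
  })

  con <- file(path, "wb")
  on.exit(close(con))
  wrt <- function(x, width) writeChar(paste0(pad(x, width), collapse = ""),
                                      con, eos = NULL)
  wrt("0", 8)
  wrt(rec$subject_id, 80)
  wrt("neoapnea recording", 80)
  wrt("01.01.00", 8)
  wrt("00.00.00", 8)
  wrt(256 + ns * 256, 8)
  wrt("", 44)
  wrt(n_rec, 8)
  wrt("1", 8)
  wrt(ns, 4)
  roles <- names(chs)
  lab <- ifelse(roles %in% names(edf_labels), edf_labels[roles], roles)
  dim_ <- ifelse(roles %in% names(edf_dims), edf_dims[roles], "")
  for (l in lab) wrt(l, 16)
  for (i in seq_len(ns)) wrt("", 80)
  for (d in dim_) wrt(d, 8)
  for (s in scale) wrt(format(s$pmin, digits = 7), 8)
  for (s in scale) wrt(format(s$pmax, digits = 7), 8)
  for (i in seq_len(ns)) wrt("-32767", 8)
  for (i in seq_len(ns)) wrt("32767", 8)
  for (i in seq_len(ns)) wrt("", 80)
  for (r in rates) wrt(r, 8)
  for (i in seq_len(ns)) wrt("", 32)

  # digitize each channel fully, pad to n_rec records, then interleave
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    ch <- chs[[i]]
    s <- scale[[i]]
    d <- as.integer(round((ch$values - s$pmin) / (s$pmax - s$pmin) * 65534)
                    - 32767L)
    d[d > 32767L] <- 32767L
    d[d < -32767L] <- -32767L
    d[!ch$valid] <- -32768L
    want <- n_rec * ch$rate
    if (length(d) < want) d <- c(d, rep(-32768L, want - length(d)))
    dig[[i]] <- d
  }
  spr <- as.integer(rates)
  out <- integer(n_rec * sum(spr))
  off <- 0L
  starts <- cumsum(c(0L, spr[-ns]))
  tot <- sum(spr)
  for (i in seq_len(ns)) {
    # positions of channel i's block within each record
    pos <- rep((0:(n_rec - 1L)) * tot, each = spr[i]) + starts[i] +
      seq_len(spr[i])
    out[pos] <- dig[[i]]
  }
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Supports continuous EDF with 16-bit samples. Channel roles are inferred
#' from labels (`Resp*` -> `resp`, `SpO2`/`Sa02` -> `spo2`, `HR`/`Heart
#' rate` -> `hr`, `ECG`/`EKG` -> `ecg`) unless an explicit `channel_map` is
#' given. Digital-minimum samples are marked invalid rather than dropped,
#' so the total of valid and invalid samples always equals the file length.
#'
#' @param path EDF file path.
#' @param channel_map optional named character vector mapping EDF labels to
#'   roles, e.g. `c("Airflow" = "resp")`.
#' @return a [recording()].
#' @export
read_edf <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop("not an EDF file: ", path, call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  dims <- vapply(seq_len(ns), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  tot <- sum(spr)
  raw <- readBin(con, integer(), n = n_rec * tot, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(raw) < n_rec * tot) {
    stop("read_edf: file truncated (expected ", n_rec * tot,
         " samples, got ", length(raw), ")", call. = FALSE)
  }
  starts <- cumsum(c(0L, spr[-ns]))
  channels <- list()
  for (i in seq_len(ns)) {
    pos <- rep((0:(n_rec - 1L)) * tot, each = spr[i]) + starts[i] +
      seq_len(spr[i])
    d <- raw[pos]
    invalid <- d == -32768L
    gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    v <- (d - dmin_[i]) * gain + pmin_[i]
    role <- edf_role(labels[i], channel_map)
    channels[[role]] <- list(values = v, rate = spr[i] / rec_dur,
                             valid = !invalid)
  }
  recording(channels, start_time = 0,
            subject_id = if (nzchar(patient)) patient else "subject")
}

edf_role <- function(label, channel_map) {
  if (!is.null(channel_map) && label %in% names(channel_map)) {
    return(unname(channel_map[label]))
  }
  l <- tolower(label)
  if (grepl("^resp|^thor|airflow|effort", l)) return("resp")
  if (grepl("spo2|sao2|sat", l)) return("spo2")
  if (grepl("^hr$|heart rate|pulse", l)) return("hr")
  if (grepl("ecg|ekg", l)) return("ecg")
  label
}
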