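#' Frame packetization
#'
#' One frame carries the sign-extended 32-bit codes of all channels for a
#' single sample instant, wrapped in the wire dialect: a fixed 2-byte header
#' `0xA5 0x5A`, a 4-byte little-endian packet number, 4 bytes per channel of
#' little-endian signed payload, and a trailing XOR checksum over everything
#' before it. The checksum detects any single-bit corruption.
#'
#' @param sample_codes Integer vector of per-channel ADC codes (must fit a
#'   signed 32-bit word; 24-bit codes always do).
#' @param packet_number Non-negative frame counter (< 2^32).
#' @return `encode_frame()` returns a raw vector; `decode_frame()` returns a
#'   list of class `emg_frame` with fields `packet_number`, `sample_codes`,
#'   `checksum`.
#' @export
#' @examples
#' f <- decode_frame(encode_frame(c(-5L, 120L), 7), n_channels = 2)
#' f$sample_codes
encode_frame <- function(sample_codes, packet_number) {
  if (any(abs(sample_codes) > 2^31 - 1)) stop("code does not fit 32-bit signed")
  if (packet_number < 0 || packet_number >= 2^32) {
    stop("packet number out of 32-bit unsigned range")
  }
  body <- c(
    frame_header_bytes(),
    uint32_le(packet_number),
    int32_le(sample_codes)
  )
  c(body, xor_checksum(body))
}

frame_header_bytes <- function() as.raw(c(0xA5, 0x5A))

uint32_le <- function(n) {
  as.raw(c(n %% 256, (n %/% 256) %% 256, (n %/% 256^2) %% 256, (n %/% 256^3) %% 256))
}

int32_le <- function(codes) {
  writeBin(as.integer(codes), raw(), size = 4L, endian = "little")
}

xor_checksum <- function(bytes) Reduce(xor, bytes, as.raw(0))

frame_size <- function(n_channels) 2L + 4L + 4L * n_channels + 1L

#' @rdname encode_frame
#' @param bytes Raw vector holding exactly one frame.
#' @param n_channels Number of channels in the payload.
#' @export
decode_frame <- function(bytes, n_channels) {
  sz <- frame_size(n_channels)
  if (length(bytes) < sz) stop("truncated frame: expected ", sz, " bytes")
  bytes <- bytes[seq_len(sz)]
  if (!identical(bytes[1:2], frame_header_bytes())) stop("bad frame header tag")
  if (!identical(xor_checksum(bytes[seq_len(sz - 1L)]), bytes[sz])) {
    stop("frame checksum mismatch")
  }
  pn <- sum(as.numeric(bytes[3:6]) * 256^(0:3))
  codes <- readBin(bytes[7:(6L + 4L * n_channels)], integer(),
                   n = n_channels, size = 4L, endian = "little")
  structure(list(packet_number = pn, sample_codes = codes,
                 checksum = bytes[sz]),
            class = "emg_frame")
}

#' Decode a stream of frames with resynchronization
#'
#' Walks a raw buffer, decoding consecutive frames. After a corrupted or
#' partial frame the scanner advances to the next valid header so subsequent
#' frames still decode. Gaps in the packet-number sequence are reported as
#' dropped packets.
#'
#' @param bytes Raw vector holding zero or more concatenated frames.
#' @param n_channels Channels per frame.
#' @return A list with `frames` (list of decoded frames), `n_corrupt`
#'   (skipped byte runs that failed to decode) and `dropped_packets`
#'   (packet numbers missing from the decoded sequence).
#' @export
decode_frame_stream <- function(bytes, n_channels) {
  sz <- frame_size(n_channels)
  frames <- list()
  n_corrupt <- 0L
  pos <- 1L
  while (pos + sz - 1L <= length(bytes)) {
    chunk <- bytes[pos:(pos + sz - 1L)]
    ok <- identical(chunk[1:2], frame_header_bytes()) &&
      identical(xor_checksum(chunk[seq_len(sz - 1L)]), chunk[sz])
    if (ok) {
      frames[[length(frames) + 1L]] <- decode_frame(chunk, n_channels)
      pos <- pos + sz
    } else {
      n_corrupt <- n_corrupt + 1L
      # resync: scan forward for the next plausible header
      nxt <- pos + 1L
      while (nxt + 1L <= length(bytes) &&
             !(bytes[nxt] == as.raw(0xA5) && bytes[nxt + 1L] == as.raw(0x5A))) {
        nxt <- nxt + 1L
      }
      pos <- nxt
      if (pos + 1L > length(bytes)) break
    }
  }
  pns <- vapply(frames, `[[`, numeric(1), "packet_number")
  dropped <- numeric(0)
  if (length(pns) > 1L) {
    gaps <- which(diff(pns) > 1)
    for (g in gaps) dropped <- c(dropped, seq(pns[g] + 1, pns[g + 1] - 1))
  }
  list(frames = frames, n_corrupt = n_corrupt, dropped_packets = dropped)
}

#' Assemble decoded frames into a recording
#'
#' @param frames List of decoded frames (same channel count).
#' @param adc [adc_config()] used to convert codes to volts.
#' @param rate Sampling rate in Hz; defaults to the ADC `sps`.
#' @param channel_labels Optional channel names.
#' @return An [emg_recording()].
#' @export
frames_to_recording <- function(frames, adc = adc_config(), rate = adc$sps,
                                channel_labels = NULL) {
  if (!length(frames)) stop("no frames to assemble")
  codes <- do.call(rbind, lapply(frames, `[[`, "sample_codes"))
  emg_recording(code_to_volts(codes, adc), rate, channel_labels, adc)
}
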