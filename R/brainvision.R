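#' Write an EEG recording as a BrainVision triplet
#'
#' Writes the standard three-file set: a text header (\code{.vhdr}), a text
#' marker file (\code{.vmrk}) and the binary data file (\code{.eeg},
#' IEEE float32, multiplexed channel order, microvolts).
#'
#' @param recording An \code{\link{eeg_recording}}.
#' @param path Base path without extension; the three files are written as
#'   \code{path.vhdr}, \code{path.vmrk}, \code{path.eeg}.
#' @return Invisibly, the header path.
#' @export
write_brainvision <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  base <- basename(path)
  vhdr <- paste0(path, ".vhdr")
  vmrk <- paste0(path, ".vmrk")
  eeg <- paste0(path, ".eeg")

  nchan <- nrow(recording$data)
  samp_int_us <- 1e6 / recording$sampling_rate
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nchan),
    sprintf("SamplingInterval=%g", samp_int_us),
    "",
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nchan), recording$channel_labels))
  writeLines(hdr, vhdr, useBytes = TRUE)

  mk <- recording$markers
  desc <- ifelse(mk$kind == "stimulus", sprintf("S%d", mk$trial),
          ifelse(mk$kind == "response_left", sprintf("RL%d", mk$trial),
                 sprintf("RR%d", mk$trial)))
  type <- ifelse(mk$kind == "stimulus", "Stimulus", "Response")
  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(mk)) + 1L, type, desc,
            mk$sample))
  writeLines(mrk, vmrk, useBytes = TRUE)

  con <- file(eeg, "wb")
  on.exit(close(con))
  # multiplexed: all channels of sample 1, then sample 2, ...
  writeBin(as.vector(recording$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

bv_get <- function(lines, key) {
  hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
  if (length(hit) == 0)
    stop(sprintf("BrainVision header: missing field '%s'", key),
         call. = FALSE)
  sub(sprintf("^%s=", key), "", hit[1])
}

#' Read a BrainVision triplet
#'
#' Parses the \code{.vhdr} header, the \code{.vmrk} markers and the binary
#' \code{.eeg} payload. Only the combination written by
#' \code{\link{write_brainvision}} (binary, multiplexed, IEEE float32) is
#' supported; mismatched channel counts and missing companion files raise
#' errors naming the offending file or line.
#'
#' @param header_path Path to the \code{.vhdr} file.
#' @return An \code{\link{eeg_recording}}.
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path))
    stop("header not found: ", header_path, call. = FALSE)
  lines <- readLines(header_path, warn = FALSE, encoding = "UTF-8")
  dir <- dirname(header_path)

  fmt <- bv_get(lines, "BinaryFormat")
  if (fmt != "IEEE_FLOAT_32")
    stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  if (bv_get(lines, "DataOrientation") != "MULTIPLEXED")
    stop("unsupported DataOrientation", call. = FALSE)
  nchan <- as.integer(bv_get(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(bv_get(lines, "SamplingInterval"))

  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  if (length(ch_lines) != nchan)
    stop(sprintf(
      "header declares %d channels but lists %d channel lines",
      nchan, length(ch_lines)), call. = FALSE)
  labels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                   `[`, character(1), 1)

  eeg_path <- file.path(dir, bv_get(lines, "DataFile"))
  vmrk_path <- file.path(dir, bv_get(lines, "MarkerFile"))
  if (!file.exists(vmrk_path))
    stop("marker file not found: ", vmrk_path, call. = FALSE)
  if (!file.exists(eeg_path))
    stop("data file not found: ", eeg_path, call. = FALSE)

  nbytes <- file.info(eeg_path)$size
  nvals <- nbytes / 4
  if (nvals %% nchan != 0)
    stop(sprintf(
      "data file holds %d values, not divisible by %d channels",
      nvals, nchan), call. = FALSE)
  con <- file(eeg_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = nvals, size = 4, endian = "little")
  dat <- matrix(raw, nrow = nchan,
                dimnames = list(labels, NULL))

  mlines <- readLines(vmrk_path, warn = FALSE, encoding = "UTF-8")
  mk <- grep("^Mk[0-9]+=", mlines, value = TRUE)
  parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
  keep <- vapply(parts, function(p) p[1] %in% c("Stimulus", "Response"),
                 logical(1))
  parts <- parts[keep]
  if (length(parts) > 0) {
    desc <- vapply(parts, `[`, character(1), 2)
    kind <- ifelse(grepl("^S", desc), "stimulus",
            ifelse(grepl("^RL", desc), "response_left", "response_right"))
    trial <- as.integer(sub("^(S|RL|RR)", "", desc))
    smp <- as.integer(vapply(parts, `[`, character(1), 3))
    markers <- data.frame(sample = smp, kind = kind, trial = trial)
    markers <- markers[order(markers$sample), ]
    rownames(markers) <- NULL
  } else {
    markers <- data.frame(sample = integer(), kind = character(),
                          trial = integer())
  }
  eeg_recording(dat, labels, fs, markers)
}
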