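# Minimal BrainVision (.vhdr/.vmrk/.eeg) support: read-side handles the
# multiplexed INT_16 and IEEE_FLOAT_32 binary dialects; write-side produces
# just enough of the format for fixtures and interchange.

parse_ini_sections <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)            # strip comments
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[(.+)\\]$", ln))[[1]]
    if (length(m) == 2) {
      current <- m[2]
      sections[[current]] <- character(0)
      next
    }
    if (!is.null(current)) sections[[current]] <- c(sections[[current]], ln)
  }
  sections
}

ini_value <- function(section, key) {
  hits <- grep(paste0("^", key, "="), section, value = TRUE, ignore.case = TRUE)
  if (!length(hits)) return(NULL)
  sub("^[^=]*=", "", hits[1])
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header, the `.vmrk` marker file and the binary `.eeg`
#' payload. Supported binary layouts: multiplexed `INT_16` (scaled to uV by
#' the per-channel resolution) and `IEEE_FLOAT_32` (taken as uV as written).
#' Marker positions (1-based in the file format) are converted to the
#' package's 0-based sample indices.
#'
#' @param header_path Path to the `.vhdr` file.
#' @return An `erp_recording`.
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path)) {
    stop(sprintf("header file not found: %s", header_path), call. = FALSE)
  }
  hdr <- parse_ini_sections(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  chi <- hdr[["Channel Infos"]]
  if (is.null(ci)) {
    stop(sprintf("'%s': missing [Common Infos] section", header_path), call. = FALSE)
  }
  dir <- dirname(header_path)
  eeg_path <- file.path(dir, ini_value(ci, "DataFile"))
  vmrk_path <- file.path(dir, ini_value(ci, "MarkerFile"))
  if (!file.exists(eeg_path)) {
    stop(sprintf("data file referenced by '%s' not found: %s",
                 header_path, eeg_path), call. = FALSE)
  }
  orientation <- toupper(ini_value(ci, "DataOrientation") %||% "MULTIPLEXED")
  if (orientation != "MULTIPLEXED") {
    stop(sprintf("unsupported BrainVision data orientation '%s' in %s",
                 orientation, header_path), call. = FALSE)
  }
  n_channels <- as.integer(ini_value(ci, "NumberOfChannels"))
  samp_int_us <- as.numeric(ini_value(ci, "SamplingInterval"))
  fs <- 1e6 / samp_int_us
  fmt <- toupper(ini_value(bi, "BinaryFormat") %||% "INT_16")

  # Channel Infos lines: Ch<k>=<name>,<ref>,<resolution>,<unit>
  labels <- character(n_channels)
  resolutions <- rep(1, n_channels)
  for (k in seq_len(n_channels)) {
    raw <- ini_value(chi, sprintf("Ch%d", k))
    if (is.null(raw)) {
      stop(sprintf("'%s': missing Ch%d entry in [Channel Infos]",
                   header_path, k), call. = FALSE)
    }
    parts <- strsplit(raw, ",", fixed = TRUE)[[1]]
    labels[k] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) {
      resolutions[k] <- as.numeric(parts[3])
    }
  }

  sz <- file.info(eeg_path)$size
  if (fmt == "INT_16") {
    n_vals <- sz / 2
    raw <- readBin(eeg_path, "integer", n = n_vals, size = 2, signed = TRUE,
                   endian = "little")
  } else if (fmt == "IEEE_FLOAT_32") {
    n_vals <- sz / 4
    raw <- readBin(eeg_path, "numeric", n = n_vals, size = 4, endian = "little")
  } else {
    stop(sprintf("unsupported BrainVision binary format '%s' in %s",
                 fmt, header_path), call. = FALSE)
  }
  if (length(raw) %% n_channels != 0) {
    stop(sprintf("data file %s is truncated: %d values not divisible by %d channels",
                 eeg_path, length(raw), n_channels), call. = FALSE)
  }
  n_samples <- length(raw) %/% n_channels
  signal <- matrix(as.numeric(raw), nrow = n_channels, ncol = n_samples)
  if (fmt == "INT_16") signal <- signal * resolutions  # recycle by channel (rows)

  markers <- data.frame(onset_sample = integer(0), code = character(0),
                        stringsAsFactors = FALSE)
  if (!is.null(vmrk_path) && file.exists(vmrk_path)) {
    mk <- parse_ini_sections(readLines(vmrk_path, warn = FALSE))[["Marker Infos"]]
    if (!is.null(mk)) {
      onset <- integer(0); code <- character(0)
      for (ln in mk) {
        val <- sub("^[^=]*=", "", ln)
        parts <- strsplit(val, ",", fixed = TRUE)[[1]]
        if (length(parts) < 3 || !identical(parts[1], "Stimulus")) next
        code <- c(code, parts[2])
        onset <- c(onset, as.integer(parts[3]) - 1L)  # file is 1-based
      }
      markers <- data.frame(onset_sample = onset, code = code,
                            stringsAsFactors = FALSE)
    }
  } else if (!is.null(ini_value(ci, "MarkerFile"))) {
    stop(sprintf("marker file referenced by '%s' not found: %s",
                 header_path, vmrk_path), call. = FALSE)
  }

  new_recording(signal, fs, labels, markers,
                metadata = list(source = header_path, binary_format = fmt))
}

#' Write a recording as a BrainVision triplet
#'
#' Minimal writer used for fixtures and interchange: multiplexed binary
#' payload in either `IEEE_FLOAT_32` (default, lossless for single
#' precision) or `INT_16` with a fixed resolution.
#'
#' @param recording An `erp_recording`.
#' @param basename_path Path without extension; `.vhdr`, `.vmrk` and `.eeg`
#'   are written next to each other.
#' @param binary_format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @param resolution uV per integer unit when writing `INT_16`.
#' @return The `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(recording, basename_path,
                              binary_format = c("IEEE_FLOAT_32", "INT_16"),
                              resolution = 0.1) {
  stopifnot(inherits(recording, "erp_recording"))
  binary_format <- match.arg(binary_format)
  base <- basename(basename_path)
  vhdr <- paste0(basename_path, ".vhdr")
  vmrk <- paste0(basename_path, ".vmrk")
  eeg <- paste0(basename_path, ".eeg")
  nc <- nrow(recording$signal)

  res <- if (binary_format == "INT_16") resolution else 1
  ch_lines <- sprintf("Ch%d=%s,,%g,µV", seq_len(nc),
                      recording$channel_labels, rep(res, nc))
  writeLines(c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nc),
    sprintf("SamplingInterval=%g", 1e6 / recording$sampling_rate),
    "",
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binary_format),
    "",
    "[Channel Infos]",
    ch_lines
  ), vhdr)

  mk <- recording$markers
  mk_lines <- if (nrow(mk)) {
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(mk)) + 1L, mk$code,
            mk$onset_sample + 1L)
  } else character(0)
  writeLines(c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", base),
    "",
    "[Marker Infos]",
    sprintf("Mk1=New Segment,,1,1,0"),
    mk_lines
  ), vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(recording$signal), con, size = 4, endian = "little")
  } else {
    raw <- as.integer(round(recording$signal / resolution))
    if (any(abs(raw) > 32767)) {
      stop("signal exceeds INT_16 range at the requested resolution", call. = FALSE)
    }
    writeBin(raw, con, size = 2, endian = "little")
  }
  invisible(vhdr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
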