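#' ECG record container
#'
#' A sampled multi-lead signal with sampling rate and per-beat annotations.
#' Annotation sample indices are 0-based (the convention of the WFDB tools
#' this container interoperates with) and must lie in `[0, nrow(signal))`.
#'
#' @param signal Numeric matrix, one column per lead.
#' @param fs Sampling frequency in Hz.
#' @param annotations `data.frame` with columns `sample` (0-based integer
#'   index) and `symbol` (single-character beat annotation).
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs,
                       annotations = data.frame(sample = integer(),
                                                symbol = character())) {
  if (is.vector(signal)) signal <- matrix(signal, ncol = 1)
  stopifnot(is.matrix(signal), fs > 0)
  stopifnot(all(c("sample", "symbol") %in% names(annotations)))
  if (nrow(annotations)) {
    if (any(annotations$sample < 0L | annotations$sample >= nrow(signal)))
      stop("annotation indices must lie in [0, record length)")
    if (is.unsorted(annotations$sample))
      annotations <- annotations[order(annotations$sample), , drop = FALSE]
  }
  structure(list(signal = signal, fs = fs,
                 lead_names = colnames(signal),
                 annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d lead(s) @ %g Hz (%.1f s), %d annotations\n",
              nrow(x$signal), ncol(x$signal), x$fs,
              nrow(x$signal) / x$fs, nrow(x$annotations)))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$symbol)
    cat("  beats:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

# ---- format 212 bit packing --------------------------------------------

# Two 12-bit two's-complement samples per 3 bytes:
#   s1 = low nibble of byte2 (high bits) | byte1
#   s2 = high nibble of byte2 (high bits) | byte3
decode_212 <- function(raw_bytes) {
  b <- as.integer(raw_bytes)
  stopifnot(length(b) %% 3 == 0)
  b1 <- b[seq(1, length(b), by = 3)]
  b2 <- b[seq(2, length(b), by = 3)]
  b3 <- b[seq(3, length(b), by = 3)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 0x0F), 8), b1)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 0xF0), 4), b3)
  s1 <- ifelse(s1 >= 2048L, s1 - 4096L, s1)
  s2 <- ifelse(s2 >= 2048L, s2 - 4096L, s2)
  # interleave: pair i contributes samples (2i-1, 2i)
  out <- integer(2L * length(s1))
  out[c(TRUE, FALSE)] <- s1
  out[c(FALSE, TRUE)] <- s2
  out
}

encode_212 <- function(samples) {
  s <- as.integer(samples)
  if (any(s > 2047L | s < -2048L))
    stop("sample overflow: format 212 stores 12-bit values in [-2048, 2047]")
  if (length(s) %% 2 == 1L) s <- c(s, 0L)   # zero-pad final pair
  s[s < 0L] <- s[s < 0L] + 4096L
  s1 <- s[c(TRUE, FALSE)]
  s2 <- s[c(FALSE, TRUE)]
  b1 <- bitwAnd(s1, 0xFF)
  b2 <- bitwOr(bitwAnd(bitwShiftR(s1, 8), 0x0F),
               bitwShiftL(bitwAnd(bitwShiftR(s2, 8), 0x0F), 4))
  b3 <- bitwAnd(s2, 0xFF)
  out <- integer(3L * length(s1))
  out[seq(1, length(out), by = 3)] <- b1
  out[seq(2, length(out), by = 3)] <- b2
  out[seq(3, length(out), by = 3)] <- b3
  as.raw(out)
}

# ---- MIT annotation file (binary) --------------------------------------

# Annotation code numbers for the beat/non-beat symbols we read and write.
.ann_code_table <- c("N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L,
                     "F" = 6L, "J" = 7L, "A" = 8L, "S" = 9L, "E" = 10L,
                     "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L, "e" = 34L,
                     "f" = 38L, "x" = 37L, "+" = 28L, "\"" = 22L)

read_annotation_binary <- function(path) {
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  b <- as.integer(raw_bytes)
  i <- 1L
  t_now <- 0L
  samples <- integer(0); codes <- integer(0)
  while (i + 1L <= length(b)) {
    w <- b[i] + 256L * b[i + 1L]     # little-endian 16-bit word
    code <- bitwShiftR(w, 10)
    interval <- bitwAnd(w, 1023L)
    i <- i + 2L
    if (code == 0L && interval == 0L) break          # EOF
    if (code == 59L) {                               # SKIP: 4-byte interval
      hi <- b[i] + 256L * b[i + 1L]
      lo <- b[i + 2L] + 256L * b[i + 3L]
      t_now <- t_now + hi * 65536L + lo
      i <- i + 4L
    } else if (code %in% c(60L, 61L, 62L, 63L)) {    # NUM/SUB/CHN/AUX: skip
      if (code == 63L) i <- i + interval + interval %% 2L
    } else {
      t_now <- t_now + interval
      samples <- c(samples, t_now)
      codes <- c(codes, code)
    }
  }
  sym <- names(.ann_code_table)[match(codes, .ann_code_table)]
  sym[is.na(sym)] <- "Q"
  data.frame(sample = samples, symbol = sym, stringsAsFactors = FALSE)
}

write_annotation_binary <- function(annotations, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  t_prev <- 0L
  for (i in seq_len(nrow(annotations))) {
    code <- .ann_code_table[[annotations$symbol[i]]]
    if (is.null(code)) stop("no annotation code for symbol ", annotations$symbol[i])
    dt <- annotations$sample[i] - t_prev
    if (dt > 1023L) {                               # emit SKIP word
      w <- bitwShiftL(59L, 10)
      writeBin(as.raw(c(bitwAnd(w, 255L), bitwShiftR(w, 8))), con)
      hi <- dt %/% 65536L; lo <- dt %% 65536L
      writeBin(as.raw(c(hi %% 256L, hi %/% 256L, lo %% 256L, lo %/% 256L)), con)
      dt <- 0L
    }
    w <- bitwOr(bitwShiftL(code, 10), dt)
    writeBin(as.raw(c(bitwAnd(w, 255L), bitwShiftR(w, 8))), con)
    t_prev <- annotations$sample[i]
  }
  writeBin(as.raw(c(0L, 0L)), con)                  # EOF word
  invisible(path)
}

# Plain-text fallback dialect: lines of "sample,symbol".
read_annotation_text <- function(path) {
  df <- utils::read.csv(path, header = FALSE, col.names = c("sample", "symbol"),
                        colClasses = c("integer", "character"))
  df
}

write_annotation_text <- function(annotations, path) {
  utils::write.table(annotations[, c("sample", "symbol")], path,
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- header ------------------------------------------------------------

parse_header <- function(header_path) {
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- if (length(rec) >= 3) as.numeric(rec[3]) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[4]) else NA_integer_
  sig <- lapply(seq_len(nsig), function(i) {
    f <- strsplit(trimws(lines[1 + i]), "[ \t]+")[[1]]
    gain_spec <- f[3]
    baseline <- 0
    gain <- 200
    m <- regmatches(gain_spec, regexec("^([-0-9.]+)(\\(([-0-9]+)\\))?", gain_spec))[[1]]
    if (length(m) && nzchar(m[2])) gain <- as.numeric(m[2])
    if (length(m) >= 4 && nzchar(m[4])) baseline <- as.numeric(m[4])
    if (gain == 0) gain <- 200
    checksum <- if (length(f) >= 7) suppressWarnings(as.integer(f[7])) else NA_integer_
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         checksum = checksum,
         lead = if (length(f) >= 9) f[length(f)] else paste0("lead", i))
  })
  list(record = rec[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

#' Read a WFDB format-212 record
#'
#' Parses the text header, unpacks the 3-byte/2-sample format-212 data
#' file, and (if present) reads the beat annotation file — either the
#' standard binary MIT dialect (`.atr`) or the plain-text `sample,symbol`
#' fallback (`.txt.atr`) written by [write_record()].
#'
#' @param header_path Path to the `.hea` file.
#' @param physical If `TRUE` (default) apply per-lead gain/baseline so
#'   samples are in physical units (mV); otherwise raw ADC integers.
#' @return An [ecg_record()]. A stored-checksum mismatch raises a warning,
#'   not an error.
#' @export
read_record <- function(header_path, physical = TRUE) {
  hdr <- parse_header(header_path)
  dir <- dirname(header_path)
  dat_path <- file.path(dir, hdr$signals[[1]]$file)
  if (!file.exists(dat_path)) stop("data file not found: ", dat_path)
  fmt <- hdr$signals[[1]]$format
  if (!grepl("^212", fmt)) stop("unsupported format code: ", fmt)
  if (hdr$nsig != 2L && hdr$nsig != 1L)
    stop("format 212 reader supports 1 or 2 leads, got ", hdr$nsig)
  raw_bytes <- readBin(dat_path, "raw", n = file.size(dat_path))
  usable <- 3L * (length(raw_bytes) %/% 3L)
  if (usable < length(raw_bytes))
    warning("truncated .dat: ", length(raw_bytes) - usable, " trailing byte(s) ignored")
  if (usable == 0L) stop("truncated .dat: no complete 3-byte frame")
  flat <- decode_212(raw_bytes[seq_len(usable)])
  if (hdr$nsig == 2L) {
    nsamp <- length(flat) %/% 2L
    sig <- cbind(flat[c(TRUE, FALSE)][seq_len(nsamp)],
                 flat[c(FALSE, TRUE)][seq_len(nsamp)])
  } else {
    sig <- matrix(flat, ncol = 1)
  }
  if (!is.na(hdr$nsamp) && hdr$nsamp <= nrow(sig)) {
    sig <- sig[seq_len(hdr$nsamp), , drop = FALSE]
  } else if (!is.na(hdr$nsamp) && hdr$nsamp > nrow(sig)) {
    warning("header declares ", hdr$nsamp, " samples but .dat holds ", nrow(sig))
  }
  colnames(sig) <- vapply(hdr$signals[seq_len(ncol(sig))], `[[`, "", "lead")
  for (j in seq_len(ncol(sig))) {
    stored <- hdr$signals[[j]]$checksum
    if (!is.na(stored) && stored != 0L) {
      cs <- sum(sig[, j]) %% 65536
      if (cs >= 32768) cs <- cs - 65536     # signed 16-bit convention
      if (cs != stored)
        warning(sprintf("checksum mismatch on lead %d (stored %d, computed %d)",
                        j, stored, cs))
    }
  }
  sig <- sig * 1.0
  if (physical) {
    for (j in seq_len(ncol(sig))) {
      s <- hdr$signals[[j]]
      sig[, j] <- (sig[, j] - s$baseline) / s$gain
    }
  }
  base <- file.path(dir, hdr$record)
  ann <- data.frame(sample = integer(), symbol = character())
  if (file.exists(paste0(base, ".txt.atr"))) {
    ann <- read_annotation_text(paste0(base, ".txt.atr"))
  } else if (file.exists(paste0(base, ".atr"))) {
    ann <- read_annotation_binary(paste0(base, ".atr"))
  }
  ann <- ann[ann$sample >= 0L & ann$sample < nrow(sig), , drop = FALSE]
  ecg_record(signal = sig, fs = hdr$fs, annotations = ann)
}

#' Write a WFDB format-212 record
#'
#' Emits `<record>.hea`, `<record>.dat` (format 212) and, when the record
#' carries annotations, an annotation file (binary `.atr` by default, or
#' the plain-text fallback `.txt.atr`). The inverse of [read_record()]:
#' round-tripping is the identity on samples and annotations.
#'
#' @param record An [ecg_record()]; samples are taken as physical units and
#'   digitized with `gain` ADC units/mV unless `digital = TRUE`.
#' @param dir Output directory (created if needed).
#' @param name Record name (file stem).
#' @param gain ADC gain (units per mV), default 200.
#' @param digital If `TRUE`, samples are already ADC integers.
#' @param annotation_dialect `"binary"` or `"text"`.
#' @return Invisibly, the header path.
#' @export
write_record <- function(record, dir, name = "rec", gain = 200,
                         digital = FALSE, annotation_dialect = "binary") {
  stopifnot(inherits(record, "ecg_record"))
  if (nrow(record$signal) == 0L) stop("cannot write an empty record")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nsig <- ncol(record$signal)
  if (nsig > 2L) stop("format 212 writer supports at most 2 leads")
  adc <- if (digital) round(record$signal) else round(record$signal * gain)
  if (any(adc > 2047 | adc < -2048))
    stop("sample overflow: format 212 stores 12-bit values in [-2048, 2047]")
  nsamp <- nrow(adc)
  if (nsig == 2L) {
    flat <- as.integer(t(adc))          # interleave lead1,lead2 per frame
  } else {
    flat <- as.integer(adc[, 1])
  }
  writeBin(encode_212(flat), file.path(dir, paste0(name, ".dat")))
  leads <- record$lead_names
  if (is.null(leads)) leads <- paste0("lead", seq_len(nsig))
  hea <- c(sprintf("%s %d %g %d", name, nsig, record$fs, nsamp),
           vapply(seq_len(nsig), function(j) {
             cs <- sum(adc[, j]) %% 65536
             if (cs >= 32768) cs <- cs - 65536
             sprintf("%s.dat 212 %g(0)/mV 12 0 %d %d 0 %s",
                     name, gain, as.integer(adc[1, j]), as.integer(cs), leads[j])
           }, ""))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  if (nrow(record$annotations)) {
    if (annotation_dialect == "binary") {
      write_annotation_binary(record$annotations, file.path(dir, paste0(name, ".atr")))
    } else {
      write_annotation_text(record$annotations, file.path(dir, paste0(name, ".txt.atr")))
    }
  }
  invisible(file.path(dir, paste0(name, ".hea")))
}

# ---- AAMI mapping ------------------------------------------------------

# ANSI/AAMI EC57 convention: MIT-BIH beat symbol -> AAMI super-class.
.default_aami_map <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "S", "a" = "S", "J" = "S", "S" = "S",
  "V" = "V", "E" = "V",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

#' AAMI label levels
#' @return Character vector `c("N","S","V","F","Q")`.
#' @export
aami_levels <- function() c("N", "S", "V", "F", "Q")

#' Map a beat annotation symbol to its AAMI super-class
#'
#' Uses the ANSI/AAMI EC57 convention: `N,L,R,e,j -> N`; `A,a,J,S -> S`;
#' `V,E -> V`; `F -> F`; `/,f,Q -> Q`. Non-beat symbols (rhythm changes,
#' artifacts, comments) are rejected.
#'
#' @param symbol Character vector of single-character annotation symbols.
#' @param map Named character vector overriding the default table.
#' @return Character vector of AAMI labels in `{N,S,V,F,Q}`.
#' @export
#' @examples
#' map_symbol_to_aami(c("L", "V", "f"))
map_symbol_to_aami <- function(symbol, map = .default_aami_map) {
  out <- unname(map[symbol])
  if (anyNA(out))
    stop("not a beat annotation: ",
         paste(unique(symbol[is.na(out)]), collapse = " "))
  out
}
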