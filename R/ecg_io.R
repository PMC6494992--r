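# WFDB (MIT-BIH dialect) record I/O: .hea header, .dat signal (formats 212
# and 16), .atr annotations (MIT annotation format).  Only the subset of the
# format family used by the MIT-BIH arrhythmia records is supported.

# Standard WFDB annotation mnemonics for codes 1..41 (codes without a
# mnemonic print as their number).
wfdb_ann_codes <- c(
  "N", "L", "R", "a", "V", "F", "J", "A", "S", "E",
  "j", "/", "Q", "~", "", "|", "", "s", "T", "*",
  "D", "\"", "=", "p", "B", "^", "t", "+", "u", "?",
  "!", "[", "]", "e", "n", "@", "x", "f", "(", ")", "r"
)

ann_symbol <- function(code) {
  sym <- ifelse(code >= 1L & code <= length(wfdb_ann_codes), wfdb_ann_codes[code], "")
  ifelse(sym == "" | is.na(sym), as.character(code), sym)
}

new_ecg_record <- function(record_id, sampling_rate, signals, gains = NULL,
                           lead_names = NULL, annotations = NULL) {
  stopifnot(is.matrix(signals))
  structure(list(
    record_id = record_id,
    sampling_rate = sampling_rate,
    n_samples = nrow(signals),
    n_leads = ncol(signals),
    signals = signals,
    gains = gains %||% rep(200, ncol(signals)),
    lead_names = lead_names %||% paste0("lead", seq_len(ncol(signals)) - 1L),
    annotations = annotations %||% tibble::tibble(sample = integer(0), code = integer(0),
                                                  symbol = character(0))
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d lead(s) x %d samples @ %g Hz, %d annotation(s)\n",
              x$record_id, x$n_leads, x$n_samples, x$sampling_rate,
              nrow(x$annotations)))
  invisible(x)
}

#' Read a WFDB record
#'
#' Reads a MIT-BIH-style record from its header file: the `.hea` header, the
#' referenced `.dat` signal file (formats 212 and 16), and, when present, the
#' `.atr` annotation file.  Raw ADC integer samples are returned unscaled;
#' use [extract_lead()] to obtain lead values.
#'
#' @param header_path Path to the `.hea` header file.
#' @return An `ecg_record`: `record_id`, `sampling_rate`, `n_samples`,
#'   integer `signals` matrix (samples x leads), per-lead `gains` and
#'   `lead_names`, and an `annotations` tibble (`sample`, `code`, `symbol`;
#'   empty when no `.atr` file exists).
#' @export
read_wfdb_record <- function(header_path) {
  if (!file.exists(header_path)) stop_io("header file not found: %s", header_path)
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 2L) stop_format("header %s has no signal lines", header_path)
  rec <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  if (length(rec) < 4L) stop_format("malformed record line in %s", header_path)
  record_id <- sub("/.*$", "", rec[[1L]])
  n_sig <- suppressWarnings(as.integer(rec[[2L]]))
  fs <- suppressWarnings(as.numeric(sub("/.*$", "", rec[[3L]])))
  n_samples <- suppressWarnings(as.integer(rec[[4L]]))
  if (is.na(n_sig) || is.na(fs) || is.na(n_samples)) {
    stop_format("malformed record line in %s", header_path)
  }
  sig_lines <- lines[1L + seq_len(n_sig)]
  dat_files <- character(n_sig); fmts <- integer(n_sig)
  gains <- numeric(n_sig); names_ <- character(n_sig)
  for (i in seq_len(n_sig)) {
    f <- strsplit(trimws(sig_lines[[i]]), "\\s+")[[1L]]
    if (length(f) < 2L) stop_format("malformed signal line in %s", header_path)
    dat_files[i] <- f[[1L]]
    fmts[i] <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", f[[2L]])))
    g <- if (length(f) >= 3L) suppressWarnings(as.numeric(sub("^([-0-9.eE+]+).*$", "\\1", f[[3L]]))) else NA
    gains[i] <- if (is.na(g) || g == 0) 200 else g
    names_[i] <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else paste0("lead", i - 1L)
  }
  if (length(unique(dat_files)) != 1L) {
    stop_format("%s: multiple .dat files per record are not supported", header_path)
  }
  if (length(unique(fmts)) != 1L || !fmts[1L] %in% c(212L, 16L)) {
    stop_format("%s: unsupported signal format (%s); formats 212 and 16 are supported",
                header_path, paste(unique(fmts), collapse = ","))
  }
  dat_path <- file.path(dirname(header_path), dat_files[1L])
  if (!file.exists(dat_path)) stop_io("data file not found: %s", dat_path)
  signals <- read_wfdb_dat(dat_path, fmts[1L], n_sig, n_samples)
  atr_path <- file.path(dirname(header_path),
                        paste0(sub("\\.hea$", "", basename(header_path)), ".atr"))
  ann <- if (file.exists(atr_path)) read_wfdb_annotations(atr_path) else NULL
  new_ecg_record(record_id, fs, signals, gains = gains, lead_names = names_,
                 annotations = ann)
}

read_wfdb_dat <- function(path, fmt, n_sig, n_samples) {
  total <- n_sig * n_samples
  if (fmt == 16L) {
    v <- readBin(path, "integer", n = total, size = 2L, signed = TRUE, endian = "little")
    if (length(v) < total) stop_format("data file %s too short for declared sample count", path)
  } else {
    bytes <- readBin(path, "integer", n = file.size(path), size = 1L, signed = FALSE)
    n_pairs <- ceiling(total / 2)
    if (length(bytes) < 3L * n_pairs) {
      stop_format("data file %s too short for declared sample count", path)
    }
    idx <- seq_len(n_pairs)
    b1 <- bytes[3L * idx - 2L]; b2 <- bytes[3L * idx - 1L]; b3 <- bytes[3L * idx]
    s1 <- b1 + 256L * bitwAnd(b2, 15L)
    s2 <- b3 + 256L * bitwShiftR(b2, 4L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))[seq_len(total)]
  }
  matrix(as.integer(v), nrow = n_samples, ncol = n_sig, byrow = TRUE)
}

read_wfdb_annotations <- function(path) {
  bytes <- readBin(path, "integer", n = file.size(path), size = 1L, signed = FALSE)
  n_words <- length(bytes) %/% 2L
  samples <- integer(0); codes <- integer(0)
  t_cur <- 0L
  w <- 1L
  word_at <- function(k) bytes[2L * k - 1L] + 256L * bytes[2L * k]
  while (w <= n_words) {
    word <- word_at(w)
    code <- word %/% 1024L
    interval <- word %% 1024L
    w <- w + 1L
    if (code == 0L && interval == 0L) break
    if (code == 59L) {                      # SKIP: 4-byte interval, high word first
      if (w + 1L > n_words) stop_format("truncated SKIP annotation in %s", path)
      interval <- word_at(w) * 65536 + word_at(w + 1L)
      w <- w + 2L
      t_cur <- t_cur + interval
      # the annotation itself follows as the next word
      next
    } else if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN: field change only
      next
    } else if (code == 63L) {                # AUX: skip the string payload
      w <- w + ceiling(interval / 2)
      next
    }
    t_cur <- t_cur + interval
    samples <- c(samples, t_cur)
    codes <- c(codes, code)
  }
  tibble::tibble(sample = samples, code = codes, symbol = ann_symbol(codes))
}

#' Write a WFDB record
#'
#' Writes `.hea` + `.dat` (and `.atr` when the record carries annotations)
#' in format 212 or 16, round-trippable by [read_wfdb_record()].
#'
#' @param record An `ecg_record` (integer samples; format 212 requires values
#'   in \[-2048, 2047\]).
#' @param dir Output directory (created if needed).
#' @param fmt WFDB signal format: 212 (default) or 16.
#' @return Invisibly, the path of the header file.
#' @export
write_wfdb_record <- function(record, dir, fmt = 212L) {
  stopifnot(inherits(record, "ecg_record"))
  if (!fmt %in% c(212L, 16L)) stop_validation("fmt must be 212 or 16")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- record$record_id
  hea <- file.path(dir, paste0(base, ".hea"))
  dat <- paste0(base, ".dat")
  lines <- sprintf("%s %d %g %d", base, record$n_leads, record$sampling_rate,
                   record$n_samples)
  for (i in seq_len(record$n_leads)) {
    lines <- c(lines, sprintf("%s %d %g 11 0 %d 0 0 %s", dat, fmt,
                              record$gains[i], record$signals[1L, i],
                              record$lead_names[i]))
  }
  writeLines(lines, hea)
  v <- as.integer(t(record$signals))     # interleaved sample stream
  dat_path <- file.path(dir, dat)
  if (fmt == 16L) {
    writeBin(v, dat_path, size = 2L, endian = "little")
  } else {
    if (any(v < -2048L | v > 2047L)) {
      stop_validation("format 212 requires samples in [-2048, 2047]")
    }
    if (length(v) %% 2L == 1L) v <- c(v, 0L)
    s1 <- v[seq(1L, length(v), 2L)]
    s2 <- v[seq(2L, length(v), 2L)]
    s1 <- ifelse(s1 < 0L, s1 + 4096L, s1)
    s2 <- ifelse(s2 < 0L, s2 + 4096L, s2)
    b1 <- s1 %% 256L
    b2 <- (s1 %/% 256L) + 16L * (s2 %/% 256L)
    b3 <- s2 %% 256L
    writeBin(as.raw(as.vector(rbind(b1, b2, b3))), dat_path)
  }
  if (nrow(record$annotations) > 0L) {
    write_wfdb_annotations(record$annotations, file.path(dir, paste0(base, ".atr")))
  }
  invisible(hea)
}

write_wfdb_annotations <- function(ann, path) {
  ann <- ann[order(ann$sample), ]
  words <- integer(0)
  t_prev <- 0L
  for (i in seq_len(nrow(ann))) {
    interval <- ann$sample[i] - t_prev
    t_prev <- ann$sample[i]
    if (interval > 1023L) {
      words <- c(words, 59L * 1024L, interval %/% 65536L, interval %% 65536L)
      interval <- 0L
    }
    words <- c(words, ann$code[i] * 1024L + interval)
  }
  words <- c(words, 0L)                   # EOF marker
  bytes <- as.vector(rbind(words %% 256L, words %/% 256L))
  writeBin(as.raw(bytes), path)
}

#' Extract and scale one lead
#'
#' Returns the lead value series `v(x_t) = raw / scale` for one lead of a
#' record; the published protocol divides the raw MIT-BIH ADC samples by a
#' fixed constant of 200 (the nominal ADC gain of those records).
#'
#' @param record An `ecg_record`.
#' @param lead_index 0-based lead index (default 0, the first signal).
#' @param scale Divisor applied to raw samples (default 200).
#' @return Numeric vector of length `n_samples`.
#' @examples
#' rec <- ecggan:::new_ecg_record("r", 360, matrix(c(400L, 0L, -200L), ncol = 1))
#' extract_lead(rec, 0)  # 2, 0, -1
#' @export
extract_lead <- function(record, lead_index = 0L, scale = 200) {
  stopifnot(inherits(record, "ecg_record"))
  scale <- check_number(scale, "scale")
  if (scale == 0) stop_validation("scale must be nonzero")
  if (!is_count(lead_index, min = 0L) || lead_index >= record$n_leads) {
    stop_index("lead_index %s out of range [0, %d]",
               paste(format(lead_index), collapse = ","), record$n_leads - 1L)
  }
  as.numeric(record$signals[, lead_index + 1L]) / scale
}

#' Segment a sequence into fixed-length windows
#'
#' Windows start at sample offsets 0, `hop`, `2 hop`, ... (0-based,
#' half-open `[start, start + window_length)`); a trailing partial window is
#' discarded.  With `hop == window_length` the windows partition a prefix of
#' the input.
#'
#' @param sequence Numeric vector.
#' @param window_length Window length in samples (default 3120).
#' @param hop Offset between window starts (default `window_length`,
#'   i.e. non-overlapping).
#' @param record_id Provenance label stored with each window.
#' @return A `sequence_windows` tibble: `source_record`, `start_index`
#'   (0-based), `length`, and a `values` list-column.  Zero rows when the
#'   sequence is shorter than one window.
#' @examples
#' nrow(segment_windows(rnorm(10000), 3120))  # 3
#' @export
segment_windows <- function(sequence, window_length = 3120L, hop = window_length,
                            record_id = "") {
  window_length <- check_count(window_length, "window_length")
  hop <- check_count(hop, "hop")
  sequence <- as.numeric(sequence)
  n <- length(sequence)
  starts <- integer(0)
  if (n >= window_length) {
    starts <- seq.int(0L, n - window_length, by = hop)
  }
  out <- tibble::tibble(
    source_record = rep(record_id, length(starts)),
    start_index = as.integer(starts),
    length = rep(as.integer(window_length), length(starts)),
    values = lapply(starts, function(s) sequence[(s + 1L):(s + window_length)])
  )
  class(out) <- c("sequence_windows", class(out))
  out
}

#' Min-max normalization
#'
#' Affinely rescales a sequence by its range.  The default (`"unit"`) maps
#' the minimum to 0 and the maximum to 1, `(x - min) / (max - min)` — the
#' conventional reading of the published normalization step.  Mode
#' `"as-printed"` reproduces that step exactly as typeset,
#' `(x - max) / (max - min)`, which maps the maximum to 0 and the minimum to
#' -1.
#'
#' @param sequence Non-empty numeric vector with `max > min`.
#' @param mode `"unit"` (default) or `"as-printed"`.
#' @return Rescaled numeric vector.
#' @export
minmax_normalize <- function(sequence, mode = c("unit", "as-printed")) {
  mode <- match.arg(mode)
  x <- as.numeric(sequence)
  if (length(x) == 0L || anyNA(x)) stop_validation("sequence must be non-empty and free of NA")
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop_domain("cannot min-max normalize a constant sequence (max == min)")
  if (mode == "unit") (x - lo) / (hi - lo) else (x - hi) / (hi - lo)
}

## ---- delimited-text sequence I/O -------------------------------------------

#' Write a sequence as delimited text with a JSON sidecar
#'
#' One sample per line, full precision, plus `<path>.json` recording
#' provenance (`record_id`, `sampling_rate`, `lead_index`, `scaling`).
#'
#' @param values Numeric vector.
#' @param path Output file path.
#' @param record_id,sampling_rate,lead_index,scaling Sidecar metadata.
#' @return Invisibly, `path`.
#' @export
write_sequence <- function(values, path, record_id = "", sampling_rate = 360,
                           lead_index = 0L, scaling = 200) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(format(as.numeric(values), digits = 17, scientific = TRUE, trim = TRUE), path)
  jsonlite::write_json(
    list(record_id = record_id, sampling_rate = sampling_rate,
         lead_index = lead_index, scaling = scaling, n_samples = length(values)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a delimited-text sequence and its sidecar
#'
#' @param path File written by [write_sequence()] (or any one-sample-per-line
#'   text file; the sidecar is optional).
#' @return List with `values` (numeric) and `meta` (sidecar list, or `NULL`).
#' @export
read_sequence <- function(path) {
  if (!file.exists(path)) stop_io("sequence file not found: %s", path)
  values <- suppressWarnings(as.numeric(readLines(path, warn = FALSE)))
  if (anyNA(values)) stop_format("non-numeric content in sequence file %s", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  list(values = values, meta = meta)
}

#' Write a window set as CSV with a JSON sidecar
#'
#' Rows are windows, columns are samples (`s1..sL`), preceded by the
#' provenance columns of the `sequence_windows` tibble.
#'
#' @param windows A `sequence_windows` tibble (or window matrix).
#' @param path Output CSV path.
#' @param meta Optional named list merged into the sidecar.
#' @return Invisibly, `path`.
#' @export
write_windows <- function(windows, path, meta = list()) {
  mat <- as_window_matrix(windows)
  info <- if (is.data.frame(windows)) {
    data.frame(source_record = windows$source_record, start_index = windows$start_index)
  } else {
    data.frame(source_record = rep("", nrow(mat)), start_index = 0L)
  }
  df <- cbind(info, as.data.frame(mat))
  names(df) <- c("source_record", "start_index", paste0("s", seq_len(ncol(mat))))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(c(list(n_windows = nrow(mat), window_length = ncol(mat)), meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a window set written by [write_windows()]
#' @param path CSV path.
#' @return A `sequence_windows` tibble.
#' @export
read_windows <- function(path) {
  if (!file.exists(path)) stop_io("window file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  scols <- grepl("^s[0-9]+$", names(df))
  if (!any(scols)) stop_format("no sample columns (s1..sL) in %s", path)
  mat <- as.matrix(df[, scols, drop = FALSE])
  out <- matrix_to_windows(mat,
                           record_ids = as.character(df$source_record),
                           start_index = as.integer(df$start_index))
  class(out) <- c("sequence_windows", class(out))
  out
}
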