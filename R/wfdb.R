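# Minimal WFDB dialect: format-16 signal files (.hea + .dat) and MIT-format
# annotation files (.atr). Covers what PhysioNet-style 12-lead records need:
# gain/baseline honoured when converting to millivolts, beat/non-beat
# annotation codes, SKIP/NUM/SUB/CHN/AUX pseudo-annotations on read.

# annotation codes counted as beats (QRS marks) in the MIT code table
WFDB_BEAT_CODES <- c(1:13, 25, 30, 31, 34, 35, 37, 38, 41)

#' Write an ECG record (and optionally annotations) in WFDB format
#'
#' Writes `<record_id>.hea`, a format-16 `.dat` (16-bit little-endian,
#' interleaved) and, when annotations are given, a MIT-format `.atr`.
#'
#' @param record an [ecg_record()].
#' @param dir output directory (created if missing).
#' @param annotations optional [beat_annotations()].
#' @param gain ADC units per millivolt (default 2000, ~0.5 uV resolution).
#' @return The header path, invisibly.
#' @export
write_wfdb <- function(record, dir, annotations = NULL, gain = 2000) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rid <- record$record_id
  n_sig <- ncol(record$signal)
  dig <- round(record$signal * gain)
  dig <- pmin(pmax(dig, -32768), 32767)
  storage.mode(dig) <- "integer"
  checksums <- vapply(seq_len(n_sig), function(j) {
    s <- sum(as.double(dig[, j])) %% 65536
    as.integer(if (s > 32767) s - 65536 else s)
  }, integer(1))
  hea <- file.path(dir, paste0(rid, ".hea"))
  dat <- paste0(rid, ".dat")
  lines <- sprintf("%s %d %g %d", rid, n_sig, record$sampling_rate,
                   record$n_samples)
  for (j in seq_len(n_sig)) {
    lines <- c(lines, sprintf("%s 16 %g(0)/mV 16 0 %d %d 0 %s",
                              dat, gain, dig[1, j], checksums[j],
                              record$lead_names[j]))
  }
  writeLines(lines, hea)
  con <- file(file.path(dir, dat), "wb")
  on.exit(close(con), add = TRUE)
  interleaved <- as.integer(t(dig))
  writeBin(interleaved, con, size = 2L, endian = "little")
  if (!is.null(annotations)) {
    write_wfdb_annotations(annotations,
                           file.path(dir, paste0(rid, ".atr")))
  }
  invisible(hea)
}

parse_gain_spec <- function(tok) {
  # "gain(baseline)/units", every part optional
  units <- sub("^[^/]*/?", "", tok)
  lead <- sub("/.*$", "", tok)
  baseline <- 0
  if (grepl("\\(", lead)) {
    baseline <- as.numeric(sub("^.*\\(([-0-9.]+)\\).*$", "\\1", lead))
    lead <- sub("\\(.*$", "", lead)
  }
  gain <- as.numeric(lead)
  if (is.na(gain) || gain == 0) gain <- 200
  list(gain = gain, baseline = baseline,
       units = if (nzchar(units)) units else "mV")
}

#' Read a WFDB record
#'
#' Supports single-.dat, format-16 records. Signals are converted to
#' millivolts using the per-signal gain and baseline. When `leads` is given,
#' the returned record contains exactly those leads in that order; otherwise
#' the canonical eight-lead order (I, II, V1-V6) is applied when all eight
#' are present, else the stored order is kept.
#'
#' @param path path to the `.hea` header (extension optional).
#' @param leads optional ordered lead names to select.
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(path, leads = NULL) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    vcg_abort(sprintf("header not found: %s", hea), "vcg_io_error")
  }
  ln <- readLines(hea, warn = FALSE)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  top <- strsplit(trimws(ln[1]), "\\s+")[[1]]
  rid <- sub("/.*$", "", top[1])
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  n_samples <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig_lines <- ln[2:(1 + n_sig)]
  specs <- lapply(sig_lines, function(s) {
    tok <- strsplit(trimws(s), "\\s+")[[1]]
    fmt <- as.integer(sub("[^0-9].*$", "", tok[2]))
    g <- parse_gain_spec(if (length(tok) >= 3) tok[3] else "200")
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
      else NA_character_
    list(file = tok[1], fmt = fmt, gain = g$gain, baseline = g$baseline,
         desc = desc)
  })
  files <- unique(vapply(specs, `[[`, character(1), "file"))
  fmts <- unique(vapply(specs, `[[`, integer(1), "fmt"))
  if (length(files) != 1L || !identical(fmts, 16L)) {
    vcg_abort("only single-file format-16 records are supported",
              "vcg_io_error")
  }
  dat <- file.path(dirname(hea), files)
  raw_n <- file.info(dat)$size / 2
  vals <- readBin(dat, integer(), n = raw_n, size = 2L, endian = "little",
                  signed = TRUE)
  if (is.na(n_samples)) n_samples <- length(vals) %/% n_sig
  m <- matrix(vals[seq_len(n_samples * n_sig)], ncol = n_sig, byrow = TRUE)
  phys <- vapply(seq_len(n_sig), function(j) {
    (m[, j] - specs[[j]]$baseline) / specs[[j]]$gain
  }, numeric(n_samples))
  lead_names <- vapply(seq_len(n_sig), function(j) {
    if (!is.na(specs[[j]]$desc)) specs[[j]]$desc else sprintf("sig%d", j)
  }, character(1))
  rec <- ecg_record(phys, fs, lead_names, rid)
  if (is.null(leads) && all(KORS_LEADS %in% lead_names)) leads <- KORS_LEADS
  if (!is.null(leads)) rec <- select_leads(rec, leads)
  rec
}

#' Write beat annotations in MIT (.atr) format
#'
#' @param annotations a [beat_annotations()] (or integer vector of 0-based
#'   sample indices).
#' @param path output file path.
#' @param codes annotation code per mark (default 1, a normal beat).
#' @return `path`, invisibly.
#' @export
write_wfdb_annotations <- function(annotations, path, codes = 1L) {
  idx <- if (inherits(annotations, "beat_annotations"))
    annotations$sample_indices else as.integer(annotations)
  stopifnot(!is.unsorted(idx))
  codes <- rep_len(as.integer(codes), length(idx))
  words <- integer(0)
  prev <- 0L
  for (i in seq_along(idx)) {
    delta <- idx[i] - prev
    if (delta > 1023L) {
      words <- c(words, bitwShiftL(59L, 10L),            # SKIP
                 bitwAnd(bitwShiftR(delta, 16L), 65535L), # high 16 bits
                 bitwAnd(delta, 65535L))                  # low 16 bits
      delta <- 0L
    }
    words <- c(words, bitwOr(bitwShiftL(codes[i], 10L), delta))
    prev <- idx[i]
  }
  words <- c(words, 0L) # end of stream
  words[words > 32767L] <- words[words > 32767L] - 65536L
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  invisible(path)
}

#' Read beat annotations from a MIT (.atr) file
#'
#' Decodes the annotation stream (including SKIP/NUM/SUB/CHN/AUX
#' pseudo-annotations), keeps beat-class marks only, de-duplicates, sorts
#' and clips to `[0, n_samples)`.
#'
#' @param path annotation file path.
#' @param n_samples record length used for clipping (optional).
#' @param record_id,reference_lead passed to [beat_annotations()].
#' @return A [beat_annotations()].
#' @export
read_wfdb_annotations <- function(path, n_samples = NULL,
                                  record_id = "record",
                                  reference_lead = "II") {
  if (!file.exists(path)) {
    vcg_abort(sprintf("annotation file not found: %s", path), "vcg_io_error")
  }
  raw_n <- file.info(path)$size / 2
  w <- readBin(path, integer(), n = raw_n, size = 2L, endian = "little",
               signed = TRUE)
  w[w < 0] <- w[w < 0] + 65536L
  tcur <- 0L
  marks <- integer(0)
  mcodes <- integer(0)
  i <- 1L
  while (i <= length(w)) {
    word <- w[i]
    code <- bitwShiftR(word, 10L)
    field <- bitwAnd(word, 1023L)
    if (word == 0L) break
    if (code == 59L) { # SKIP: next two words hold a long interval
      if (i + 2L > length(w)) {
        vcg_abort("truncated SKIP in annotation stream", "vcg_parse_error")
      }
      hi <- w[i + 1L]
      lo <- w[i + 2L]
      tcur <- tcur + bitwShiftL(hi, 16L) + lo
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { # NUM / SUB / CHN: no time advance
      i <- i + 1L
      next
    }
    if (code == 63L) { # AUX: field = byte count, padded to even
      i <- i + 1L + (field + field %% 2L) %/% 2L
      next
    }
    tcur <- tcur + field
    marks <- c(marks, tcur)
    mcodes <- c(mcodes, code)
    i <- i + 1L
  }
  beats <- marks[mcodes %in% WFDB_BEAT_CODES]
  if (!is.null(n_samples)) beats <- beats[beats >= 0 & beats < n_samples]
  beat_annotations(beats, record_id, reference_lead, n_samples)
}
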