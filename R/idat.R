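# IDAT format version 3: magic "IDAT", int64 version, int32 field count,
# then a directory of (uint16 field code, int64 byte offset) pairs. All
# little-endian. Strings are length-prefixed with a 7-bit varint. Reading is
# directory-driven: unknown field codes are simply never visited, which is
# what makes the parser robust to vendor additions.

IDAT_FIELD_N       <- 1000L  # int32 number of probes
IDAT_FIELD_IDS     <- 102L   # int32[n] bead addresses
IDAT_FIELD_SD      <- 103L   # uint16[n]
IDAT_FIELD_MEAN    <- 104L   # uint16[n]
IDAT_FIELD_NBEADS  <- 107L   # uint8[n]
IDAT_FIELD_RUNINFO <- 300L   # int32 m, then m records of 5 strings
IDAT_FIELD_BARCODE <- 402L   # string
IDAT_FIELD_POSITION <- 404L  # string

#' Construct an in-memory IDAT record
#'
#' @param addresses Integer vector of bead addresses, no duplicates.
#' @param mean_intensity Integer vector of per-address mean intensities in
#'   \[0, 65535\] (the on-disk field is an unsigned 16-bit integer).
#' @param n_beads Integer vector of bead counts per address (0-255).
#' @param sd Integer vector of per-address intensity standard deviations.
#' @param barcode,position Chip barcode and position strings.
#' @param run_info Character vector of opaque run-log records.
#' @param format_version IDAT format version; only 3 is supported.
#' @return A list of class `idat_file`.
#' @export
idat_file <- function(addresses, mean_intensity,
                      n_beads = rep(10L, length(addresses)),
                      sd = rep(0L, length(addresses)),
                      barcode = "0000000000", position = "R01C01",
                      run_info = character(), format_version = 3L) {
  addresses <- as.integer(addresses)
  mean_intensity <- as.integer(round(mean_intensity))
  if (anyDuplicated(addresses)) {
    abort("duplicate addresses in IDAT record",
          class = "methylite_validation_error")
  }
  if (length(mean_intensity) != length(addresses)) {
    abort("mean_intensity must match addresses in length",
          class = "methylite_validation_error")
  }
  if (length(addresses) > 0 &&
      (min(mean_intensity) < 0 || max(mean_intensity) > 65535)) {
    abort("mean intensities must lie in [0, 65535] (uint16 on disk)",
          class = "methylite_validation_error")
  }
  if (format_version != 3L) {
    abort(paste0("unsupported IDAT format version: ", format_version),
          class = "methylite_unsupported_version_error")
  }
  structure(list(addresses = addresses,
                 mean_intensity = mean_intensity,
                 n_beads = as.integer(n_beads),
                 sd = as.integer(sd),
                 barcode = as.character(barcode),
                 position = as.character(position),
                 run_info = as.character(run_info),
                 format_version = 3L),
            class = "idat_file")
}

#' @export
print.idat_file <- function(x, ...) {
  cat(sprintf("<idat_file> %s_%s: %d addresses (format v%d)\n",
              x$barcode, x$position, length(x$addresses), x$format_version))
  invisible(x)
}

# ---- low-level byte helpers -------------------------------------------------

write_int64 <- function(con, x) {
  # files we write stay far below 2^31, so the high word is always 0/-1
  lo <- as.integer(x %% 2^32 - ifelse(x %% 2^32 >= 2^31, 2^32, 0))
  hi <- as.integer(floor(x / 2^32))
  writeBin(c(lo, hi), con, size = 4, endian = "little")
}

read_int64 <- function(con, what = "int64 field") {
  b <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  if (length(b) < 2) {
    abort(paste0("truncated ", what), class = "methylite_parse_error")
  }
  lo <- b[1] + ifelse(b[1] < 0, 2^32, 0)
  b[2] * 2^32 + lo
}

write_prefixed_string <- function(con, s) {
  bytes <- charToRaw(s)
  n <- length(bytes)
  repeat {  # 7-bit varint length
    byte <- n %% 128L
    n <- n %/% 128L
    writeBin(as.raw(byte + if (n > 0) 128L else 0L), con)
    if (n == 0) break
  }
  if (length(bytes) > 0) writeBin(bytes, con)
}

read_prefixed_string <- function(con, what = "string field") {
  n <- 0
  shift <- 0
  repeat {
    byte <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
    if (length(byte) == 0) {
      abort(paste0("truncated ", what), class = "methylite_parse_error")
    }
    n <- n + (byte %% 128L) * 2^shift
    if (byte < 128L) break
    shift <- shift + 7
  }
  if (n == 0) return("")
  bytes <- readBin(con, "raw", n = n)
  if (length(bytes) < n) {
    abort(paste0("truncated ", what), class = "methylite_parse_error")
  }
  rawToChar(bytes)
}

# ---- writer -----------------------------------------------------------------

#' Write an IDAT file (format version 3)
#'
#' Emits a minimal well-formed file readable by [read_idat()] (and by other
#' directory-driven IDAT parsers). Serialization is deterministic: the same
#' record always produces identical bytes.
#'
#' @param idat An [idat_file()].
#' @param path Output path; a `.gz` suffix gzip-compresses the file.
#' @return `path`, invisibly.
#' @export
write_idat <- function(idat, path) {
  stopifnot(inherits(idat, "idat_file"))
  if (anyDuplicated(idat$addresses)) {
    abort("duplicate addresses", class = "methylite_validation_error")
  }
  n <- length(idat$addresses)

  serialize_field <- function(code) {
    con <- rawConnection(raw(), "wb")
    on.exit(close(con))
    if (code == IDAT_FIELD_N) {
      writeBin(as.integer(n), con, size = 4, endian = "little")
    } else if (code == IDAT_FIELD_IDS) {
      writeBin(idat$addresses, con, size = 4, endian = "little")
    } else if (code == IDAT_FIELD_SD) {
      writeBin(as.integer(idat$sd), con, size = 2, endian = "little")
    } else if (code == IDAT_FIELD_MEAN) {
      writeBin(as.integer(idat$mean_intensity), con, size = 2,
               endian = "little")
    } else if (code == IDAT_FIELD_NBEADS) {
      writeBin(as.integer(pmin(idat$n_beads, 255L)), con, size = 1)
    } else if (code == IDAT_FIELD_RUNINFO) {
      writeBin(length(idat$run_info), con, size = 4, endian = "little")
      for (rec in idat$run_info) {
        write_prefixed_string(con, rec)        # RunTime slot carries the text
        for (j in 1:4) write_prefixed_string(con, "")
      }
    } else if (code == IDAT_FIELD_BARCODE) {
      write_prefixed_string(con, idat$barcode)
    } else if (code == IDAT_FIELD_POSITION) {
      write_prefixed_string(con, idat$position)
    }
    rawConnectionValue(con)
  }

  codes <- c(IDAT_FIELD_N, IDAT_FIELD_IDS, IDAT_FIELD_SD, IDAT_FIELD_MEAN,
             IDAT_FIELD_NBEADS, IDAT_FIELD_RUNINFO, IDAT_FIELD_BARCODE,
             IDAT_FIELD_POSITION)
  bodies <- lapply(codes, serialize_field)
  header_size <- 4 + 8 + 4 + length(codes) * (2 + 8)
  offsets <- header_size + cumsum(c(0, vapply(bodies, length, 0L)))[seq_along(codes)]

  con <- rawConnection(raw(), "wb")
  writeBin(charToRaw("IDAT"), con)
  write_int64(con, 3)
  writeBin(length(codes), con, size = 4, endian = "little")
  for (i in seq_along(codes)) {
    writeBin(as.integer(codes[i]), con, size = 2, endian = "little")
    write_int64(con, offsets[i])
  }
  for (b in bodies) if (length(b) > 0) writeBin(b, con)
  bytes <- rawConnectionValue(con)
  close(con)

  if (grepl("\\.gz$", path)) {
    gz <- gzfile(path, "wb")
    writeBin(bytes, gz)
    close(gz)
  } else {
    writeBin(bytes, path)
  }
  invisible(path)
}

# ---- reader -----------------------------------------------------------------

#' Read an IDAT file (format version 3)
#'
#' Parses the field directory and reads the address, mean-intensity,
#' bead-count, sd, barcode, position and run-info fields; any other field
#' code present in the directory is skipped (fields are located by their
#' directory offsets, so unknown fields never have to be understood).
#' Gzipped files are detected by their magic bytes and decompressed
#' transparently.
#'
#' @param path Path to an IDAT file, plain or gzip-compressed.
#' @return An [idat_file()].
#' @export
read_idat <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("IDAT file not found: ", path), class = "methylite_io_error")
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) >= 2 && bytes[1] == as.raw(0x1f) && bytes[2] == as.raw(0x8b)) {
    bytes <- memDecompress(bytes, type = "gzip")
  }
  if (length(bytes) < 16 || rawToChar(bytes[1:4]) != "IDAT") {
    abort(paste0("not an IDAT file (bad magic): ", path),
          class = "methylite_format_error")
  }
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  seek(con, 4)
  version <- read_int64(con, "version")
  if (version != 3) {
    abort(paste0("unsupported IDAT format version ", version, ": ", path),
          class = "methylite_unsupported_version_error")
  }
  n_fields <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(n_fields) == 0 || n_fields < 0) {
    abort("truncated field directory", class = "methylite_parse_error")
  }
  dir <- list()
  for (i in seq_len(n_fields)) {
    code <- readBin(con, "integer", n = 1, size = 2, signed = FALSE,
                    endian = "little")
    if (length(code) == 0) {
      abort("truncated field directory", class = "methylite_parse_error")
    }
    dir[[as.character(code)]] <- read_int64(con, "field directory")
  }

  field_offset <- function(code) dir[[as.character(code)]]
  read_vec <- function(code, n, size, signed, what) {
    off <- field_offset(code)
    if (is.null(off)) return(NULL)
    seek(con, off)
    v <- readBin(con, "integer", n = n, size = size, signed = signed,
                 endian = "little")
    if (length(v) < n) {
      abort(paste0("truncated field '", what, "'"),
            class = "methylite_parse_error")
    }
    v
  }

  off_n <- field_offset(IDAT_FIELD_N)
  if (is.null(off_n)) {
    abort("IDAT file lacks the probe-count field",
          class = "methylite_parse_error")
  }
  seek(con, off_n)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (length(n) == 0 || n < 0) {
    abort("truncated field 'nSNPsRead'", class = "methylite_parse_error")
  }

  addresses <- read_vec(IDAT_FIELD_IDS, n, 4, TRUE, "IlluminaID")
  if (is.null(addresses)) {
    abort("IDAT file lacks the address field", class = "methylite_parse_error")
  }
  means <- read_vec(IDAT_FIELD_MEAN, n, 2, FALSE, "Mean")
  if (is.null(means)) {
    abort("IDAT file lacks the mean-intensity field",
          class = "methylite_parse_error")
  }
  sds <- read_vec(IDAT_FIELD_SD, n, 2, FALSE, "SD") %||% rep(0L, n)
  nbeads <- read_vec(IDAT_FIELD_NBEADS, n, 1, FALSE, "NBeads") %||% rep(0L, n)

  read_string_field <- function(code, what, default) {
    off <- field_offset(code)
    if (is.null(off)) return(default)
    seek(con, off)
    read_prefixed_string(con, what)
  }
  barcode <- read_string_field(IDAT_FIELD_BARCODE, "Barcode", "")
  position <- read_string_field(IDAT_FIELD_POSITION, "Position", "")

  run_info <- character()
  off_ri <- field_offset(IDAT_FIELD_RUNINFO)
  if (!is.null(off_ri)) {
    seek(con, off_ri)
    m <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (length(m) == 1 && m >= 0) {
      run_info <- vapply(seq_len(m), function(i) {
        rec <- vapply(1:5, function(j) read_prefixed_string(con, "RunInfo"), "")
        rec[1]
      }, "")
    }
  }

  idat_file(addresses, means, n_beads = nbeads, sd = sds,
            barcode = barcode, position = position, run_info = run_info)
}

# ---- sample-level reader ----------------------------------------------------

resolve_idat_path <- function(basename, channel) {
  for (ext in c(".idat", ".idat.gz")) {
    p <- paste0(basename, "_", channel, ext)
    if (file.exists(p)) return(p)
  }
  abort(paste0("missing ", channel, " IDAT file for basename '", basename, "'"),
        class = "methylite_io_error")
}

#' Read paired Grn/Red IDAT files for a set of samples
#'
#' For each basename, `<basename>_Grn.idat` and `<basename>_Red.idat`
#' (optionally `.gz`) are read and all samples are aligned on the union of
#' addresses required by the manifest and controls. Addresses present in the
#' files but not required are dropped with a single warning; a required
#' address missing from any sample is an error naming the addresses.
#'
#' @param basenames Character vector of path prefixes.
#' @param manifest A [probe_manifest()].
#' @param controls Optional [control_manifest()].
#' @param sample_ids Sample names; defaults to `basename(basenames)`.
#' @return A [raw_intensity_set()].
#' @export
read_metharray <- function(basenames, manifest, controls = NULL,
                           sample_ids = base::basename(basenames)) {
  required <- manifest_addresses(manifest)
  if (!is.null(controls)) required <- c(required, controls$address)
  required <- sort(unique(required))

  grn <- matrix(NA_real_, length(required), length(basenames))
  red <- grn
  dropped_any <- FALSE
  for (i in seq_along(basenames)) {
    for (channel in c("Grn", "Red")) {
      idat <- read_idat(resolve_idat_path(basenames[i], channel))
      idx <- match(required, idat$addresses)
      if (anyNA(idx)) {
        abort(paste0("sample '", sample_ids[i], "' (", channel,
                     ") lacks required address(es): ",
                     paste(head(required[is.na(idx)], 10), collapse = ", ")),
              class = "methylite_extraction_error")
      }
      if (length(idat$addresses) > length(required)) dropped_any <- TRUE
      vals <- idat$mean_intensity[idx]
      if (channel == "Grn") grn[, i] <- vals else red[, i] <- vals
    }
  }
  if (dropped_any) {
    warn("addresses not required by the manifest/controls were dropped")
  }
  raw_intensity_set(required, grn, red, sample_ids)
}
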