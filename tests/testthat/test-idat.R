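# In-test byte-level writer, independent of write_idat(), used to craft
# files with unknown fields and shuffled directories.
craft_idat_bytes <- function(fields) {
  int64_bytes <- function(x) {
    writeBin(c(as.integer(x %% 2^32), as.integer(x %/% 2^32)),
             raw(), size = 4, endian = "little")
  }
  header <- c(charToRaw("IDAT"), int64_bytes(3),
              writeBin(length(fields), raw(), size = 4, endian = "little"))
  dir_size <- length(fields) * 10
  offset <- length(header) + dir_size
  dir_bytes <- raw(0)
  body <- raw(0)
  for (f in fields) {
    dir_bytes <- c(dir_bytes,
                   writeBin(as.integer(f$code), raw(), size = 2,
                            endian = "little"),
                   int64_bytes(offset))
    body <- c(body, f$bytes)
    offset <- offset + length(f$bytes)
  }
  c(header, dir_bytes, body)
}

le <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                 endian = "little")
pstr <- function(s) c(as.raw(nchar(s)), charToRaw(s))

std_fields <- function(addresses, means) {
  list(list(code = 1000L, bytes = le(length(addresses), 4)),
       list(code = 102L, bytes = le(addresses, 4)),
       list(code = 104L, bytes = le(means, 2)),
       list(code = 402L, bytes = pstr("123456789")),
       list(code = 404L, bytes = pstr("R01C01")))
}

test_that("IDAT files round-trip field by field, plain and gzipped", {
  set.seed(9)
  x <- idat_file(sample.int(1e6, 1000), sample.int(65535, 1000) - 1L,
                 n_beads = sample.int(30, 1000, replace = TRUE),
                 sd = sample.int(500, 1000, replace = TRUE),
                 barcode = "201234567890", position = "R02C01",
                 run_info = c("scan", "decode"))
  for (ext in c(".idat", ".idat.gz")) {
    path <- withr::local_tempfile(fileext = ext)
    write_idat(x, path)
    y <- read_idat(path)
    expect_identical(y$addresses, x$addresses)
    expect_identical(y$mean_intensity, x$mean_intensity)
    expect_identical(y$n_beads, x$n_beads)
    expect_identical(y$sd, x$sd)
    expect_identical(y$barcode, x$barcode)
    expect_identical(y$position, x$position)
    expect_identical(y$run_info, x$run_info)
  }
})

test_that("serialization is deterministic and write-read-write is byte-stable", {
  x <- idat_file(1:1000, rep(500L, 1000))
  p1 <- withr::local_tempfile(fileext = ".idat")
  p2 <- withr::local_tempfile(fileext = ".idat")
  p3 <- withr::local_tempfile(fileext = ".idat")
  write_idat(x, p1)
  write_idat(x, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  write_idat(read_idat(p1), p3)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p3, "raw", file.size(p3)))
})

test_that("an empty address list round-trips", {
  p <- withr::local_tempfile(fileext = ".idat")
  write_idat(idat_file(integer(0), integer(0)), p)
  y <- read_idat(p)
  expect_length(y$addresses, 0)
  expect_length(y$mean_intensity, 0)
})

test_that("unknown directory fields are skipped and order does not matter", {
  addresses <- c(11L, 22L, 33L)
  means <- c(100L, 200L, 300L)
  fields <- std_fields(addresses, means)
  fuzzed <- append(fields, list(list(code = 999L,
                                     bytes = as.raw(sample(0:255, 40)))), 2)
  shuffled <- fuzzed[c(4, 1, 6, 3, 2, 5)]
  for (layout in list(fields, fuzzed, shuffled)) {
    p <- withr::local_tempfile(fileext = ".idat")
    writeBin(craft_idat_bytes(layout), p)
    y <- read_idat(p)
    expect_identical(y$addresses, addresses)
    expect_identical(y$mean_intensity, means)
  }
})

test_that("malformed files raise specific errors", {
  p <- withr::local_tempfile(fileext = ".idat")
  writeBin(charToRaw("NOPEnope not an idat"), p)
  expect_error(read_idat(p), class = "methylite_format_error")

  bytes <- craft_idat_bytes(std_fields(1:3, 4:6))
  bytes[5] <- as.raw(7)  # version 7
  writeBin(bytes, p)
  expect_error(read_idat(p), class = "methylite_unsupported_version_error")

  bytes <- craft_idat_bytes(std_fields(1:3, 4:6))
  writeBin(bytes[seq_len(length(bytes) - 10)], p)  # truncate the tail
  expect_error(read_idat(p), regexp = "truncated",
               class = "methylite_parse_error")

  expect_error(write_idat(idat_file(1:3, c(1L, 2L, 70000L)), p),
               class = "methylite_validation_error")
})

test_that("read_metharray aligns fixture sample pairs on required addresses", {
  cfg <- sim_config(seed = 13, n_samples = 3)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(cfg, dir)
  man <- load_manifest(paths$manifest_a, platform = "450K")
  ctl <- load_controls(paths$controls)
  raw <- read_metharray(paths$idat_basenames, man, ctl)
  expect_length(raw$sample_ids, 3)
  expect_setequal(raw$addresses, sort(c(manifest_addresses(man), ctl$address)))

  # a missing channel file errors with the basename in the message
  file.remove(paste0(paths$idat_basenames[2], "_Grn.idat"))
  expect_error(read_metharray(paths$idat_basenames, man, ctl),
               regexp = basename(paths$idat_basenames[2]),
               class = "methylite_io_error")
})

test_that("mixed gzipped/plain inputs and CSV ingestion agree exactly", {
  cfg <- sim_config(seed = 17, n_samples = 2)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(cfg, dir)
  man <- load_manifest(paths$manifest_a, platform = "450K")
  ctl <- load_controls(paths$controls)
  plain <- read_metharray(paths$idat_basenames, man, ctl)

  # gzip one channel of one sample in place
  target <- paste0(paths$idat_basenames[1], "_Grn.idat")
  bytes <- readBin(target, "raw", file.size(target))
  gz <- gzfile(paste0(target, ".gz"), "wb")
  writeBin(bytes, gz)
  close(gz)
  file.remove(target)
  mixed <- read_metharray(paths$idat_basenames, man, ctl)
  expect_identical(mixed$grn, plain$grn)
  expect_identical(mixed$red, plain$red)

  # CSV fallback carries the same matrix (samples named s1/s2 there,
  # by IDAT basename here)
  from_csv <- read_intensity_csv(base = file.path(dir, "intensities"))
  expect_identical(from_csv$addresses, plain$addresses)
  expect_equal(unname(from_csv$grn), unname(plain$grn),
               ignore_attr = TRUE)
  expect_equal(unname(from_csv$red), unname(plain$red),
               ignore_attr = TRUE)
})
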