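#' Construct an address-level raw intensity set
#'
#' Holds mean bead intensities per address and sample for both color
#' channels, prior to any manifest mapping. This is the in-memory equivalent
#' of a set of paired Grn/Red IDAT files.
#'
#' @param addresses Integer vector of bead addresses (unique).
#' @param grn,red Numeric matrices (address x sample) of non-negative, finite
#'   mean intensities, sharing shape and address order.
#' @param sample_ids Character vector of sample identifiers (one per column).
#' @return A list of class `raw_intensity_set` with elements `addresses`,
#'   `sample_ids`, `grn`, `red`.
#' @export
raw_intensity_set <- function(addresses, grn, red, sample_ids = colnames(grn)) {
  addresses <- as.integer(addresses)
  grn <- as.matrix(grn)
  red <- as.matrix(red)
  if (anyDuplicated(addresses)) {
    abort("duplicate addresses in raw intensity set",
          class = "methylite_validation_error")
  }
  if (!identical(dim(grn), dim(red))) {
    abort("grn and red matrices must share shape",
          class = "methylite_validation_error")
  }
  if (nrow(grn) != length(addresses)) {
    abort("matrix rows must match address vector",
          class = "methylite_validation_error")
  }
  if (is.null(sample_ids)) {
    sample_ids <- paste0("sample", seq_len(ncol(grn)))
  }
  if (anyDuplicated(sample_ids)) {
    abort("duplicate sample_ids", class = "methylite_validation_error")
  }
  if (any(!is.finite(grn)) || any(!is.finite(red)) ||
      any(grn < 0) || any(red < 0)) {
    abort("intensities must be finite and >= 0",
          class = "methylite_validation_error")
  }
  dimnames(grn) <- dimnames(red) <- list(as.character(addresses), sample_ids)
  structure(list(addresses = addresses, sample_ids = sample_ids,
                 grn = grn, red = red),
            class = "raw_intensity_set")
}

#' @export
print.raw_intensity_set <- function(x, ...) {
  cat(sprintf("<raw_intensity_set> %d addresses x %d samples\n",
              length(x$addresses), length(x$sample_ids)))
  invisible(x)
}

#' Subset a raw intensity set by sample
#' @param raw A [raw_intensity_set()].
#' @param samples Character vector of sample ids (or integer indices).
#' @return A [raw_intensity_set()] restricted to those samples.
#' @export
subset_samples <- function(raw, samples) {
  stopifnot(inherits(raw, "raw_intensity_set"))
  raw_intensity_set(raw$addresses,
                    raw$grn[, samples, drop = FALSE],
                    raw$red[, samples, drop = FALSE],
                    colnames(raw$grn[, samples, drop = FALSE]))
}

#' Write a raw intensity set to a CSV file pair
#'
#' Writes `<base>_Grn.csv` and `<base>_Red.csv`, each with an `address`
#' first column and one column per sample.
#'
#' @param raw A [raw_intensity_set()].
#' @param base Path prefix for the two files.
#' @return Character vector of the two file paths, invisibly.
#' @export
write_intensity_csv <- function(raw, base) {
  stopifnot(inherits(raw, "raw_intensity_set"))
  paths <- paste0(base, c("_Grn.csv", "_Red.csv"))
  for (i in 1:2) {
    mat <- if (i == 1) raw$grn else raw$red
    df <- data.frame(address = raw$addresses, mat, check.names = FALSE)
    write.csv(df, paths[i], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Read a raw intensity set from CSV
#'
#' Two layouts are accepted: a file pair `<base>_Grn.csv` / `<base>_Red.csv`
#' (pass `base`), or a single long file with a `channel` column (pass
#' `path`). In both layouts the first column must be `address` and remaining
#' columns are samples.
#'
#' @param base Path prefix of a `_Grn`/`_Red` CSV pair.
#' @param path Alternatively, a single CSV with a `channel` column
#'   (`"Grn"`/`"Red"`).
#' @return A [raw_intensity_set()].
#' @export
read_intensity_csv <- function(base = NULL, path = NULL) {
  if (!is.null(base)) {
    paths <- paste0(base, c("_Grn.csv", "_Red.csv"))
    for (p in paths) {
      if (!file.exists(p)) {
        abort(paste0("intensity file not found: ", p),
              class = "methylite_io_error")
      }
    }
    g <- read.csv(paths[1], check.names = FALSE)
    r <- read.csv(paths[2], check.names = FALSE)
    if (names(g)[1] != "address" || names(r)[1] != "address") {
      abort("intensity CSV must have 'address' as first column",
            class = "methylite_format_error")
    }
    if (!identical(g$address, r$address)) {
      abort("Grn and Red files disagree on addresses",
            class = "methylite_validation_error")
    }
    return(raw_intensity_set(g$address,
                             as.matrix(g[-1]), as.matrix(r[-1]),
                             names(g)[-1]))
  }
  if (is.null(path)) abort("supply either base or path")
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("address", "channel") %in% names(df))) {
    abort("long intensity CSV needs 'address' and 'channel' columns",
          class = "methylite_format_error")
  }
  g <- df[df$channel == "Grn", setdiff(names(df), "channel")]
  r <- df[df$channel == "Red", setdiff(names(df), "channel")]
  if (!identical(g$address, r$address)) {
    abort("Grn and Red blocks disagree on addresses",
          class = "methylite_validation_error")
  }
  raw_intensity_set(g$address, as.matrix(g[-1]), as.matrix(r[-1]),
                    names(g)[-1])
}
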