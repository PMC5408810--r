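#' Construct a probe manifest
#'
#' A probe manifest describes an array platform: one row per probe, giving its
#' Infinium design type, color channel and bead addresses. Type I probes use
#' two bead addresses (`address_A` = unmethylated, `address_B` = methylated)
#' read in a single color channel; Type II probes use one address
#' (`address_A`) read in both channels.
#'
#' @param probes A data frame with columns `probe_id`, `design_type`
#'   (`"I"`/`"II"`), `channel` (`"Grn"`/`"Red"` for Type I, `"Both"` for
#'   Type II), `address_A` (integer), `address_B` (integer, `NA` for
#'   Type II) and `chromosome` (e.g. `"chr1"`, `"chrX"`). Extra columns are
#'   preserved but ignored.
#' @param platform One of `"450K"`, `"EPIC"`, `"VIRTUAL"`.
#' @param behaves_as For `platform = "VIRTUAL"`, the platform the manifest
#'   should be treated as downstream (`"450K"` or `"EPIC"`).
#'
#' @return A tibble of class `probe_manifest` with attributes `platform` and
#'   (for virtual arrays) `behaves_as`.
#' @export
#' @examples
#' probe_manifest(
#'   data.frame(
#'     probe_id = c("cg01", "cg02"),
#'     design_type = c("I", "II"),
#'     channel = c("Grn", "Both"),
#'     address_A = c(100L, 300L),
#'     address_B = c(101L, NA),
#'     chromosome = "chr1"
#'   ),
#'   platform = "450K"
#' )
probe_manifest <- function(probes, platform = c("450K", "EPIC", "VIRTUAL"),
                           behaves_as = NULL) {
  platform <- match.arg(platform)
  probes <- as_tibble(probes)
  required <- c("probe_id", "design_type", "channel", "address_A",
                "address_B", "chromosome")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0) {
    abort(paste0("manifest is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "methylite_format_error")
  }
  probes$probe_id <- as.character(probes$probe_id)
  probes$design_type <- as.character(probes$design_type)
  probes$channel <- as.character(probes$channel)
  probes$address_A <- as.integer(probes$address_A)
  probes$address_B <- as.integer(probes$address_B)
  probes$chromosome <- as.character(probes$chromosome)
  out <- structure(probes,
                   class = c("probe_manifest", class(probes)),
                   platform = platform,
                   behaves_as = if (platform == "VIRTUAL") {
                     match.arg(behaves_as, c("450K", "EPIC"))
                   })
  validate_probe_manifest(out)
  out
}

validate_probe_manifest <- function(m) {
  if (anyDuplicated(m$probe_id)) {
    abort("duplicate probe_id values in manifest",
          class = "methylite_validation_error")
  }
  if (!all(m$design_type %in% c("I", "II"))) {
    abort("design_type must be 'I' or 'II'",
          class = "methylite_validation_error")
  }
  ii <- m$design_type == "II"
  if (any(!is.na(m$address_B[ii]))) {
    abort("Type II probes must not carry an address_B",
          class = "methylite_validation_error")
  }
  if (any(m$channel[ii] != "Both")) {
    abort("Type II probes must have channel 'Both'",
          class = "methylite_validation_error")
  }
  if (any(is.na(m$address_B[!ii]))) {
    abort("Type I probes require an address_B",
          class = "methylite_validation_error")
  }
  if (!all(m$channel[!ii] %in% c("Grn", "Red"))) {
    abort("Type I probes must have channel 'Grn' or 'Red'",
          class = "methylite_validation_error")
  }
  addr <- manifest_addresses(m)
  if (anyDuplicated(addr)) {
    dup <- unique(addr[duplicated(addr)])
    abort(paste0("duplicate bead address(es) in manifest: ",
                 paste(head(dup, 5), collapse = ", ")),
          class = "methylite_validation_error")
  }
  invisible(m)
}

#' All bead addresses used by a manifest
#' @param m A [probe_manifest()].
#' @return Integer vector of addresses (A addresses, then non-missing B).
#' @export
manifest_addresses <- function(m) {
  c(m$address_A, m$address_B[!is.na(m$address_B)])
}

#' Platform identifier of a dataset or manifest
#' @param x A `probe_manifest`, `probe_signal_set` or `methyl_set`.
#' @return Character scalar, one of `"450K"`, `"EPIC"`, `"VIRTUAL"`.
#' @export
platform_id <- function(x) {
  if (inherits(x, "probe_manifest")) return(attr(x, "platform"))
  if (!is.null(x$manifest)) return(attr(x$manifest, "platform"))
  abort("no platform information in object")
}

#' Read a probe manifest from CSV
#'
#' The CSV must have a header row with at least the columns documented in
#' [probe_manifest()]; unknown extra columns are preserved but ignored.
#'
#' @param path Path to a UTF-8 CSV file.
#' @inheritParams probe_manifest
#' @return A [probe_manifest()].
#' @export
load_manifest <- function(path, platform = c("450K", "EPIC", "VIRTUAL"),
                          behaves_as = NULL) {
  if (!file.exists(path)) {
    abort(paste0("manifest file not found: ", path),
          class = "methylite_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("address_B" %in% names(df)) {
    df$address_B[df$address_B %in% c("", "NA")] <- NA
  }
  probe_manifest(df, platform = platform, behaves_as = behaves_as)
}

#' Write a probe manifest to CSV
#' @param m A [probe_manifest()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  write.csv(as.data.frame(m), path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct a control-probe manifest
#'
#' Normalization controls are built-in bead types whose extension base
#' determines their expected channel: C/G extension probes measure in the
#' green channel, A/T extension probes in the red channel. Their average
#' intensities drive dye-bias equalization.
#'
#' @param controls Data frame with columns `address` (integer),
#'   `control_type` (free text, e.g. `"NORM_C"`) and `expected_channel`
#'   (`"Grn"` or `"Red"`).
#' @return A tibble of class `control_manifest`.
#' @export
control_manifest <- function(controls) {
  controls <- as_tibble(controls)
  required <- c("address", "control_type", "expected_channel")
  missing_cols <- setdiff(required, names(controls))
  if (length(missing_cols) > 0) {
    abort(paste0("control manifest is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "methylite_format_error")
  }
  controls$address <- as.integer(controls$address)
  controls$control_type <- as.character(controls$control_type)
  controls$expected_channel <- as.character(controls$expected_channel)
  if (anyDuplicated(controls$address)) {
    abort("duplicate control addresses", class = "methylite_validation_error")
  }
  if (!all(controls$expected_channel %in% c("Grn", "Red"))) {
    abort("expected_channel must be 'Grn' or 'Red'",
          class = "methylite_validation_error")
  }
  for (ch in c("Grn", "Red")) {
    if (!any(controls$expected_channel == ch)) {
      abort(paste0("need at least one ", ch, "-measuring control"),
            class = "methylite_validation_error")
    }
  }
  structure(controls, class = c("control_manifest", class(controls)))
}

#' Read a control-probe manifest from CSV
#' @param path Path to a UTF-8 CSV with columns `address`, `control_type`,
#'   `expected_channel`.
#' @return A [control_manifest()].
#' @export
load_controls <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("control manifest file not found: ", path),
          class = "methylite_io_error")
  }
  control_manifest(read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat(sprintf("<probe_manifest> platform %s%s: %d probes (%d Type I, %d Type II)\n",
              attr(x, "platform"),
              if (!is.null(attr(x, "behaves_as"))) {
                paste0(" (behaves as ", attr(x, "behaves_as"), ")")
              } else "",
              nrow(x), sum(x$design_type == "I"), sum(x$design_type == "II")))
  NextMethod()
}
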