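#' Extract probe-level signals (including out-of-band) from raw intensities
#'
#' Maps address-level intensities onto probes using the manifest:
#' * Type I Grn probe: meth = Grn at `address_B`, unmeth = Grn at `address_A`;
#' * Type I Red probe: meth = Red at `address_B`, unmeth = Red at `address_A`;
#' * Type II probe: meth = Grn at `address_A`, unmeth = Red at `address_A`.
#'
#' Out-of-band (OOB) signals are the Type I probe intensities read in the
#' *opposite* channel: `oob_grn` holds Grn-channel intensities at all (A and
#' B) addresses of Type I Red probes, `oob_red` the Red-channel intensities
#' at all addresses of Type I Grn probes. Because an OOB measurement carries
#' no target signal, these are pure background draws, exploited by the Noob
#' background model.
#'
#' @param raw A [raw_intensity_set()] containing every manifest address.
#' @param manifest A [probe_manifest()].
#' @param controls Optional [control_manifest()]; when supplied, control
#'   intensities are carried along (`ctrl_grn`, `ctrl_red`) so that dye-bias
#'   correction needs no further access to the raw data.
#' @return A list of class `probe_signal_set` with elements `manifest`,
#'   `sample_ids`, `meth`, `unmeth` (probe x sample), `oob_grn`, `oob_red`
#'   (rows keyed `<probe_id>.A` / `<probe_id>.B`), and, when controls were
#'   given, `controls`, `ctrl_grn`, `ctrl_red`.
#' @export
extract_signals <- function(raw, manifest, controls = NULL) {
  stopifnot(inherits(raw, "raw_intensity_set"),
            inherits(manifest, "probe_manifest"))
  needed <- manifest_addresses(manifest)
  if (!is.null(controls)) {
    overlap <- intersect(controls$address, needed)
    if (length(overlap) > 0) {
      abort("control addresses overlap probe addresses",
            class = "methylite_validation_error")
    }
    needed <- c(needed, controls$address)
  }
  missing_addr <- setdiff(needed, raw$addresses)
  if (length(missing_addr) > 0) {
    abort(paste0("manifest address(es) absent from raw data: ",
                 paste(head(missing_addr, 10), collapse = ", "),
                 if (length(missing_addr) > 10) " ..."),
          class = "methylite_extraction_error")
  }

  key <- function(a) as.character(a)
  g <- raw$grn
  r <- raw$red
  n_s <- length(raw$sample_ids)
  is_ii <- manifest$design_type == "II"
  is_ig <- manifest$design_type == "I" & manifest$channel == "Grn"
  is_ir <- manifest$design_type == "I" & manifest$channel == "Red"

  meth <- matrix(NA_real_, nrow(manifest), n_s,
                 dimnames = list(manifest$probe_id, raw$sample_ids))
  unmeth <- meth
  meth[is_ig, ] <- g[key(manifest$address_B[is_ig]), , drop = FALSE]
  unmeth[is_ig, ] <- g[key(manifest$address_A[is_ig]), , drop = FALSE]
  meth[is_ir, ] <- r[key(manifest$address_B[is_ir]), , drop = FALSE]
  unmeth[is_ir, ] <- r[key(manifest$address_A[is_ir]), , drop = FALSE]
  meth[is_ii, ] <- g[key(manifest$address_A[is_ii]), , drop = FALSE]
  unmeth[is_ii, ] <- r[key(manifest$address_A[is_ii]), , drop = FALSE]

  oob_rows <- function(idx) {
    c(paste0(manifest$probe_id[idx], ".A"), paste0(manifest$probe_id[idx], ".B"))
  }
  oob_addr <- function(idx) c(manifest$address_A[idx], manifest$address_B[idx])
  oob_grn <- g[key(oob_addr(is_ir)), , drop = FALSE]
  rownames(oob_grn) <- oob_rows(is_ir)
  oob_red <- r[key(oob_addr(is_ig)), , drop = FALSE]
  rownames(oob_red) <- oob_rows(is_ig)

  out <- structure(list(manifest = manifest, sample_ids = raw$sample_ids,
                        meth = meth, unmeth = unmeth,
                        oob_grn = oob_grn, oob_red = oob_red),
                   class = "probe_signal_set")
  if (!is.null(controls)) {
    out$controls <- controls
    out$ctrl_grn <- g[key(controls$address), , drop = FALSE]
    out$ctrl_red <- r[key(controls$address), , drop = FALSE]
  }
  out
}

#' @export
print.probe_signal_set <- function(x, ...) {
  cat(sprintf(
    "<probe_signal_set> %d probes x %d samples (oob: %d Grn, %d Red rows)\n",
    nrow(x$meth), length(x$sample_ids), nrow(x$oob_grn), nrow(x$oob_red)))
  invisible(x)
}

# channel each probe's meth / unmeth signal is measured in
signal_channels <- function(manifest) {
  meth_ch <- ifelse(manifest$design_type == "II", "Grn", manifest$channel)
  unmeth_ch <- ifelse(manifest$design_type == "II", "Red", manifest$channel)
  list(meth = meth_ch, unmeth = unmeth_ch)
}
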