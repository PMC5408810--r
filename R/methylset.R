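#' Construct a methylation signal set
#'
#' Probe-level methylated / unmethylated signal matrices plus an ordered log
#' of every preprocessing step applied, so a dataset always carries its own
#' provenance.
#'
#' @param manifest A [probe_manifest()].
#' @param meth,unmeth Numeric matrices (probe x sample), finite and >= 0,
#'   rows matching the manifest probe set.
#' @param log List of preprocessing records, each `list(step = , params = )`.
#' @return A list of class `methyl_set`.
#' @export
methyl_set <- function(manifest, meth, unmeth, log = list()) {
  meth <- as.matrix(meth)
  unmeth <- as.matrix(unmeth)
  if (!identical(dim(meth), dim(unmeth))) {
    abort("meth and unmeth must share shape",
          class = "methylite_validation_error")
  }
  if (nrow(meth) != nrow(manifest) ||
      !identical(rownames(meth), manifest$probe_id)) {
    abort("signal rows must match the manifest probe set",
          class = "methylite_validation_error")
  }
  if (any(!is.finite(meth)) || any(!is.finite(unmeth)) ||
      any(meth < 0) || any(unmeth < 0)) {
    abort("signals must be finite and >= 0",
          class = "methylite_validation_error")
  }
  structure(list(manifest = manifest, meth = meth, unmeth = unmeth,
                 log = log),
            class = "methyl_set")
}

#' @export
print.methyl_set <- function(x, ...) {
  cat(sprintf("<methyl_set> %d probes x %d samples; preprocessing: %s\n",
              nrow(x$meth), ncol(x$meth),
              if (length(x$log) == 0) "none" else
                paste(vapply(x$log, function(s) s$step, ""), collapse = " -> ")))
  invisible(x)
}

log_step <- function(m, step, params = list()) {
  m$log <- c(m$log, list(list(step = step, params = params)))
  m
}

#' Create a methyl_set with no normalization
#'
#' Simply promotes in-band signals to the methylated/unmethylated channels,
#' the "no normalization" baseline.
#'
#' @param signals A [extract_signals()] result.
#' @return A [methyl_set()] whose log records the `raw` step.
#' @export
preprocess_raw <- function(signals) {
  stopifnot(inherits(signals, "probe_signal_set"))
  m <- methyl_set(signals$manifest, signals$meth, signals$unmeth)
  log_step(m, "raw")
}

#' Beta values (methylation fractions)
#'
#' `beta = meth / (meth + unmeth + offset)`. With `offset = 0` and both
#' signals zero the ratio is 0/0; by convention this returns 0 (empty signal
#' treated as unmethylated-unknown) with a warning.
#'
#' @param m A [methyl_set()], or anything with `meth`/`unmeth` matrices.
#' @param offset Non-negative stabilizing offset, default 100 (the
#'   conventional Infinium choice).
#' @return A probe x sample matrix in \[0, 1\] with attribute `offset`.
#' @export
get_beta <- function(m, offset = 100) {
  if (!is.numeric(offset) || length(offset) != 1 || offset < 0) {
    abort("offset must be a non-negative scalar",
          class = "methylite_argument_error")
  }
  tot <- m$meth + m$unmeth + offset
  beta <- m$meth / tot
  if (offset == 0 && any(tot == 0)) {
    warn("0/0 Beta values (meth = unmeth = 0 with offset 0) set to 0")
    beta[tot == 0] <- 0
  }
  attr(beta, "offset") <- offset
  beta
}

#' M-values (log2 methylation ratios)
#'
#' `log2((meth + pseudocount) / (unmeth + pseudocount))`; the
#' variance-stabilized companion statistic to Beta.
#'
#' @param m A [methyl_set()].
#' @param pseudocount Positive stabilizing constant, default 100.
#' @return A probe x sample matrix of M-values.
#' @export
get_mvalue <- function(m, pseudocount = 100) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("pseudocount must be a positive scalar",
          class = "methylite_argument_error")
  }
  log2((m$meth + pseudocount) / (m$unmeth + pseudocount))
}

#' @export
tidy.methyl_set <- function(x, offset = 100, ...) {
  beta <- get_beta(x, offset = offset)
  out <- tibble(
    probe_id = rep(rownames(x$meth), times = ncol(x$meth)),
    sample = rep(colnames(x$meth), each = nrow(x$meth)),
    meth = as.vector(x$meth),
    unmeth = as.vector(x$unmeth),
    beta = as.vector(beta)
  )
  dplyr::left_join(out,
                   dplyr::select(as_tibble(x$manifest),
                                 "probe_id", "design_type", "chromosome"),
                   by = "probe_id")
}

#' @export
glance.methyl_set <- function(x, ...) {
  tibble(
    n_probes = nrow(x$meth),
    n_samples = ncol(x$meth),
    platform = platform_id(x),
    steps = paste(vapply(x$log, function(s) s$step, ""), collapse = ";")
  )
}
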