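#' Estimate normal-exponential convolution parameters from out-of-band probes
#'
#' The background model treats an observed intensity as `X = S + B` with true
#' signal `S ~ Exponential(mean alpha)` and optical/background noise
#' `B ~ Normal(mu, sigma^2)`. Out-of-band (OOB) measurements contain no
#' target signal, so they are direct draws from the background: `(mu, sigma)`
#' are estimated as a robust location/scale of the OOB distribution by joint
#' Huber M-estimation (Huber's Proposal 2, tuning constant `k`), and
#' `alpha` as the robust location of the in-band foreground minus `mu`,
#' floored at `alpha_floor`.
#'
#' The Huber location of a skewed exponential-plus-normal foreground sits
#' below its mean, so `alpha` is estimated with a moderate negative bias
#' (roughly 10-15 percent when signal dominates background); this is a
#' property of the robust estimator, accepted in exchange for insensitivity
#' to hot beads. `method = "mean"` switches to the plain mean/sd for oracle
#' comparisons.
#'
#' @param foreground Numeric vector of in-band intensities (nonempty).
#' @param oob Numeric vector of OOB intensities; at least `oob_floor` values.
#' @param method `"huber"` (default) or `"mean"`.
#' @param oob_floor Minimum number of OOB values required (default 30).
#' @param alpha_floor Lower bound for `alpha` in intensity units (default 10).
#' @param k Huber tuning constant (default 1.5).
#' @param tol Relative convergence tolerance of the Huber iteration.
#' @return A list of class `normexp_params` with `mu`, `sigma`, `alpha`.
#' @export
estimate_normexp_params <- function(foreground, oob,
                                    method = c("huber", "mean"),
                                    oob_floor = 30, alpha_floor = 10,
                                    k = 1.5, tol = 1e-6) {
  method <- match.arg(method)
  foreground <- foreground[is.finite(foreground)]
  oob <- oob[is.finite(oob)]
  if (length(foreground) == 0) {
    abort("empty foreground vector", class = "methylite_estimation_error")
  }
  if (length(oob) < oob_floor) {
    abort(paste0("need at least ", oob_floor, " OOB values, got ",
                 length(oob)),
          class = "methylite_estimation_error")
  }
  if (stats::sd(oob) == 0) {
    abort("zero-variance OOB distribution",
          class = "methylite_estimation_error")
  }
  if (method == "huber") {
    h <- MASS::hubers(oob, k = k, tol = tol)
    mu <- h$mu
    sigma <- h$s
    fg_loc <- MASS::hubers(foreground, k = k, tol = tol)$mu
  } else {
    mu <- mean(oob)
    sigma <- stats::sd(oob)
    fg_loc <- mean(foreground)
  }
  if (!is.finite(sigma) || sigma <= 0) {
    abort("degenerate OOB scale estimate",
          class = "methylite_estimation_error")
  }
  structure(list(mu = mu, sigma = sigma,
                 alpha = max(fg_loc - mu, alpha_floor),
                 method = method),
            class = "normexp_params")
}

#' @export
print.normexp_params <- function(x, ...) {
  cat(sprintf("<normexp_params> mu = %.2f, sigma = %.2f, alpha = %.2f (%s)\n",
              x$mu, x$sigma, x$alpha, x$method))
  invisible(x)
}

#' Background-corrected signal under the normal-exponential model
#'
#' Returns the posterior mean `E[S | X = x]` under `X = S + B`,
#' `S ~ Exp(mean alpha)`, `B ~ N(mu, sigma^2)`. The posterior of `S` is a
#' normal with mean `m = x - mu - sigma^2/alpha` and sd `sigma`, truncated to
#' `(0, Inf)`, so
#' `E[S|X] = m + sigma * phi(m/sigma) / Phi(m/sigma)`
#' with standard-normal density/cdf `phi`, `Phi`. The Mills ratio is
#' evaluated in log space, which keeps the result finite, strictly positive
#' and accurate even for `m/sigma` far below -10.
#'
#' @param params A [estimate_normexp_params()] result (or any list with
#'   `mu`, `sigma`, `alpha`).
#' @param x Numeric vector of observed intensities.
#' @return Numeric vector of corrected intensities, strictly positive.
#' @export
normexp_signal <- function(params, x) {
  mu <- params$mu
  sigma <- params$sigma
  alpha <- params$alpha
  if (!is.finite(mu) || !is.finite(sigma) || sigma <= 0 ||
      !is.finite(alpha) || alpha <= 0) {
    abort("invalid normexp parameters", class = "methylite_argument_error")
  }
  m <- x - mu - sigma^2 / alpha
  z <- m / sigma
  mills <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
  out <- m + sigma * mills
  # deep-background guard: the exact expression is positive but can round to
  # <= 0 in double precision around z ~ -1e8; clamp to a tiny positive value
  pmax(out, .Machine$double.xmin)
}

#' Noob background correction of a probe signal set
#'
#' Per sample and per color channel, fits the normal-exponential background
#' model to (all in-band signals measured in that channel, all OOB signals
#' of that channel) and replaces every in-band signal by its posterior-mean
#' corrected value plus `offset`. Type I probes are corrected with their own
#' channel's fit; Type II probes use the Grn fit for the methylated and the
#' Red fit for the unmethylated signal. Each sample is processed using only
#' its own column, so results are independent of batch composition.
#'
#' @param signals A [extract_signals()] result with nonempty OOB matrices in
#'   both channels.
#' @param offset Additive offset applied after correction (default 15).
#' @inheritParams estimate_normexp_params
#' @return A [methyl_set()] whose log records the per-sample, per-channel
#'   parameter estimates; control intensities (if carried) are corrected the
#'   same way.
#' @export
background_correct_noob <- function(signals, offset = 15,
                                    method = c("huber", "mean"),
                                    oob_floor = 30, alpha_floor = 10) {
  stopifnot(inherits(signals, "probe_signal_set"))
  method <- match.arg(method)
  if (nrow(signals$oob_grn) == 0 || nrow(signals$oob_red) == 0) {
    abort("Noob needs Type I probes of both channels for OOB background",
          class = "methylite_estimation_error")
  }
  man <- signals$manifest
  ch <- signal_channels(man)
  meth <- signals$meth
  unmeth <- signals$unmeth
  has_ctrl <- !is.null(signals$ctrl_grn)
  ctrl_grn <- signals$ctrl_grn
  ctrl_red <- signals$ctrl_red

  fits <- list()
  for (s in seq_along(signals$sample_ids)) {
    sample_fit <- list()
    for (channel in c("Grn", "Red")) {
      mg <- ch$meth == channel
      ug <- ch$unmeth == channel
      fg <- c(meth[mg, s], unmeth[ug, s])
      oob <- if (channel == "Grn") signals$oob_grn[, s] else signals$oob_red[, s]
      params <- tryCatch(
        estimate_normexp_params(fg, oob, method = method,
                                oob_floor = oob_floor,
                                alpha_floor = alpha_floor),
        methylite_estimation_error = function(e) {
          abort(paste0("normexp fit failed for sample '",
                       signals$sample_ids[s], "', channel ", channel, ": ",
                       conditionMessage(e)),
                class = "methylite_estimation_error")
        })
      meth[mg, s] <- normexp_signal(params, meth[mg, s]) + offset
      unmeth[ug, s] <- normexp_signal(params, unmeth[ug, s]) + offset
      if (has_ctrl) {
        if (channel == "Grn") {
          ctrl_grn[, s] <- normexp_signal(params, ctrl_grn[, s]) + offset
        } else {
          ctrl_red[, s] <- normexp_signal(params, ctrl_red[, s]) + offset
        }
      }
      sample_fit[[channel]] <- list(mu = params$mu, sigma = params$sigma,
                                    alpha = params$alpha)
    }
    fits[[signals$sample_ids[s]]] <- sample_fit
  }

  out <- methyl_set(man, meth, unmeth)
  out <- log_step(out, "noob_background",
                  list(offset = offset, method = method,
                       alpha_floor = alpha_floor, fits = fits))
  if (has_ctrl) {
    out$controls <- signals$controls
    out$ctrl_grn <- ctrl_grn
    out$ctrl_red <- ctrl_red
  }
  out
}

#' Per-sample normalization-control averages
#'
#' The green-measuring (C/G extension) controls are averaged in the Grn
#' channel and the red-measuring (A/T extension) controls in the Red
#' channel; their ratio measures the dye bias of a sample.
#'
#' @param x A [raw_intensity_set()] (then `controls` is required) or a
#'   [extract_signals()] result that carried controls.
#' @param controls A [control_manifest()] when `x` is address-level data.
#' @return A tibble with columns `sample`, `grn_avg`, `red_avg`.
#' @export
average_normalization_controls <- function(x, controls = NULL) {
  if (inherits(x, "raw_intensity_set")) {
    if (is.null(controls)) abort("controls manifest required for raw data")
    g_addr <- as.character(controls$address[controls$expected_channel == "Grn"])
    r_addr <- as.character(controls$address[controls$expected_channel == "Red"])
    g <- x$grn[g_addr, , drop = FALSE]
    r <- x$red[r_addr, , drop = FALSE]
    samples <- x$sample_ids
  } else if (!is.null(x$ctrl_grn)) {
    ctl <- x$controls
    g <- x$ctrl_grn[ctl$expected_channel == "Grn", , drop = FALSE]
    r <- x$ctrl_red[ctl$expected_channel == "Red", , drop = FALSE]
    samples <- x$sample_ids
  } else {
    abort("no control intensities available; pass a raw_intensity_set with a control manifest, or extract signals with controls")
  }
  if (nrow(g) == 0 || nrow(r) == 0) {
    abort("need at least one control of each expected channel",
          class = "methylite_estimation_error")
  }
  tibble(sample = samples,
         grn_avg = unname(colMeans(g)),
         red_avg = unname(colMeans(r)))
}

#' Dye-bias equalization
#'
#' Rescales each color channel so that the normalization-control averages of
#' both channels meet at a common reference level `L`:
#' every Grn-channel signal of sample `s` is multiplied by `L / grn_avg_s`
#' and every Red-channel signal by `L / red_avg_s`.
#'
#' * `mode = "reference"` (classic Noob): `L` is the midpoint of the two
#'   control averages of a designated reference sample, the same constant
#'   for every sample — so a reference array must be available.
#' * `mode = "single"` (ssNoob): `L_s` is the midpoint of sample `s`'s own
#'   control averages. No other sample is consulted, which makes the method
#'   a true single-sample procedure. The Grn/Red factor *ratio* is identical
#'   in both modes; they differ only by a per-sample overall scale, which
#'   cancels exactly in Beta values computed with offset 0.
#'
#' @param m A [methyl_set()] (typically from [background_correct_noob()]).
#' @param control_avgs Result of [average_normalization_controls()].
#' @param mode `"single"` or `"reference"`.
#' @param reference_sample Sample id defining `L` when `mode = "reference"`.
#' @return `m` with both channels rescaled and the dye factors logged.
#' @export
dye_bias_correct <- function(m, control_avgs,
                             mode = c("single", "reference"),
                             reference_sample = NULL) {
  stopifnot(inherits(m, "methyl_set"))
  mode <- match.arg(mode)
  samples <- colnames(m$meth)
  avgs <- control_avgs[match(samples, control_avgs$sample), ]
  if (any(is.na(avgs$sample))) {
    abort("control averages missing for some samples",
          class = "methylite_validation_error")
  }
  bad <- avgs$grn_avg <= 0 | avgs$red_avg <= 0
  if (any(bad)) {
    abort(paste0("zero/negative control average for sample(s): ",
                 paste(avgs$sample[bad], collapse = ", ")),
          class = "methylite_estimation_error")
  }
  if (mode == "reference") {
    if (is.null(reference_sample)) {
      abort("mode = 'reference' requires a reference_sample",
            class = "methylite_argument_error")
    }
    ref <- control_avgs[control_avgs$sample == reference_sample, ]
    if (nrow(ref) != 1) {
      abort(paste0("reference sample '", reference_sample,
                   "' not found in control averages"),
            class = "methylite_argument_error")
    }
    L <- rep((ref$grn_avg + ref$red_avg) / 2, length(samples))
  } else {
    L <- (avgs$grn_avg + avgs$red_avg) / 2
  }
  grn_factor <- unname(L / avgs$grn_avg)
  red_factor <- unname(L / avgs$red_avg)
  L <- unname(L)

  ch <- signal_channels(m$manifest)
  meth <- m$meth
  unmeth <- m$unmeth
  for (s in seq_along(samples)) {
    mg <- ch$meth == "Grn"
    ug <- ch$unmeth == "Grn"
    meth[mg, s] <- meth[mg, s] * grn_factor[s]
    meth[!mg, s] <- meth[!mg, s] * red_factor[s]
    unmeth[ug, s] <- unmeth[ug, s] * grn_factor[s]
    unmeth[!ug, s] <- unmeth[!ug, s] * red_factor[s]
  }
  out <- m
  out$meth <- meth
  out$unmeth <- unmeth
  log_step(out, "dye_bias",
           list(mode = mode,
                reference_sample = reference_sample,
                factors = tibble(sample = samples,
                                 grn_factor = grn_factor,
                                 red_factor = red_factor,
                                 reference_level = L)))
}

#' Noob preprocessing (background correction + dye-bias equalization)
#'
#' Composition `extract_signals` -> `background_correct_noob` ->
#' `dye_bias_correct`. With `dye_method = "single"` this is ssNoob: every
#' sample is processed using only its own data, so processing one sample at
#' a time gives bitwise-identical results to batch processing.
#'
#' @param raw A [raw_intensity_set()].
#' @param manifest A [probe_manifest()].
#' @param controls A [control_manifest()].
#' @param dye_method `"single"` (ssNoob) or `"reference"` (classic Noob).
#' @param reference_sample Required when `dye_method = "reference"`.
#' @inheritParams background_correct_noob
#' @return A [methyl_set()] with the full preprocessing log.
#' @export
preprocess_noob <- function(raw, manifest, controls,
                            dye_method = c("single", "reference"),
                            reference_sample = NULL,
                            offset = 15, method = c("huber", "mean"),
                            oob_floor = 30, alpha_floor = 10) {
  dye_method <- match.arg(dye_method)
  signals <- extract_signals(raw, manifest, controls)
  m <- background_correct_noob(signals, offset = offset, method = method,
                               oob_floor = oob_floor,
                               alpha_floor = alpha_floor)
  avgs <- average_normalization_controls(raw, controls)
  dye_bias_correct(m, avgs, mode = dye_method,
                   reference_sample = reference_sample)
}

#' Single-sample Noob (ssNoob)
#'
#' [preprocess_noob()] with within-sample dye-bias equalization: no
#' reference array is needed, and each sample's output is independent of
#' which other samples (if any) are processed with it. Suitable for
#' incremental processing of datasets that arrive in batches.
#'
#' @inheritParams preprocess_noob
#' @return A [methyl_set()].
#' @export
preprocess_ssnoob <- function(raw, manifest, controls, offset = 15,
                              method = c("huber", "mean"),
                              oob_floor = 30, alpha_floor = 10) {
  preprocess_noob(raw, manifest, controls, dye_method = "single",
                  offset = offset, method = method,
                  oob_floor = oob_floor, alpha_floor = alpha_floor)
}

#' Logged normexp parameter estimates of a preprocessed dataset
#' @param m A [methyl_set()] produced by [background_correct_noob()].
#' @return A tibble with columns `sample`, `channel`, `mu`, `sigma`, `alpha`.
#' @export
noob_params <- function(m) {
  step <- Filter(function(s) s$step == "noob_background", m$log)
  if (length(step) == 0) abort("no Noob background step in preprocessing log")
  fits <- step[[1]]$params$fits
  purrr::map_dfr(names(fits), function(smp) {
    purrr::map_dfr(names(fits[[smp]]), function(channel) {
      p <- fits[[smp]][[channel]]
      tibble(sample = smp, channel = channel,
             mu = p$mu, sigma = p$sigma, alpha = p$alpha)
    })
  })
}

#' Logged dye-bias factors of a preprocessed dataset
#' @param m A [methyl_set()] produced by [dye_bias_correct()].
#' @return A tibble with `sample`, `grn_factor`, `red_factor`,
#'   `reference_level` and a `mode` column.
#' @export
dye_factors <- function(m) {
  step <- Filter(function(s) s$step == "dye_bias", m$log)
  if (length(step) == 0) abort("no dye-bias step in preprocessing log")
  out <- step[[1]]$params$factors
  out$mode <- step[[1]]$params$mode
  out
}
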