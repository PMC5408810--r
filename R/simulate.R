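# Synthetic-data generator. All randomness flows from one config seed through
# deterministic substreams keyed by purpose and sample index, so adding
# samples to a simulated batch never perturbs the draws of earlier samples
# (required for honest single-sample separability tests).

substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(id) * 7919) %%
               2147483647)
}

with_substream <- function(seed, id, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, id))
  expr
}

#' Simulation configuration
#'
#' Encodes the generative model used by all fixtures: observed intensity =
#' `dye_factor * (S + B)` with true signal `S ~ Exponential(mean alpha * w)`
#' (where `w` splits a probe's signal between the methylated and
#' unmethylated channels according to its true Beta), background
#' `B ~ Normal(mu, sigma^2)` truncated at zero, out-of-band entries pure
#' dye-scaled background, and normalization controls
#' `dye_factor * Normal(control_level, sigma^2)`.
#'
#' Default dye factors model channel *imbalance* at constant overall
#' brightness: per sample a draw `b ~ Uniform(0.75, 1.25)` gives
#' `dye_grn = b`, `dye_red = 2 - b` (Grn/Red ratio 0.6-1.67). Explicit
#' per-sample `dye_grn` / `dye_red` vectors override this.
#'
#' @param seed Integer master seed; every random stream derives from it.
#' @param n_typeI_grn,n_typeI_red,n_typeII Probe counts by design.
#' @param n_samples Number of samples for intensity simulation.
#' @param n_controls_per_channel Normalization controls per channel.
#' @param control_level Mean control intensity (arbitrary fluorescence units).
#' @param mu,sigma,alpha Named per-channel (`Grn`, `Red`) background mean,
#'   background sd and exponential signal mean, in intensity units.
#' @param dye_grn,dye_red Optional explicit per-sample dye factors.
#' @param true_beta Optional per-probe methylation fractions; drawn
#'   `Uniform(0, 1)` when `NULL`.
#' @param shared_signal Technical-replicate mode: when `TRUE`, the
#'   exponential signal draw of each probe is made once and shared by every
#'   sample, so replicates differ only through background noise, dye
#'   factors and rounding (re-hybridizations of the same specimen). When
#'   `FALSE` (default), every sample redraws its signals independently.
#' @param overlap_fraction Shared-probe fraction for two-platform fixtures.
#' @param n_chemistry_mismatch Probes sharing an id across platforms but
#'   assayed with different chemistry (excluded from probe-level sharing).
#' @param k_cell_types,n_mixture_samples,beta_noise_sd Mixture-panel knobs.
#' @param n_reference_probes Panel size for the mixture reference.
#' @param n_discriminative_per_type Truly discriminative probes per type.
#' @param delta_beta_range Range of the discriminative Beta shift.
#' @param n_ref_samples_per_type,ref_noise_sd Sorted reference replicates
#'   per type and their Beta noise sd.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_typeI_grn = 150, n_typeI_red = 150, n_typeII = 700,
                       n_samples = 3,
                       n_controls_per_channel = 60, control_level = 10000,
                       mu = c(Grn = 500, Red = 500),
                       sigma = c(Grn = 100, Red = 100),
                       alpha = c(Grn = 4000, Red = 4000),
                       dye_grn = NULL, dye_red = NULL,
                       true_beta = NULL, shared_signal = FALSE,
                       overlap_fraction = 0.933,
                       n_chemistry_mismatch = 0,
                       k_cell_types = 6, n_mixture_samples = 20,
                       beta_noise_sd = 0.02,
                       n_reference_probes = 1000,
                       n_discriminative_per_type = 60,
                       delta_beta_range = c(0.3, 0.9),
                       n_ref_samples_per_type = 3, ref_noise_sd = 0.01) {
  cfg <- list(seed = as.integer(seed),
              n_typeI_grn = n_typeI_grn, n_typeI_red = n_typeI_red,
              n_typeII = n_typeII, n_samples = n_samples,
              n_controls_per_channel = n_controls_per_channel,
              control_level = control_level,
              mu = mu, sigma = sigma, alpha = alpha,
              dye_grn = dye_grn, dye_red = dye_red,
              true_beta = true_beta, shared_signal = isTRUE(shared_signal),
              overlap_fraction = overlap_fraction,
              n_chemistry_mismatch = n_chemistry_mismatch,
              k_cell_types = k_cell_types,
              n_mixture_samples = n_mixture_samples,
              beta_noise_sd = beta_noise_sd,
              n_reference_probes = n_reference_probes,
              n_discriminative_per_type = n_discriminative_per_type,
              delta_beta_range = delta_beta_range,
              n_ref_samples_per_type = n_ref_samples_per_type,
              ref_noise_sd = ref_noise_sd)
  stopifnot(cfg$n_typeI_grn > 0, cfg$n_typeI_red > 0, cfg$n_typeII > 0,
            cfg$n_samples > 0, cfg$n_controls_per_channel > 0,
            cfg$overlap_fraction > 0, cfg$overlap_fraction <= 1,
            all(cfg$sigma > 0), all(cfg$alpha > 0))
  structure(cfg, class = "sim_config")
}

# deterministic probe table (no randomness needed)
make_probe_table <- function(n_ig, n_ir, n_ii, id_start, addr_start) {
  n <- n_ig + n_ir + n_ii
  design <- c(rep("I", n_ig + n_ir), rep("II", n_ii))
  channel <- c(rep("Grn", n_ig), rep("Red", n_ir), rep("Both", n_ii))
  probe_id <- sprintf("cg%08d", id_start + seq_len(n) - 1)
  address_A <- integer(n)
  address_B <- rep(NA_integer_, n)
  addr <- addr_start
  for (i in seq_len(n)) {
    address_A[i] <- addr
    addr <- addr + 1L
    if (design[i] == "I") {
      address_B[i] <- addr
      addr <- addr + 1L
    }
  }
  # a sprinkling of sex-chromosome probes, the rest cycling the autosomes
  chromosome <- paste0("chr", rep_len(1:22, n))
  chromosome[seq_len(n) %% 20 == 0] <- "chrX"
  chromosome[seq_len(n) %% 50 == 3] <- "chrY"
  tibble(probe_id = probe_id, design_type = design, channel = channel,
         address_A = address_A, address_B = address_B,
         chromosome = chromosome)
}

#' Simulate a single-platform manifest
#' @param cfg A [sim_config()].
#' @param platform Platform tag for the manifest.
#' @return A [probe_manifest()].
#' @export
simulate_manifest <- function(cfg, platform = "450K") {
  probe_manifest(make_probe_table(cfg$n_typeI_grn, cfg$n_typeI_red,
                                  cfg$n_typeII, id_start = 1,
                                  addr_start = 10000L),
                 platform = platform)
}

#' Simulate a control-probe manifest
#' @param cfg A [sim_config()].
#' @return A [control_manifest()] with C/G-extension (Grn) and
#'   A/T-extension (Red) normalization controls.
#' @export
simulate_controls <- function(cfg) {
  n <- cfg$n_controls_per_channel
  control_manifest(tibble(
    address = 9000000L + seq_len(2 * n),
    control_type = rep(c("NORM_C", "NORM_A"), each = n),
    expected_channel = rep(c("Grn", "Red"), each = n)))
}

#' Simulate a pair of overlapping platforms
#'
#' Platform B shares `floor(overlap_fraction * nrow(A))` of A's probes with
#' identical design type and channel (different bead addresses, as on real
#' successive platforms), plus B-only probes topping it up to A's size.
#' Optionally, `n_chemistry_mismatch` probe ids are shared but assayed with
#' a different chemistry on B (Type II on A, Type I Grn on B); these are
#' excluded from the shared list.
#'
#' @param cfg A [sim_config()].
#' @return A list with `manifest_a`, `manifest_b` and `shared` (probe ids).
#' @export
simulate_platform_pair <- function(cfg) {
  man_a <- simulate_manifest(cfg, platform = "450K")
  n_a <- nrow(man_a)
  n_shared <- floor(cfg$overlap_fraction * n_a)
  if (n_shared < 1) {
    abort("overlap_fraction too small: no probes would be shared",
          class = "methylite_argument_error")
  }
  shared_idx <- with_substream(cfg$seed, 2,
                               sort(sample(n_a, n_shared)))
  n_cm <- cfg$n_chemistry_mismatch
  cm_pool <- setdiff(which(man_a$design_type == "II"), shared_idx)
  if (n_cm > length(cm_pool)) {
    abort("not enough non-shared Type II probes for chemistry mismatches",
          class = "methylite_argument_error")
  }
  cm_idx <- head(cm_pool, n_cm)

  shared_tbl <- as_tibble(man_a)[shared_idx, ]
  n_only <- n_a - n_shared - n_cm
  only_tbl <- if (n_only > 0) {
    n_ig_o <- min(round(n_only * cfg$n_typeI_grn / n_a), n_only)
    n_ir_o <- min(round(n_only * cfg$n_typeI_red / n_a), n_only - n_ig_o)
    make_probe_table(n_ig = n_ig_o, n_ir = n_ir_o,
                     n_ii = n_only - n_ig_o - n_ir_o,
                     id_start = 1000001, addr_start = 1L)
  } else {
    make_probe_table(0L, 0L, 0L, 1000001, 1L)
  }

  # reassign B-side addresses for shared (and mismatch) probes
  addr <- 5000000L
  reassign <- function(tbl) {
    for (i in seq_len(nrow(tbl))) {
      tbl$address_A[i] <- addr
      addr <<- addr + 1L
      if (tbl$design_type[i] == "I") {
        tbl$address_B[i] <- addr
        addr <<- addr + 1L
      } else {
        tbl$address_B[i] <- NA_integer_
      }
    }
    tbl
  }
  shared_tbl <- reassign(shared_tbl)
  b_tbl <- dplyr::bind_rows(shared_tbl, only_tbl)
  if (n_cm > 0) {
    cm_tbl <- as_tibble(man_a)[cm_idx, ]
    cm_tbl$design_type <- "I"
    cm_tbl$channel <- "Grn"
    cm_tbl <- reassign(cm_tbl)
    b_tbl <- dplyr::bind_rows(b_tbl, cm_tbl)
  }
  list(manifest_a = man_a,
       manifest_b = probe_manifest(b_tbl, platform = "EPIC"),
       shared = shared_tbl$probe_id)
}

sample_dye_factors <- function(cfg, i) {
  if (!is.null(cfg$dye_grn)) {
    c(Grn = cfg$dye_grn[i], Red = cfg$dye_red[i])
  } else {
    b <- with_substream(cfg$seed, 2000 + i, runif(1, 0.75, 1.25))
    c(Grn = b, Red = 2 - b)
  }
}

true_betas_for <- function(cfg, n_probes) {
  if (!is.null(cfg$true_beta)) {
    rep_len(cfg$true_beta, n_probes)
  } else {
    with_substream(cfg$seed, 3, runif(n_probes))
  }
}

rexp_mean <- function(n, m) {
  out <- numeric(n)
  pos <- m > 1e-12
  out[pos] <- rexp(sum(pos), rate = 1 / m[pos])
  out
}

trunc_norm <- function(n, mu, sigma) pmax(rnorm(n, mu, sigma), 0)

#' Simulate address-level raw intensities under the Noob generative model
#'
#' Produces a full two-channel intensity matrix for the manifest plus
#' controls, with a truth record sufficient to check every downstream
#' estimate. Intensities are rounded to integers in \[0, 65535\] (the IDAT
#' on-disk representation), so CSV and IDAT round-trips are exact.
#'
#' @param cfg A [sim_config()].
#' @param manifest A [probe_manifest()], e.g. [simulate_manifest()].
#' @param controls A [control_manifest()], e.g. [simulate_controls()].
#' @param sample_ids Sample names, default `s1..sN` for `cfg$n_samples`.
#' @return A list with `raw` (a [raw_intensity_set()]) and `truth`
#'   (per-probe true Betas, true signal matrices, observed in-band
#'   intensities, per-sample dye factors and the model parameters).
#' @export
simulate_raw_intensities <- function(cfg, manifest = simulate_manifest(cfg),
                                     controls = simulate_controls(cfg),
                                     sample_ids = paste0("s", seq_len(cfg$n_samples))) {
  n_s <- length(sample_ids)
  addresses <- sort(c(manifest_addresses(manifest), controls$address))
  idx <- function(a) match(a, addresses)

  is_ig <- manifest$design_type == "I" & manifest$channel == "Grn"
  is_ir <- manifest$design_type == "I" & manifest$channel == "Red"
  is_ii <- manifest$design_type == "II"
  beta_true <- true_betas_for(cfg, nrow(manifest))
  names(beta_true) <- manifest$probe_id

  grn <- matrix(0, length(addresses), n_s,
                dimnames = list(as.character(addresses), sample_ids))
  red <- grn
  meth_s <- matrix(0, nrow(manifest), n_s,
                   dimnames = list(manifest$probe_id, sample_ids))
  unmeth_s <- meth_s
  meth_obs <- meth_s
  unmeth_obs <- meth_s
  dye <- matrix(0, n_s, 2, dimnames = list(sample_ids, c("Grn", "Red")))

  shared <- NULL
  if (isTRUE(cfg$shared_signal)) {
    ch <- signal_channels(manifest)
    shared <- with_substream(cfg$seed, 7, list(
      m = rexp_mean(nrow(manifest), cfg$alpha[ch$meth] * beta_true),
      u = rexp_mean(nrow(manifest), cfg$alpha[ch$unmeth] * (1 - beta_true))))
  }

  ctl_g <- controls$expected_channel == "Grn"

  for (i in seq_len(n_s)) {
    f <- sample_dye_factors(cfg, i)
    dye[i, ] <- f
    with_substream(cfg$seed, 100 + i, {
      g <- numeric(length(addresses))
      r <- numeric(length(addresses))
      place <- function(kind, sel) {
        n_p <- sum(sel)
        if (n_p == 0) return(invisible())
        ch_meth <- switch(kind, ig = "Grn", ir = "Red", ii = "Grn")
        ch_unmeth <- switch(kind, ig = "Grn", ir = "Red", ii = "Red")
        if (is.null(shared)) {
          s_m <- rexp_mean(n_p, cfg$alpha[ch_meth] * beta_true[sel])
          s_u <- rexp_mean(n_p, cfg$alpha[ch_unmeth] * (1 - beta_true[sel]))
        } else {
          s_m <- shared$m[sel]
          s_u <- shared$u[sel]
        }
        b_m <- trunc_norm(n_p, cfg$mu[ch_meth], cfg$sigma[ch_meth])
        b_u <- trunc_norm(n_p, cfg$mu[ch_unmeth], cfg$sigma[ch_unmeth])
        meth_s[sel, i] <<- s_m
        unmeth_s[sel, i] <<- s_u
        obs_m <- f[ch_meth] * (s_m + b_m)
        obs_u <- f[ch_unmeth] * (s_u + b_u)
        if (kind == "ii") {
          ia <- idx(manifest$address_A[sel])
          g[ia] <<- obs_m
          r[ia] <<- obs_u
        } else {
          ia <- idx(manifest$address_A[sel])  # unmeth address
          ib <- idx(manifest$address_B[sel])  # meth address
          if (kind == "ig") {
            g[ib] <<- obs_m
            g[ia] <<- obs_u
            # OOB: red channel reads of Grn Type I addresses are background
            r[ib] <<- f["Red"] * trunc_norm(n_p, cfg$mu["Red"], cfg$sigma["Red"])
            r[ia] <<- f["Red"] * trunc_norm(n_p, cfg$mu["Red"], cfg$sigma["Red"])
          } else {
            r[ib] <<- obs_m
            r[ia] <<- obs_u
            g[ib] <<- f["Grn"] * trunc_norm(n_p, cfg$mu["Grn"], cfg$sigma["Grn"])
            g[ia] <<- f["Grn"] * trunc_norm(n_p, cfg$mu["Grn"], cfg$sigma["Grn"])
          }
        }
        meth_obs[sel, i] <<- round(pmin(pmax(obs_m, 0), 65535))
        unmeth_obs[sel, i] <<- round(pmin(pmax(obs_u, 0), 65535))
      }
      place("ig", is_ig)
      place("ir", is_ir)
      place("ii", is_ii)

      nc <- nrow(controls)
      ic <- idx(controls$address)
      ctrl_sig_g <- f["Grn"] * trunc_norm(sum(ctl_g), cfg$control_level,
                                          cfg$sigma["Grn"])
      ctrl_sig_r <- f["Red"] * trunc_norm(sum(!ctl_g), cfg$control_level,
                                          cfg$sigma["Red"])
      g[ic[ctl_g]] <- ctrl_sig_g
      r[ic[!ctl_g]] <- ctrl_sig_r
      # the opposite channel at a control address reads background
      r[ic[ctl_g]] <- f["Red"] * trunc_norm(sum(ctl_g), cfg$mu["Red"],
                                            cfg$sigma["Red"])
      g[ic[!ctl_g]] <- f["Grn"] * trunc_norm(sum(!ctl_g), cfg$mu["Grn"],
                                             cfg$sigma["Grn"])
      grn[, i] <- round(pmin(pmax(g, 0), 65535))
      red[, i] <- round(pmin(pmax(r, 0), 65535))
    })
  }

  list(raw = raw_intensity_set(addresses, grn, red, sample_ids),
       truth = list(beta = beta_true,
                    meth_signal = meth_s, unmeth_signal = unmeth_s,
                    meth_observed = meth_obs, unmeth_observed = unmeth_obs,
                    dye = tibble(sample = sample_ids,
                                 grn = dye[, "Grn"], red = dye[, "Red"]),
                    mu = cfg$mu, sigma = cfg$sigma, alpha = cfg$alpha,
                    control_level = cfg$control_level))
}

#' Simulate a cell-type mixture panel
#'
#' Builds `k_cell_types` Beta profiles sharing a common (bimodal) baseline
#' except at disjoint blocks of `n_discriminative_per_type` probes, where
#' the owning type is shifted by `Uniform(delta_beta_range)` (direction
#' chosen to stay in \[0, 1\]); sorted reference replicates and
#' Dirichlet(1, ..., 1) mixtures with clipped Gaussian Beta noise are drawn
#' from the profiles.
#'
#' @param cfg A [sim_config()].
#' @return A list with `reference` (a [cell_type_reference()] of the true
#'   profiles), `ref_beta` / `ref_labels` (sorted reference replicates for
#'   probe selection), `mixtures` (probe x sample Beta matrix) and
#'   `proportions` (sample x cell type truth).
#' @export
simulate_mixture_panel <- function(cfg) {
  k <- cfg$k_cell_types
  stopifnot(k >= 2)
  n <- cfg$n_reference_probes
  types <- paste0("CT", seq_len(k))
  probes <- sprintf("cg%08d", seq_len(n))

  profiles <- with_substream(cfg$seed, 4, {
    base <- stats::rbeta(n, 0.4, 0.4)
    P <- matrix(base, n, k, dimnames = list(probes, types))
    n_d <- cfg$n_discriminative_per_type
    if (n_d * k > n) abort("panel too small for the discriminative blocks")
    if (n_d > 0) {
      for (j in seq_len(k)) {
        block <- ((j - 1) * n_d + 1):(j * n_d)
        delta <- runif(n_d, cfg$delta_beta_range[1], cfg$delta_beta_range[2])
        up <- base[block] + delta <= 1
        P[block, j] <- pmin(pmax(base[block] + ifelse(up, delta, -delta), 0), 1)
      }
    }
    P
  })

  n_r <- cfg$n_ref_samples_per_type
  ref <- with_substream(cfg$seed, 5, {
    ref_beta <- matrix(0, n, k * n_r)
    labels <- character(k * n_r)
    for (j in seq_len(k)) {
      for (rdx in seq_len(n_r)) {
        col <- (j - 1) * n_r + rdx
        ref_beta[, col] <- pmin(pmax(
          profiles[, j] + rnorm(n, 0, cfg$ref_noise_sd), 0), 1)
        labels[col] <- types[j]
      }
    }
    dimnames(ref_beta) <- list(probes,
                               paste0(rep(types, each = n_r), "_r",
                                      rep(seq_len(n_r), k)))
    list(beta = ref_beta, labels = labels)
  })

  mix <- with_substream(cfg$seed, 6, {
    W <- matrix(rgamma(cfg$n_mixture_samples * k, 1), ncol = k)
    W <- W / rowSums(W)
    dimnames(W) <- list(sprintf("mix%02d", seq_len(cfg$n_mixture_samples)),
                        types)
    Y <- profiles %*% t(W)
    if (cfg$beta_noise_sd > 0) {
      Y <- Y + rnorm(length(Y), 0, cfg$beta_noise_sd)
    }
    Y <- pmin(pmax(Y, 0), 1)
    dimnames(Y) <- list(probes, rownames(W))
    list(W = W, Y = Y)
  })

  list(reference = cell_type_reference(profiles, platform = "450K"),
       ref_beta = ref$beta, ref_labels = ref$labels,
       mixtures = mix$Y, proportions = mix$W)
}

#' Write a complete fixture bundle to disk
#'
#' Emits the manifests, control manifest, per-sample Grn/Red IDAT pairs,
#' the equivalent CSV intensity pair, a mixture-panel reference CSV, a
#' truth JSON and a plain-text README listing the files and the seed.
#' Output is deterministic: the same config always produces identical bytes.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
write_fixture_bundle <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- simulate_platform_pair(cfg)
  controls <- simulate_controls(cfg)
  sim <- simulate_raw_intensities(cfg, pair$manifest_a, controls)
  panel <- simulate_mixture_panel(cfg)

  paths <- list(
    manifest_a = file.path(out_dir, "manifest_450K.csv"),
    manifest_b = file.path(out_dir, "manifest_EPIC.csv"),
    controls = file.path(out_dir, "controls.csv"),
    reference = file.path(out_dir, "celltype_reference.csv"),
    truth = file.path(out_dir, "truth.json"),
    readme = file.path(out_dir, "README.txt"))
  write_manifest(pair$manifest_a, paths$manifest_a)
  write_manifest(pair$manifest_b, paths$manifest_b)
  write.csv(as.data.frame(controls), paths$controls, row.names = FALSE,
            quote = FALSE)
  write_reference(panel$reference, paths$reference)

  csv_base <- file.path(out_dir, "intensities")
  write_intensity_csv(sim$raw, csv_base)
  paths$intensities <- paste0(csv_base, c("_Grn.csv", "_Red.csv"))

  basenames <- file.path(out_dir,
                         sprintf("%09d_R0%dC01", 200000000 + cfg$seed,
                                 seq_along(sim$raw$sample_ids)))
  for (i in seq_along(basenames)) {
    for (channel in c("Grn", "Red")) {
      mat <- if (channel == "Grn") sim$raw$grn else sim$raw$red
      write_idat(idat_file(sim$raw$addresses, mat[, i],
                           barcode = sprintf("%09d", 200000000 + cfg$seed),
                           position = sprintf("R0%dC01", i)),
                 paste0(basenames[i], "_", channel, ".idat"))
    }
  }
  paths$idat_basenames <- basenames

  jsonlite::write_json(
    list(seed = cfg$seed,
         sample_ids = sim$raw$sample_ids,
         dye = sim$truth$dye,
         mu = as.list(sim$truth$mu), sigma = as.list(sim$truth$sigma),
         alpha = as.list(sim$truth$alpha),
         control_level = sim$truth$control_level,
         true_beta = as.list(sim$truth$beta),
         shared_probes = pair$shared,
         mixture_proportions = as.data.frame(panel$proportions)),
    paths$truth, auto_unbox = TRUE, digits = NA)

  writeLines(c(
    "Synthetic Infinium fixture bundle (methylite)",
    paste0("seed: ", cfg$seed),
    "files:",
    paste0("  ", basename(unlist(paths, use.names = FALSE)))),
    paths$readme)
  invisible(paths)
}
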