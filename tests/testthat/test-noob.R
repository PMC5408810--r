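test_that("normexp parameter estimation validates its inputs", {
  expect_error(estimate_normexp_params(rnorm(100, 1000), rep(500, 100)),
               class = "methylite_estimation_error")  # zero variance
  expect_error(estimate_normexp_params(rnorm(100, 1000), rnorm(10, 500, 50)),
               class = "methylite_estimation_error")  # below OOB floor
  # foreground at/below background: alpha clamps to the floor
  p <- estimate_normexp_params(rnorm(1000, 300, 50), rnorm(1000, 500, 50),
                               alpha_floor = 10)
  expect_equal(p$alpha, 10)
})

test_that("background parameters are recovered from simulated draws", {
  # tolerances frozen from a Monte-Carlo of the estimators at n = 10,000:
  # mu/sigma are tight; the Huber foreground location of an
  # exponential+normal convolution carries a known negative bias
  # (~ -280 at alpha = 2000), so the huber alpha lands well below truth,
  # while the mean/sd route is nearly unbiased.
  set.seed(101)
  oob <- rnorm(10000, 500, 100)
  fg <- rnorm(10000, 500, 100) + rexp(10000, 1 / 2000)
  ph <- estimate_normexp_params(fg, oob, method = "huber")
  expect_lt(abs(ph$mu - 500), 10)
  expect_lt(abs(ph$sigma - 100), 10)
  expect_lt(abs(ph$alpha - 2000), 450)
  pm <- estimate_normexp_params(fg, oob, method = "mean")
  expect_lt(abs(pm$mu - 500), 10)
  expect_lt(abs(pm$sigma - 100), 10)
  expect_lt(abs(pm$alpha - 2000), 150)
})

test_that("normexp_signal matches the quadrature oracle and is well-behaved", {
  params <- list(mu = 500, sigma = 100, alpha = 2000)
  x <- c(400, 600, 1000, 5000)
  expect_equal(normexp_signal(params, x),
               quad_normexp_oracle(500, 100, 2000, x),
               tolerance = 1e-6)

  # large-x asymptote: corrected -> x - mu - sigma^2/alpha
  x_big <- c(1e4, 1e5, 1e6)
  m <- x_big - 500 - 100^2 / 2000
  expect_lt(max(abs(normexp_signal(params, x_big) - m)), 1e-6)

  # strictly increasing, strictly positive deep into the background
  grid <- seq(-2000, 8000, by = 7)  # m/sigma spans about [-25, 75]
  out <- normexp_signal(params, grid)
  expect_true(all(diff(out) > 0))
  expect_true(all(out > 0))
  expect_error(normexp_signal(list(mu = 0, sigma = -1, alpha = 10), 1),
               class = "methylite_argument_error")
})

test_that("noob background correction logs recoverable parameters", {
  cfg <- sim_config(seed = 23, n_samples = 1,
                    dye_grn = 1, dye_red = 1)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  sim <- simulate_raw_intensities(cfg, man, ctl)
  m <- background_correct_noob(extract_signals(sim$raw, man, ctl))
  est <- noob_params(m)
  # 600 OOB draws per channel: background location/scale within ~10%
  expect_true(all(abs(est$mu - 500) < 50))
  expect_true(all(abs(est$sigma - 100) < 25))
  # pooled foreground mixes Exp(alpha * w) across probes, w ~ U(0,1): the
  # Huber location sits near the low-signal bulk, far below alpha itself
  expect_true(all(est$alpha > 500 & est$alpha < cfg$alpha["Grn"]))
})

test_that("the offset shifts corrected signals additively", {
  cfg <- sim_config(seed = 29, n_samples = 2, n_typeI_grn = 30,
                    n_typeI_red = 30, n_typeII = 60)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  sig <- extract_signals(simulate_raw_intensities(cfg, man, ctl)$raw, man, ctl)
  m0 <- background_correct_noob(sig, offset = 0)
  m15 <- background_correct_noob(sig, offset = 15)
  expect_equal(m15$meth, m0$meth + 15)
  expect_equal(m15$unmeth, m0$unmeth + 15)
})

test_that("background correction is single-sample separable", {
  cfg <- sim_config(seed = 31, n_samples = 10)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  raw <- simulate_raw_intensities(cfg, man, ctl)$raw
  batch <- background_correct_noob(extract_signals(raw, man, ctl))
  alone <- background_correct_noob(
    extract_signals(subset_samples(raw, "s7"), man, ctl))
  expect_identical(alone$meth[, "s7"], batch$meth[, "s7"])
  expect_identical(alone$unmeth[, "s7"], batch$unmeth[, "s7"])
})

test_that("control averages behave as channel means and detect dye imbalance", {
  raw <- tiny_raw()
  raw <- set_intensity(raw, 900, "Grn", "s1", 400)
  raw <- set_intensity(raw, 901, "Grn", "s1", 600)
  avgs <- average_normalization_controls(raw, tiny_controls())
  expect_equal(avgs$grn_avg, 500)
  expect_equal(avgs$red_avg, 100)

  cfg <- sim_config(seed = 37, n_samples = 1, dye_grn = 1.6, dye_red = 0.8)
  sim <- simulate_raw_intensities(cfg)
  a <- average_normalization_controls(sim$raw, simulate_controls(cfg))
  expect_equal(a$grn_avg / a$red_avg, 2, tolerance = 0.02)
})

test_that("dye-bias factors are identity for balanced channels and logged", {
  raw <- tiny_raw(fill = 500)
  sig <- extract_signals(raw, tiny_manifest(), tiny_controls())
  m <- preprocess_raw(sig)
  avgs <- average_normalization_controls(raw, tiny_controls())
  corrected <- dye_bias_correct(m, avgs, mode = "single")
  expect_identical(corrected$meth, m$meth)
  f <- dye_factors(corrected)
  expect_equal(f$grn_factor, 1)
  expect_equal(f$red_factor, 1)
  expect_identical(f$mode, "single")
})

test_that("ssNoob output for a sample ignores the rest of the batch", {
  cfg <- sim_config(seed = 41, n_samples = 6)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  raw <- simulate_raw_intensities(cfg, man, ctl)$raw
  full <- preprocess_ssnoob(raw, man, ctl)
  pairs <- preprocess_ssnoob(subset_samples(raw, c("s2", "s5")), man, ctl)
  expect_identical(pairs$meth, full$meth[, c("s2", "s5")])
  expect_identical(pairs$unmeth, full$unmeth[, c("s2", "s5")])
})

test_that("Noob and ssNoob Betas coincide (exactly at offset 0)", {
  cfg <- sim_config(seed = 43, n_samples = 5)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  raw <- simulate_raw_intensities(cfg, man, ctl)$raw
  ss <- preprocess_ssnoob(raw, man, ctl)
  ref <- preprocess_noob(raw, man, ctl, dye_method = "reference",
                         reference_sample = "s1")
  expect_lt(max(abs(get_beta(ss, 0) - get_beta(ref, 0))), 1e-12)
  expect_lt(max(abs(get_beta(ss, 100) - get_beta(ref, 100))), 1e-3)
  # the relative Grn/Red correction is identical by construction
  fs <- dye_factors(ss)
  fr <- dye_factors(ref)
  expect_equal(fs$grn_factor / fs$red_factor,
               fr$grn_factor / fr$red_factor)
})

test_that("an all-background fixture corrects down to roughly the offset", {
  cfg <- sim_config(seed = 47, n_samples = 1,
                    alpha = c(Grn = 1, Red = 1), dye_grn = 1, dye_red = 1)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  sig <- extract_signals(simulate_raw_intensities(cfg, man, ctl)$raw,
                         man, ctl)
  m <- background_correct_noob(sig, offset = 15)
  inband <- c(m$meth, m$unmeth)
  expect_true(all(inband > 15))
  # quadrature bound: with alpha at its floor the posterior mean of a pure
  # background draw stays tiny
  worst <- quad_normexp_oracle(500, 100, 10, 500 + 5 * 100)
  expect_lt(max(inband) - 15, worst * 5)
})

test_that("ssNoob shrinks replicate Beta variance under varying dye bias", {
  n_rep <- 3
  base <- sim_config(seed = 53)
  dye <- with(list(), {
    set.seed(53)
    list(g = exp(runif(n_rep, log(0.7), log(1.4))),
         r = exp(runif(n_rep, log(0.7), log(1.4))))
  })
  cfg <- sim_config(seed = 53, n_samples = n_rep, shared_signal = TRUE,
                    dye_grn = dye$g, dye_red = dye$r)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  raw <- simulate_raw_intensities(cfg, man, ctl)$raw
  groups <- stats::setNames(rep("rep", n_rep), paste0("s", 1:n_rep))

  raw_beta <- get_beta(preprocess_raw(extract_signals(raw, man, ctl)), 100)
  ss_beta <- get_beta(preprocess_ssnoob(raw, man, ctl), 100)
  v_raw <- replicate_variance(raw_beta, groups, man)
  v_ss <- replicate_variance(ss_beta, groups, man)
  expect_lt(median(v_ss$variance), median(v_raw$variance))
})
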