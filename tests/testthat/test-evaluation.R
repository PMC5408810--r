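small_manifest_for <- function(beta) {
  n <- nrow(beta)
  probe_manifest(data.frame(
    probe_id = rownames(beta),
    design_type = rep(c("I", "II"), length.out = n),
    channel = rep(c("Grn", "Both"), length.out = n),
    address_A = seq_len(n) * 2L,
    address_B = ifelse(rep(c(TRUE, FALSE), length.out = n),
                       seq_len(n) * 2L + 1L, NA_integer_),
    chromosome = "chr1"), platform = "450K")
}

test_that("replicate variance follows the unbiased sample-variance formula", {
  beta <- matrix(0.4, 6, 4, dimnames = list(sprintf("cg%02d", 1:6),
                                            paste0("s", 1:4)))
  groups <- stats::setNames(rep(c("g1", "g2"), each = 2), colnames(beta))
  man <- small_manifest_for(beta)
  v0 <- replicate_variance(beta, groups, man)
  expect_true(all(v0$variance == 0))

  d <- 0.2
  beta2 <- beta
  beta2["cg03", "s1"] <- beta2["cg03", "s1"] + d
  v <- replicate_variance(beta2, groups, man)
  expect_equal(v$variance[v$probe_id == "cg03" & v$group == "g1"], d^2 / 2)
  expect_true(all(v$variance[v$group == "g2"] == 0))
  expect_identical(unique(v$design_type[v$probe_id == "cg01"]), "I")

  expect_error(replicate_variance(beta, c(s1 = "a", s2 = "a", s3 = "b",
                                          s4 = "c"), man),
               class = "methylite_validation_error")
})

test_that("replicate variance is order-invariant and scales quadratically", {
  set.seed(103)
  beta <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:4)))
  groups <- stats::setNames(rep("g", 4), colnames(beta))
  man <- small_manifest_for(beta)
  v <- replicate_variance(beta, groups, man)
  perm <- c("s3", "s1", "s4", "s2")
  v_perm <- replicate_variance(beta[, perm], groups, man)
  expect_equal(v_perm$variance, v$variance)
  k <- 0.35
  v_scaled <- replicate_variance(k * beta, groups, man)
  expect_equal(v_scaled$variance, k^2 * v$variance)
})

test_that("halving the noise of one design stratum quarters its median variance", {
  set.seed(105)
  n <- 4000
  probes <- sprintf("cg%05d", seq_len(n))
  design_I <- rep(c(TRUE, FALSE), length.out = n)
  sd_probe <- ifelse(design_I, 0.04, 0.02)
  truth <- runif(n, 0.2, 0.8)
  beta <- sapply(1:3, function(i) truth + rnorm(n, 0, sd_probe))
  dimnames(beta) <- list(probes, paste0("s", 1:3))
  man <- small_manifest_for(beta)
  v <- replicate_variance(beta, stats::setNames(rep("g", 3), colnames(beta)),
                          man)
  med <- tapply(v$variance, v$design_type, median)
  expect_equal(unname(med["II"] / med["I"]), 0.25, tolerance = 0.2)
  gl <- glance(v)
  expect_named(gl, c("design_type", "n", "q25", "median", "q75"))
})

test_that("median-distance scores agree with a brute-force double loop", {
  set.seed(107)
  refs <- matrix(runif(50), 10, 5,
                 dimnames = list(sprintf("cg%02d", 1:10), paste0("r", 1:5)))
  query <- matrix(runif(30), 10, 3)
  got <- median_distance_score(query, refs)
  naive <- apply(refs, 2, function(rcol) {
    median(apply(query, 2, function(qcol) sqrt(sum((rcol - qcol)^2))))
  })
  expect_equal(got$score, unname(naive), tolerance = 1e-12)

  expect_equal(median_distance_score(refs[, 2], refs)$score[2], 0)

  perm <- sample(10)
  got_perm <- median_distance_score(query[perm, ],
                                    refs[perm, , drop = FALSE])
  expect_equal(got_perm$score, got$score)

  expect_error(median_distance_score(query[1:9, ], refs),
               regexp = "combine", class = "methylite_validation_error")

  manh <- median_distance_score(query, refs, metric = "manhattan")
  naive_m <- apply(refs, 2, function(rcol) {
    median(apply(query, 2, function(qcol) sum(abs(rcol - qcol))))
  })
  expect_equal(manh$score, unname(naive_m))
})

test_that("ROC handles perfect separation, ties, and matches pair counting", {
  perfect <- roc_from_scores(c(1, 2, 3, 10, 11, 12),
                             c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(perfect$auc, 1)
  tied <- roc_from_scores(rep(5, 8), rep(c(TRUE, FALSE), 4))
  expect_equal(tied$auc, 0.5)
  expect_error(roc_from_scores(1:4, rep(TRUE, 4)),
               class = "methylite_validation_error")

  set.seed(109)
  for (i in 1:5) {
    scores <- sample(1:8, 20, replace = TRUE)  # plenty of ties
    pos <- runif(20) < 0.4
    if (!any(pos) || all(pos)) next
    r <- roc_from_scores(scores, pos)
    expect_equal(r$auc, pair_count_auc(scores, pos))
    expect_equal(r$auc + roc_from_scores(-scores, pos)$auc, 1)
    expect_true(all(r$points$fpr >= 0 & r$points$fpr <= 1))
    expect_equal(r$points$tpr[nrow(r$points)], 1)
  }
})

test_that("ROC agrees with pROC on a random instance", {
  set.seed(111)
  scores <- rnorm(40)
  pos <- runif(40) < 0.5
  got <- roc_from_scores(scores, pos)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores,
                                        direction = ">", quiet = TRUE)))
  expect_equal(got, ref)
})

test_that("QC medians track signal level and flag degraded samples", {
  man <- small_manifest_for(matrix(0, 6, 1,
                                   dimnames = list(sprintf("cg%02d", 1:6), "x")))
  mk <- function(value, samples) {
    methyl_set(man,
               matrix(value, 6, length(samples),
                      dimnames = list(man$probe_id, samples)),
               matrix(value, 6, length(samples),
                      dimnames = list(man$probe_id, samples)))
  }
  qc <- get_qc(mk(1023, "s1"))
  expect_equal(qc$m_median, 10)
  expect_equal(qc$u_median, 10)

  qc2 <- get_qc(mk(2 * 1023 + 1, "s1"))
  expect_equal(qc2$m_median, 11)

  cfg <- sim_config(seed = 113, n_samples = 2, dye_grn = c(1, 1),
                    dye_red = c(1, 1))
  man2 <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  raw <- simulate_raw_intensities(cfg, man2, ctl)$raw
  degraded <- raw_intensity_set(raw$addresses, raw$grn * 0.05,
                                raw$red * 0.05, c("d1", "d2"))
  healthy <- preprocess_raw(extract_signals(raw, man2, ctl))
  broken <- preprocess_raw(extract_signals(degraded, man2, ctl))
  cutoff <- mean(c(get_qc(healthy)$qc, get_qc(broken)$qc))
  expect_true(all(!get_qc(healthy, cutoff = cutoff)$flagged))
  expect_true(all(get_qc(broken, cutoff = cutoff)$flagged))
})

test_that("sex is predicted from sex-chromosome copy number only", {
  cfg <- sim_config(seed = 115, n_samples = 2)
  man <- simulate_manifest(cfg)
  ctl <- simulate_controls(cfg)
  raw <- simulate_raw_intensities(cfg, man, ctl)$raw
  m <- preprocess_raw(extract_signals(raw, man, ctl))

  y_rows <- man$chromosome == "chrY"
  male <- m
  female <- m
  # XX samples: only background at Y probes
  female$meth[y_rows, ] <- 30
  female$unmeth[y_rows, ] <- 30
  sex_m <- get_sex(male)
  sex_f <- get_sex(female)
  expect_true(all(sex_m$predicted_sex == "Male"))
  expect_true(all(sex_f$predicted_sex == "Female"))

  # autosomal probes are irrelevant to the call
  perturbed <- male
  auto <- !(man$chromosome %in% c("chrX", "chrY"))
  perturbed$meth[auto, ] <- perturbed$meth[auto, ] * 10 + 999
  expect_equal(get_sex(perturbed)$d, sex_m$d)

  man_no_y <- man[man$chromosome != "chrY", ]
  expect_error(get_sex(male, manifest = man_no_y),
               class = "methylite_validation_error")
})
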