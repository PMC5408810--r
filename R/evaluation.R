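#' Per-CpG variance across technical replicates, stratified by design type
#'
#' The unbiased sample variance of the Beta values across the replicates of
#' each group is computed at every CpG and tagged with the probe's Infinium
#' design type, the standard benchmark for how much technical variation a
#' preprocessing method leaves behind.
#'
#' @param beta Numeric Beta matrix (probe x sample), probe ids as row names.
#' @param replicate_groups Named character vector mapping sample -> group;
#'   every group needs at least two samples.
#' @param manifest A [probe_manifest()] supplying design types.
#' @return A tibble of class `replicate_variance` with columns `probe_id`,
#'   `design_type`, `group`, `variance`.
#' @export
replicate_variance <- function(beta, replicate_groups, manifest) {
  beta <- as.matrix(beta)
  groups <- replicate_groups[colnames(beta)]
  if (anyNA(groups)) {
    abort("replicate_groups must cover every sample column",
          class = "methylite_argument_error")
  }
  counts <- table(groups)
  if (any(counts < 2)) {
    abort(paste0("singleton replicate group(s): ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "methylite_validation_error")
  }
  design <- manifest$design_type[match(rownames(beta), manifest$probe_id)]
  if (anyNA(design)) {
    abort("beta rows not covered by the manifest",
          class = "methylite_validation_error")
  }
  out <- purrr::map_dfr(sort(unique(groups)), function(g) {
    cols <- which(groups == g)
    x <- beta[, cols, drop = FALSE]
    m <- rowMeans(x)
    v <- rowSums((x - m)^2) / (length(cols) - 1)
    tibble(probe_id = rownames(beta), design_type = design,
           group = g, variance = unname(v))
  })
  structure(out, class = c("replicate_variance", class(out)))
}

#' @export
glance.replicate_variance <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$design_type),
    n = dplyr::n(),
    q25 = quantile(.data$variance, 0.25),
    median = median(.data$variance),
    q75 = quantile(.data$variance, 0.75),
    .groups = "drop")
}

#' Median distance from reference samples to a set of query replicates
#'
#' For each reference sample, the distance (Euclidean by default) between
#' its Beta profile and each query replicate is computed over the shared
#' probes, and the per-reference-sample median of those distances is
#' returned. Used as a classification score: references of the same class
#' as the query should sit at smaller distances.
#'
#' @param query Numeric Beta matrix (probe x query replicate), or a vector
#'   for a single query profile.
#' @param references Numeric Beta matrix (probe x reference sample) on the
#'   same probe set and order (combine/convert the datasets first).
#' @param labels Optional character vector of reference class labels.
#' @param metric `"euclidean"` (default) or `"manhattan"`.
#' @return A tibble with columns `sample`, `label` (if given) and `score`
#'   (the median distance; smaller = more similar to the query).
#' @export
median_distance_score <- function(query, references, labels = NULL,
                                  metric = c("euclidean", "manhattan")) {
  metric <- match.arg(metric)
  if (is.null(dim(query))) query <- matrix(query, ncol = 1)
  query <- as.matrix(query)
  references <- as.matrix(references)
  if (nrow(query) != nrow(references) ||
      (!is.null(rownames(query)) && !is.null(rownames(references)) &&
       !identical(rownames(query), rownames(references)))) {
    abort("query and reference probes differ; align them first with combine_arrays()/convert_array()",
          class = "methylite_validation_error")
  }
  score <- vapply(seq_len(ncol(references)), function(j) {
    d <- vapply(seq_len(ncol(query)), function(q) {
      diff <- references[, j] - query[, q]
      if (metric == "euclidean") sqrt(sum(diff^2)) else sum(abs(diff))
    }, 0)
    median(d)
  }, 0)
  out <- tibble(sample = colnames(references) %||%
                  paste0("ref", seq_len(ncol(references))),
                score = score)
  if (!is.null(labels)) {
    out <- tibble(sample = out$sample, label = labels, score = out$score)
  }
  out
}

#' ROC curve and AUC from distance scores
#'
#' Sweeps a threshold over the scores, treating *smaller* scores as more
#' positive (the median-distance convention: a reference close to the query
#' is predicted to share its class). The AUC is computed by the trapezoid
#' rule, with ties averaged, and therefore equals the Mann-Whitney U
#' statistic divided by `n_pos * n_neg`.
#'
#' @param scores Numeric vector of per-sample scores (e.g. median
#'   distances).
#' @param positives Logical vector: is each sample a true positive?
#' @return A list of class `roc_result` with `points` (a tibble of
#'   `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_from_scores <- function(scores, positives) {
  positives <- as.logical(positives)
  if (length(scores) != length(positives)) {
    abort("scores and positives must have equal length",
          class = "methylite_argument_error")
  }
  n_pos <- sum(positives)
  n_neg <- sum(!positives)
  if (n_pos == 0 || n_neg == 0) {
    abort("need at least one positive and one negative sample",
          class = "methylite_validation_error")
  }
  # predicted-positive score: negated distance
  s <- -scores
  thresholds <- c(Inf, sort(unique(s), decreasing = TRUE))
  points <- purrr::map_dfr(thresholds, function(th) {
    tibble(threshold = -th,
           fpr = sum(s[!positives] >= th) / n_neg,
           tpr = sum(s[positives] >= th) / n_pos)
  })
  # tie-aware Mann-Whitney AUC via midranks
  r <- rank(s)
  auc <- (sum(r[positives]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = points, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) x$points

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Sample-level quality control summaries
#'
#' Per sample, the medians of `log2(meth + 1)` and `log2(unmeth + 1)`; a
#' sample whose midpoint `(m_median + u_median) / 2` falls below `cutoff`
#' is flagged as poor quality (degraded or failed hybridization shifts both
#' channel medians down together).
#'
#' @param m A [methyl_set()].
#' @param cutoff Flagging threshold on the log2 midpoint (default 10.5).
#' @return A tibble with columns `sample`, `m_median`, `u_median`, `qc`
#'   (the midpoint), `flagged`, and the cutoff as attribute `cutoff`.
#' @export
get_qc <- function(m, cutoff = 10.5) {
  stopifnot(inherits(m, "methyl_set"))
  m_med <- unname(apply(log2(m$meth + 1), 2, median))
  u_med <- unname(apply(log2(m$unmeth + 1), 2, median))
  out <- tibble(sample = colnames(m$meth),
                m_median = m_med, u_median = u_med,
                qc = (m_med + u_med) / 2,
                flagged = (m_med + u_med) / 2 < cutoff)
  attr(out, "cutoff") <- cutoff
  out
}

#' Predict sample sex from sex-chromosome copy number
#'
#' The total signal `meth + unmeth` measures copy number. Per sample, the
#' median `log2(meth + unmeth + 1)` is computed over chrX probes and over
#' chrY probes; their difference `d = yMed - xMed` separates the sexes (XY
#' samples have Y signal, XX samples only background there). Samples with
#' `d > cutoff` are predicted Male.
#'
#' @param m A [methyl_set()].
#' @param manifest Manifest supplying chromosomes; defaults to the
#'   manifest carried by `m`.
#' @param cutoff Decision threshold on `d` (default -2).
#' @return A tibble with columns `sample`, `x_median`, `y_median`, `d`,
#'   `predicted_sex`.
#' @export
get_sex <- function(m, manifest = m$manifest, cutoff = -2) {
  stopifnot(inherits(m, "methyl_set"))
  chrom <- manifest$chromosome[match(rownames(m$meth), manifest$probe_id)]
  x_probes <- which(chrom == "chrX")
  y_probes <- which(chrom == "chrY")
  if (length(x_probes) == 0 || length(y_probes) == 0) {
    abort("manifest has no chrX and/or chrY probes",
          class = "methylite_validation_error")
  }
  cn <- log2(m$meth + m$unmeth + 1)
  x_med <- unname(apply(cn[x_probes, , drop = FALSE], 2, median))
  y_med <- unname(apply(cn[y_probes, , drop = FALSE], 2, median))
  d <- y_med - x_med
  tibble(sample = colnames(m$meth),
         x_median = x_med, y_median = y_med, d = d,
         predicted_sex = ifelse(d > cutoff, "Male", "Female"))
}
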