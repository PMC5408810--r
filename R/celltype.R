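#' Construct a cell-type reference panel
#'
#' @param mean_beta Numeric matrix (probe x cell type) of mean Beta values
#'   in \[0, 1\], with probe ids as row names and cell-type labels as column
#'   names. At least two cell types; no missing values.
#' @param platform Platform the reference was assayed on.
#' @return A list of class `cell_type_reference`.
#' @export
cell_type_reference <- function(mean_beta,
                                platform = c("450K", "EPIC", "VIRTUAL")) {
  platform <- match.arg(platform)
  mean_beta <- as.matrix(mean_beta)
  if (ncol(mean_beta) < 2) {
    abort("a reference needs at least two cell types",
          class = "methylite_validation_error")
  }
  if (is.null(rownames(mean_beta)) && nrow(mean_beta) > 0) {
    abort("mean_beta needs probe ids as row names",
          class = "methylite_validation_error")
  }
  if (anyDuplicated(rownames(mean_beta))) {
    abort("duplicate probe ids in reference",
          class = "methylite_validation_error")
  }
  if (anyNA(mean_beta) || (nrow(mean_beta) > 0 &&
                           (min(mean_beta) < 0 || max(mean_beta) > 1))) {
    abort("reference Beta values must be complete and within [0, 1]",
          class = "methylite_validation_error")
  }
  structure(list(mean_beta = mean_beta,
                 probes = rownames(mean_beta),
                 cell_types = colnames(mean_beta),
                 platform = platform),
            class = "cell_type_reference")
}

#' @export
print.cell_type_reference <- function(x, ...) {
  cat(sprintf("<cell_type_reference> %d probes x %d cell types (%s): %s\n",
              nrow(x$mean_beta), length(x$cell_types), x$platform,
              paste(x$cell_types, collapse = ", ")))
  invisible(x)
}

#' Read a cell-type reference panel from CSV
#' @param path CSV with a `probe_id` first column and one mean-Beta column
#'   per cell type.
#' @inheritParams cell_type_reference
#' @return A [cell_type_reference()].
#' @export
load_reference <- function(path, platform = c("450K", "EPIC", "VIRTUAL")) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "probe_id") {
    abort("reference CSV must have 'probe_id' as first column",
          class = "methylite_format_error")
  }
  mb <- as.matrix(df[-1])
  rownames(mb) <- df$probe_id
  cell_type_reference(mb, platform = platform)
}

#' Write a cell-type reference panel to CSV
#' @param reference A [cell_type_reference()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(reference, path) {
  df <- data.frame(probe_id = reference$probes, reference$mean_beta,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# vectorized per-probe one-way F statistic across groups
row_f_stat <- function(beta, labels) {
  groups <- unique(labels)
  n_tot <- length(labels)
  k <- length(groups)
  grand <- rowMeans(beta)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    cols <- labels == g
    n_g <- sum(cols)
    m_g <- rowMeans(beta[, cols, drop = FALSE])
    ssb <- ssb + n_g * (m_g - grand)^2
    if (n_g > 1) {
      dev <- beta[, cols, drop = FALSE] - m_g
      ssw <- ssw + rowSums(dev^2)
    }
  }
  f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
  stats::pf(f, k - 1, n_tot - k, lower.tail = FALSE)
}

# vectorized per-probe pooled-variance two-sample t statistic
row_t_stat <- function(beta, in_group) {
  x <- beta[, in_group, drop = FALSE]
  y <- beta[, !in_group, drop = FALSE]
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  sp2 <- (rowSums((x - m1)^2) + rowSums((y - m2)^2)) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Select cell-type-discriminative probes from sorted reference samples
#'
#' Probes passing a per-probe one-way F test across cell types (significance
#' `f_alpha`) are ranked per cell type by the pooled-variance two-sample
#' t statistic of that type against all others; the `n_per_type/2` most
#' hypermethylated and `n_per_type/2` most hypomethylated probes per type
#' are retained (t ties broken by probe id for determinism), and the union
#' is deduplicated.
#'
#' @param beta Numeric matrix (probe x reference sample) of Beta values,
#'   probe ids as row names.
#' @param labels Character vector of cell-type labels, one per column; every
#'   type needs at least two samples.
#' @param n_per_type Number of probes to aim for per cell type (default 100).
#' @param f_alpha F-test significance threshold (default 1e-8).
#' @param platform Platform tag for the returned reference.
#' @return A list of class `probe_selection` with `probes` (sorted ids),
#'   `reference` (a [cell_type_reference()] of per-type mean Betas on the
#'   selected probes) and `n_candidates` (probes passing the F test).
#' @export
select_discriminative_probes <- function(beta, labels, n_per_type = 100,
                                         f_alpha = 1e-8,
                                         platform = c("450K", "EPIC", "VIRTUAL")) {
  beta <- as.matrix(beta)
  labels <- as.character(labels)
  if (length(labels) != ncol(beta)) {
    abort("one label per reference sample required",
          class = "methylite_argument_error")
  }
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(paste0("cell type(s) with fewer than 2 reference samples: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "methylite_validation_error")
  }
  types <- sort(unique(labels))

  p_f <- row_f_stat(beta, labels)
  passing <- which(!is.na(p_f) & p_f < f_alpha)
  if (length(passing) == 0) {
    warn("no probes pass the across-type F test; empty selection")
    ref <- cell_type_reference(
      matrix(numeric(0), 0, length(types),
             dimnames = list(character(0), types)),
      platform = match.arg(platform))
    return(structure(list(probes = character(0), reference = ref,
                          n_candidates = 0L),
                     class = "probe_selection"))
  }

  cand <- beta[passing, , drop = FALSE]
  half <- ceiling(n_per_type / 2)
  selected <- character(0)
  for (type in types) {
    t_stat <- row_t_stat(cand, labels == type)
    ord_hyper <- order(-t_stat, rownames(cand))
    ord_hypo <- order(t_stat, rownames(cand))
    if (nrow(cand) < n_per_type) {
      warn(paste0("only ", nrow(cand), " probes pass the F test for type '",
                  type, "' (requested ", n_per_type, "); taking all"))
    }
    selected <- c(selected,
                  rownames(cand)[ord_hyper[seq_len(min(half, nrow(cand)))]],
                  rownames(cand)[ord_hypo[seq_len(min(half, nrow(cand)))]])
  }
  selected <- sort(unique(selected))

  mean_by_type <- vapply(types, function(type) {
    rowMeans(beta[selected, labels == type, drop = FALSE])
  }, numeric(length(selected)))
  mean_by_type <- matrix(mean_by_type, ncol = length(types),
                         dimnames = list(selected, types))
  structure(list(probes = selected,
                 reference = cell_type_reference(
                   pmin(pmax(mean_by_type, 0), 1),
                   platform = match.arg(platform)),
                 n_candidates = length(passing)),
            class = "probe_selection")
}

#' Constrained projection of a methylation profile onto reference profiles
#'
#' Solves `argmin_b || y - X b ||^2` subject to `b >= 0` and (by default)
#' `sum(b) <= 1`, as a convex quadratic program. The inequality sum
#' constraint leaves an implicit "unexplained" component and is robust to
#' cell types missing from the reference; `sum_constraint = "eq1"` forces
#' the proportions to sum to one. If the cross-product matrix is not
#' positive definite (collinear reference profiles), a tiny ridge is added
#' and the minimum-norm optimum is returned with a warning.
#'
#' @param y Numeric vector of Beta values over the reference probes.
#' @param X Numeric matrix (probe x cell type) of reference mean Betas.
#' @param sum_constraint `"le1"` (default) or `"eq1"`.
#' @return A list with `proportions` (named, >= 0), `residual_norm` and
#'   `objective` (residual sum of squares).
#' @export
constrained_projection <- function(y, X, sum_constraint = c("le1", "eq1")) {
  sum_constraint <- match.arg(sum_constraint)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) {
    abort("y must align with the rows of X",
          class = "methylite_argument_error")
  }
  k <- ncol(X)
  D <- crossprod(X)
  d <- as.vector(crossprod(X, y))
  A <- cbind(-rep(1, k), diag(k))
  b0 <- c(-1, rep(0, k))
  meq <- if (sum_constraint == "eq1") 1L else 0L
  if (meq == 1L) {
    A[, 1] <- rep(1, k)
    b0[1] <- 1
  }
  sol <- tryCatch(
    quadprog::solve.QP(D, d, A, b0, meq = meq),
    error = function(e) {
      warn(paste0("reference profiles are collinear (",
                  conditionMessage(e),
                  "); returning the minimum-norm optimum"))
      ridge <- diag(1e-8 * max(mean(diag(D)), 1), k)
      quadprog::solve.QP(D + ridge, d, A, b0, meq = meq)
    })
  beta <- sol$solution
  beta[beta < 0] <- 0  # solver round-off just below the bound
  names(beta) <- colnames(X)
  resid <- y - X %*% beta
  list(proportions = beta,
       residual_norm = sqrt(sum(resid^2)),
       objective = sum(resid^2))
}

#' Estimate cell-type proportions of heterogeneous samples
#'
#' Reference-based deconvolution: each sample's Beta profile over the
#' reference's discriminative probes is projected onto the reference
#' mean-Beta profiles under non-negativity and sum constraints. When the
#' target was assayed on a different platform, it is first cast onto the
#' reference platform ([convert_array()] semantics: Beta-level matching by
#' probe id), so only probes common to both arrays are used.
#'
#' @param target A [methyl_set()] (Betas computed with `beta_offset`) or a
#'   numeric Beta matrix (probe x sample, probe ids as row names).
#' @param reference A [cell_type_reference()] or [probe_selection()] result.
#' @param sum_constraint Passed to [constrained_projection()].
#' @param overlap_floor Minimum tolerated fraction of reference probes found
#'   in the target (default 0.5).
#' @param beta_offset Offset used when `target` is a [methyl_set()]
#'   (default 100).
#' @return A tibble of class `proportion_estimate`: one row per sample, one
#'   column per cell type, plus `residual_norm`. Attributes `probes_used`
#'   and `overlap_fraction` record the cross-platform overlap.
#' @export
estimate_cell_counts <- function(target, reference,
                                 sum_constraint = c("le1", "eq1"),
                                 overlap_floor = 0.5, beta_offset = 100) {
  sum_constraint <- match.arg(sum_constraint)
  if (inherits(reference, "probe_selection")) reference <- reference$reference
  stopifnot(inherits(reference, "cell_type_reference"))
  if (nrow(reference$mean_beta) == 0) {
    abort("empty reference (no discriminative probes selected)",
          class = "methylite_validation_error")
  }
  beta <- if (inherits(target, "methyl_set")) {
    get_beta(target, offset = beta_offset)
  } else {
    as.matrix(target)
  }
  if (is.null(rownames(beta))) {
    abort("target Betas need probe ids as row names",
          class = "methylite_argument_error")
  }
  common <- intersect(reference$probes, rownames(beta))
  overlap <- length(common) / length(reference$probes)
  if (overlap < overlap_floor) {
    abort(sprintf(
      "only %d of %d reference probes present in target (%.1f%% < floor %.1f%%)",
      length(common), length(reference$probes), 100 * overlap,
      100 * overlap_floor),
      class = "methylite_validation_error")
  }
  X <- reference$mean_beta[common, , drop = FALSE]
  Y <- beta[common, , drop = FALSE]
  fits <- lapply(seq_len(ncol(Y)), function(s) {
    constrained_projection(Y[, s], X, sum_constraint = sum_constraint)
  })
  props <- do.call(rbind, lapply(fits, `[[`, "proportions"))
  out <- tibble(sample = colnames(Y))
  for (ct in reference$cell_types) out[[ct]] <- props[, ct]
  out$residual_norm <- vapply(fits, `[[`, 0, "residual_norm")
  structure(out,
            class = c("proportion_estimate", class(out)),
            cell_types = reference$cell_types,
            probes_used = common,
            overlap_fraction = overlap)
}

#' @export
tidy.proportion_estimate <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = dplyr::all_of(attr(x, "cell_types")),
                      names_to = "cell_type", values_to = "proportion")
}

#' @export
glance.proportion_estimate <- function(x, ...) {
  cts <- attr(x, "cell_types")
  tibble(n_samples = nrow(x),
         n_cell_types = length(cts),
         n_probes_used = length(attr(x, "probes_used")),
         overlap_fraction = attr(x, "overlap_fraction"),
         mean_residual_norm = mean(x$residual_norm),
         mean_explained = mean(rowSums(as.matrix(x[cts]))))
}
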