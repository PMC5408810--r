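# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the quadrature oracle integrates the posterior
# numerically, the QP oracle enumerates active sets, the AUC oracle counts
# pairs.

# E[S | X = x] for X = S + B, S ~ Exp(mean alpha), B ~ N(mu, sigma^2),
# by numeric integration of the unnormalized posterior over s > 0.
quad_normexp_oracle <- function(mu, sigma, alpha, x) {
  vapply(x, function(xi) {
    logw <- function(s) -s / alpha + dnorm(xi - s, mu, sigma, log = TRUE)
    mode <- max(xi - mu - sigma^2 / alpha, 0)
    shift <- logw(mode)
    w <- function(s) exp(logw(s) - shift)
    upper <- mode + 20 * sigma  # posterior is a truncated normal, sd sigma
    denom <- stats::integrate(w, 0, upper, rel.tol = 1e-12,
                              abs.tol = 0)$value
    numer <- stats::integrate(function(s) s * w(s), 0, upper,
                              rel.tol = 1e-12, abs.tol = 0)$value
    numer / denom
  }, 0)
}

# Exhaustive active-set enumeration for
#   min ||y - X b||^2  s.t.  b >= 0,  sum(b) <= 1.
# For every subset Z of variables pinned to zero and each state of the sum
# constraint (inactive / binding), solve the equality-constrained least
# squares via the KKT system and keep the best feasible point.
enum_qp_oracle <- function(y, X) {
  k <- ncol(X)
  best <- list(objective = Inf, beta = rep(0, k))
  for (mask in 0:(2^k - 1)) {
    zero <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    free <- setdiff(seq_len(k), zero)
    for (sum_binding in c(FALSE, TRUE)) {
      beta <- rep(0, k)
      if (length(free) > 0) {
        Xf <- X[, free, drop = FALSE]
        if (!sum_binding) {
          fit <- tryCatch(qr.solve(crossprod(Xf), crossprod(Xf, y)),
                          error = function(e) NULL)
          if (is.null(fit)) next
          beta[free] <- fit
        } else {
          nf <- length(free)
          kkt <- rbind(cbind(2 * crossprod(Xf), rep(1, nf)),
                       c(rep(1, nf), 0))
          rhs <- c(2 * as.vector(crossprod(Xf, y)), 1)
          sol <- tryCatch(qr.solve(kkt, rhs), error = function(e) NULL)
          if (is.null(sol)) next
          beta[free] <- sol[seq_len(nf)]
        }
      } else if (sum_binding) next
      if (any(beta < -1e-9) || sum(beta) > 1 + 1e-9) next
      obj <- sum((y - X %*% beta)^2)
      if (obj < best$objective) best <- list(objective = obj, beta = beta)
    }
  }
  best
}

# Tie-aware AUC by exhaustive pair counting (smaller distance = positive).
pair_count_auc <- function(scores, positives) {
  pos <- scores[positives]
  neg <- scores[!positives]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Handcrafted six-probe manifest: 2 Type I Grn, 2 Type I Red, 2 Type II,
# with sex chromosomes represented.
tiny_manifest <- function() {
  probe_manifest(data.frame(
    probe_id = c("cgA", "cgB", "cgC", "cgD", "cgE", "cgF"),
    design_type = c("I", "I", "I", "I", "II", "II"),
    channel = c("Grn", "Grn", "Red", "Red", "Both", "Both"),
    address_A = c(10L, 20L, 30L, 40L, 50L, 60L),
    address_B = c(11L, 21L, 31L, 41L, NA, NA),
    chromosome = c("chr1", "chrX", "chr2", "chrY", "chr3", "chrX")
  ), platform = "450K")
}

tiny_controls <- function() {
  control_manifest(data.frame(
    address = c(900L, 901L, 910L, 911L),
    control_type = c("NORM_C", "NORM_C", "NORM_A", "NORM_A"),
    expected_channel = c("Grn", "Grn", "Red", "Red")))
}

# Raw set over the tiny manifest + controls with a constant fill, so tests
# can overwrite individual addresses.
tiny_raw <- function(samples = "s1", fill = 100) {
  addr <- sort(c(manifest_addresses(tiny_manifest()), tiny_controls()$address))
  n <- length(addr)
  raw_intensity_set(addr,
                    matrix(fill, n, length(samples),
                           dimnames = list(addr, samples)),
                    matrix(fill, n, length(samples),
                           dimnames = list(addr, samples)),
                    samples)
}

set_intensity <- function(raw, address, channel, sample, value) {
  raw[[tolower(channel)]][as.character(address), sample] <- value
  raw
}
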