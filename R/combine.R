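# Probe-level and locus-level combination of datasets from different array
# generations. Combination is pure row/column selection plus relabeling: no
# retained value is ever altered.

# probes shared with identical chemistry (design type + channel)
shared_probe_ids <- function(man_a, man_b) {
  key <- function(m) paste(m$probe_id, m$design_type, m$channel, sep = "\r")
  ids_a <- man_a$probe_id[key(man_a) %in% key(man_b)]
  ids_a
}

virtual_manifest <- function(man, keep_ids, out_type) {
  kept <- man[match(keep_ids, man$probe_id), , drop = FALSE]
  probe_manifest(as_tibble(kept), platform = "VIRTUAL", behaves_as = out_type)
}

subset_probes <- function(x, keep_ids, new_manifest) {
  UseMethod("subset_probes")
}

#' @export
subset_probes.methyl_set <- function(x, keep_ids, new_manifest) {
  out <- x
  out$manifest <- new_manifest
  out$meth <- x$meth[keep_ids, , drop = FALSE]
  out$unmeth <- x$unmeth[keep_ids, , drop = FALSE]
  out
}

#' @export
subset_probes.probe_signal_set <- function(x, keep_ids, new_manifest) {
  out <- x
  out$manifest <- new_manifest
  out$meth <- x$meth[keep_ids, , drop = FALSE]
  out$unmeth <- x$unmeth[keep_ids, , drop = FALSE]
  keep_oob <- function(oob) {
    ids <- sub("\\.[AB]$", "", rownames(oob))
    oob[ids %in% keep_ids, , drop = FALSE]
  }
  out$oob_grn <- keep_oob(x$oob_grn)
  out$oob_red <- keep_oob(x$oob_red)
  out
}

bind_samples <- function(a, b, new_manifest) {
  stopifnot(identical(rownames(a$meth), rownames(b$meth)))
  out <- a
  out$manifest <- new_manifest
  out$meth <- cbind(a$meth, b$meth)
  out$unmeth <- cbind(a$unmeth, b$unmeth)
  if (inherits(a, "probe_signal_set")) {
    out$sample_ids <- c(a$sample_ids, b$sample_ids)
    out$oob_grn <- cbind(a$oob_grn, b$oob_grn)
    out$oob_red <- cbind(a$oob_red, b$oob_red)
  }
  out
}

sample_names_of <- function(x) {
  if (!is.null(x$sample_ids)) x$sample_ids else colnames(x$meth)
}

check_combinable <- function(a, b) {
  same_kind <- (inherits(a, "methyl_set") && inherits(b, "methyl_set")) ||
    (inherits(a, "probe_signal_set") && inherits(b, "probe_signal_set"))
  if (!same_kind) {
    abort("cannot combine datasets at different representation levels",
          class = "methylite_validation_error")
  }
  dup <- intersect(sample_names_of(a), sample_names_of(b))
  if (length(dup) > 0) {
    abort(paste0("duplicated sample_id(s) across inputs: ",
                 paste(dup, collapse = ", ")),
          class = "methylite_validation_error")
  }
}

record_provenance <- function(out, a, b) {
  prov_of <- function(x) {
    p <- attr(x$manifest, "sample_platforms")
    if (is.null(p)) {
      stats::setNames(rep(platform_id(x), length(sample_names_of(x))),
                      sample_names_of(x))
    } else p
  }
  attr(out$manifest, "sample_platforms") <- c(prov_of(a), prov_of(b))
  out
}

#' Combine two datasets into a virtual array at the probe level
#'
#' Restricts both inputs to the probes measured with the same probe id *and*
#' the same chemistry (design type and channel) on both platforms, then
#' concatenates their samples. The result carries a `VIRTUAL` manifest that
#' behaves as the platform chosen by `out_type`; each sample's native
#' platform is recorded as provenance.
#'
#' @param a,b Two datasets of the same kind (both [methyl_set()] or both
#'   `probe_signal_set`) with disjoint sample ids.
#' @param out_type Platform the virtual array should behave as
#'   (`"450K"` or `"EPIC"`).
#' @return Same kind as the inputs, on the shared-probe virtual manifest.
#' @export
combine_arrays <- function(a, b, out_type = c("450K", "EPIC")) {
  out_type <- match.arg(out_type)
  check_combinable(a, b)
  keep <- shared_probe_ids(a$manifest, b$manifest)
  if (length(keep) == 0) {
    abort("no probes shared (same probe and chemistry) between inputs",
          class = "methylite_validation_error")
  }
  vman <- virtual_manifest(a$manifest, keep, out_type)
  out <- bind_samples(subset_probes(a, keep, vman),
                      subset_probes(b, keep, vman), vman)
  out <- record_provenance(out, a, b)
  if (inherits(out, "methyl_set")) {
    out <- log_step(out, "combine_arrays",
                    list(out_type = out_type, n_shared = length(keep)))
  }
  out
}

#' Combine two datasets at the CpG locus level
#'
#' After the methylated/unmethylated channels have been formed, loci can be
#' matched by probe id alone: a locus assayed by a Type I probe on one
#' platform and a Type II probe on the other is still the same CpG, so it is
#' retained here even though [combine_arrays()] would exclude it. The native
#' design type of each platform is kept (columns `design_type` and
#' `design_type_other`) for design-stratified analyses.
#'
#' @param a,b Two [methyl_set()] objects with disjoint sample ids.
#' @inheritParams combine_arrays
#' @return A [methyl_set()] on the locus-intersection virtual manifest.
#' @export
combine_at_locus_level <- function(a, b, out_type = c("450K", "EPIC")) {
  out_type <- match.arg(out_type)
  if (!inherits(a, "methyl_set") || !inherits(b, "methyl_set")) {
    abort("locus-level combination requires methyl_set inputs (post meth/unmeth)",
          class = "methylite_validation_error")
  }
  check_combinable(a, b)
  keep <- intersect(a$manifest$probe_id, b$manifest$probe_id)
  if (length(keep) == 0) {
    abort("no probe ids shared between inputs",
          class = "methylite_validation_error")
  }
  vman <- virtual_manifest(a$manifest, keep, out_type)
  vman$design_type_other <-
    b$manifest$design_type[match(keep, b$manifest$probe_id)]
  out <- bind_samples(subset_probes(a, keep, vman),
                      subset_probes(b, keep, vman), vman)
  out <- record_provenance(out, a, b)
  log_step(out, "combine_at_locus_level",
           list(out_type = out_type, n_shared = length(keep)))
}

#' Cast a dataset onto another platform
#'
#' Projects the dataset onto the probes present (same probe and chemistry)
#' on the target platform. Converting to the dataset's own platform is the
#' identity; converting back after a conversion returns the shared probe set
#' (a projection, not a bijection).
#'
#' @param x A [methyl_set()] or `probe_signal_set`.
#' @param target A [probe_manifest()] describing the target platform.
#' @return Same kind as `x`, restricted to the target-shared probes and
#'   tagged as a virtual array behaving like the target platform.
#' @export
convert_array <- function(x, target) {
  stopifnot(inherits(target, "probe_manifest"))
  keep <- shared_probe_ids(x$manifest, target)
  if (length(keep) == 0) {
    abort("no probes shared with the target platform",
          class = "methylite_validation_error")
  }
  target_platform <- attr(target, "behaves_as") %||% attr(target, "platform")
  if (identical(keep, x$manifest$probe_id) &&
      identical(platform_id(x), target_platform)) {
    return(x)
  }
  vman <- virtual_manifest(x$manifest, keep,
                           if (target_platform == "VIRTUAL") "450K"
                           else target_platform)
  out <- subset_probes(x, keep, vman)
  if (inherits(out, "methyl_set")) {
    out <- log_step(out, "convert_array",
                    list(target = target_platform, n_shared = length(keep)))
  }
  out
}
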