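# Depth scaling and variance stabilization of binned coverage.

#' Per-sample depth scaling factors
#'
#' A sample's cumulative coverage level is the sum of its raw per-bin mean
#' coverage over all phenotyped genes' kept bins; its factor is that total
#' divided by the median total across samples. Dividing by the factors makes
#' every sample's total equal the median pre-scaling total.
#'
#' @param raws list of [binned_coverage()] objects at stage `raw_mean`, all
#'   sharing the same samples (one entry per gene).
#' @return object of class `ScalingFactors`: list with `sample_ids`,
#'   `factors` (positive, named), `reference_level` (the median total).
#' @export
scaling_factors <- function(raws) {
  stopifnot(length(raws) >= 1)
  for (x in raws) check_stage(x, "raw_mean")
  sample_ids <- raws[[1]]$sample_ids
  totals <- rep(0, length(sample_ids))
  # accumulate in sorted gene order so totals are bit-identical no matter
  # how the caller ordered or batched the genes
  raws <- raws[order(vapply(raws, `[[`, "", "gene_id"))]
  for (x in raws) {
    if (!identical(x$sample_ids, sample_ids))
      stop("inconsistent sample sets across genes (gene ", x$gene_id, ")")
    totals <- totals + rowSums(x$values)
  }
  if (any(!is.finite(totals))) stop("non-finite coverage totals")
  zero <- which(totals == 0)
  if (length(zero))
    stop("sample(s) with zero total coverage: ",
         paste(sample_ids[zero], collapse = ", "))
  ref <- stats::median(totals)
  structure(list(sample_ids = sample_ids,
                 factors = stats::setNames(totals / ref, sample_ids),
                 reference_level = ref),
            class = "ScalingFactors")
}

#' Apply depth scaling factors to one gene's binned coverage
#'
#' @param raw a [binned_coverage()] at stage `raw_mean`.
#' @param factors a [scaling_factors()] object over the same samples.
#' @return a [binned_coverage()] at stage `scaled`.
#' @export
apply_scaling <- function(raw, factors) {
  check_stage(raw, "raw_mean")
  if (!identical(raw$sample_ids, factors$sample_ids))
    stop("sample sets of coverage and scaling factors differ (gene ",
         raw$gene_id, ")")
  binned_coverage(raw$gene_id, raw$bin_ids, raw$sample_ids,
                  raw$values / factors$factors, stage = "scaled")
}

#' Pseudocount log2 transform
#'
#' `log2(value + pseudocount)`, stabilizing the variance of depth-scaled
#' binned coverage ahead of PCA.
#'
#' @param scaled a [binned_coverage()] at stage `scaled`.
#' @param pseudocount positive pseudocount (default 8).
#' @return a [binned_coverage()] at stage `log2`.
#' @export
log_transform <- function(scaled, pseudocount = 8) {
  stopifnot(pseudocount > 0)
  check_stage(scaled, "scaled")
  if (any(scaled$values < 0))
    stop("negative coverage reaching log transform (gene ", scaled$gene_id, ")")
  binned_coverage(scaled$gene_id, scaled$bin_ids, scaled$sample_ids,
                  log2(scaled$values + pseudocount), stage = "log2")
}

#' Write scaling factors as two-column TSV
#' @param factors a [scaling_factors()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_factors <- function(factors, path) {
  data.table::fwrite(
    data.table::data.table(sample_id = factors$sample_ids,
                           factor = sprintf("%.15g", factors$factors)),
    path, sep = "\t", quote = FALSE)
  invisible(path)
}
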