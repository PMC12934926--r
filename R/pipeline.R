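# End-to-end orchestration: calibrate -> bin -> normalize -> (residualize)
# -> fit, and model application to new datasets. Genes are streamed one at a
# time; results are independent of processing order.

#' Default pipeline parameters
#'
#' All tunables of the phenotyping procedure with their default values:
#' pseudocount 8, target mean bins 256, 128 calibration genes, 256 binning
#' samples, max bin size 1024, variance target 0.80, max 16 components,
#' nonzero-coverage fraction 0.5, KDP retention alpha 0.01, flank 1000 bp.
#'
#' @return named list of defaults.
#' @export
default_params <- function() {
  list(flank_bp = 1000L, pseudocount = 8, target_mean_bins = 256L,
       n_calibration_genes = 128L, n_binning_samples = 256L,
       max_bin_size = 1024L, variance_target = 0.80, max_components = 16L,
       min_nonzero_fraction = 0.5, alpha = 0.01, seed = 1L)
}

merge_params <- function(overrides = list()) {
  p <- default_params()
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides
  p
}

#' Define bin schemes for a gene set
#'
#' Calibrates the global segmentation threshold on a seeded sample of genes
#' and samples, then builds each gene's adaptive scheme from its variance
#' profile over the binning samples.
#'
#' @param regions named list of [gene_region()].
#' @param source a coverage source.
#' @param params list of overrides of [default_params()].
#' @return named list of [bin_scheme()] with the calibration recorded in an
#'   attribute `threshold`.
#' @export
define_bins <- function(regions, source, params = list()) {
  p <- merge_params(params)
  th <- calibrate_threshold(regions, source,
                            target_mean_bins = p$target_mean_bins,
                            n_calibration_genes = p$n_calibration_genes,
                            n_binning_samples = p$n_binning_samples,
                            pseudocount = p$pseudocount, seed = p$seed)
  cal_samples <- attr(th, "calibration_samples")
  cal_profiles <- attr(th, "profiles")
  schemes <- lapply(regions, function(rg) {
    prof <- cal_profiles[[rg$gene_id]] %||%
      variance_profile(source$fetch(rg, cal_samples), p$pseudocount)
    adaptive_bin_scheme(rg, prof, as.numeric(th),
                        max_bin_size = p$max_bin_size,
                        pseudocount = p$pseudocount, seed = p$seed)
  })
  attr(schemes, "threshold") <- as.numeric(th)
  schemes
}

#' Bin and normalize a dataset
#'
#' Streams genes through [mean_coverage_per_bin()], computes per-sample depth
#' scaling factors over all genes' kept bins, and returns depth-scaled,
#' log2(x + pseudocount)-transformed binned coverage.
#'
#' @param regions named list of [gene_region()].
#' @param schemes named list of [bin_scheme()].
#' @param source a coverage source.
#' @param params list of overrides of [default_params()].
#' @return list with `raw` (stage raw_mean, per gene), `normalized`
#'   (stage log2, per gene), `factors` (a `ScalingFactors`).
#' @export
bin_and_normalize <- function(regions, schemes, source, params = list()) {
  p <- merge_params(params)
  ids <- intersect(names(regions), names(schemes))
  ids <- ids[vapply(schemes[ids], function(s) nrow(s$bins) > 0, TRUE)]
  raw <- lapply(ids, function(g)
    mean_coverage_per_bin(source$fetch(regions[[g]], source$sample_ids),
                          schemes[[g]], regions[[g]]))
  names(raw) <- ids
  factors <- scaling_factors(raw)
  normalized <- lapply(raw, function(x)
    log_transform(apply_scaling(x, factors), p$pseudocount))
  list(raw = raw, normalized = normalized, factors = factors)
}

#' Fit a model store on a training dataset
#'
#' Runs the full training pipeline: threshold calibration and binning,
#' depth scaling, log transform, gene filtering, optional residualization
#' against KDPs, and per-gene PCA model fitting.
#'
#' @param regions named list of [gene_region()].
#' @param source a coverage source over the training samples.
#' @param params list of overrides of [default_params()].
#' @param kdps optional `KDPTable`; when given, models are fitted on
#'   residualized coverage (flavor `rddp`). Genes without KDPs are fitted
#'   un-residualized, with a warning.
#' @param schemes optional precomputed bin schemes (skips calibration).
#' @return a model store: list with `schemes`, `models`, `params`,
#'   `regions` (metadata for BED export), `reports` (residualization
#'   reports, when applicable).
#' @export
fit_ddp_models <- function(regions, source, params = list(), kdps = NULL,
                           schemes = NULL) {
  p <- merge_params(params)
  if (is.null(schemes)) schemes <- define_bins(regions, source, p)
  norm <- bin_and_normalize(regions, schemes, source, p)
  kept <- filter_genes(norm$raw, p$min_nonzero_fraction)
  models <- list(); reports <- list()
  for (g in kept) {
    X <- norm$normalized[[g]]
    flavor <- "ddp"
    if (!is.null(kdps)) {
      K <- kdps$genes[[g]]
      if (is.null(K)) {
        warning("gene ", g, " missing from KDP table; fitting without ",
                "residualization")
      } else {
        rr <- residualize_gene(X, K, p$alpha)
        X <- rr$residual
        reports[[g]] <- rr$report
        flavor <- "rddp"
      }
    }
    models[[g]] <- fit_gene_model(X, p$variance_target, p$max_components,
                                  flavor = flavor)
  }
  list(schemes = schemes[kept], models = models, params = p,
       regions = regions[kept], reports = reports,
       threshold = attr(schemes, "threshold"))
}

#' Apply a model store to a dataset
#'
#' Re-bins the target dataset with the stored schemes, re-filters genes on
#' the target samples, computes the target dataset's own depth scaling
#' factors, normalizes, optionally residualizes against the supplied KDPs
#' (required for rDDP stores), and projects every gene onto its stored
#' loadings using the training standardization parameters.
#'
#' @param store a model store from [fit_ddp_models()] or [load_models()].
#' @param source a coverage source over the target samples.
#' @param kdps optional `KDPTable` for rDDP stores.
#' @param restandardize see [apply_gene_model()].
#' @return a [phenotype_table()].
#' @export
apply_ddp_models <- function(store, source, kdps = NULL,
                             restandardize = FALSE) {
  p <- store$params
  norm <- bin_and_normalize(store$regions, store$schemes, source, p)
  kept <- filter_genes(norm$raw, p$min_nonzero_fraction)
  kept <- intersect(kept, names(store$models))
  projections <- list()
  for (g in kept) {
    X <- norm$normalized[[g]]
    model <- store$models[[g]]
    if (model$flavor == "rddp") {
      K <- if (!is.null(kdps)) kdps$genes[[g]] else NULL
      if (is.null(K)) {
        warning("gene ", g, ": rDDP model but no KDPs supplied; skipping")
        next
      }
      X <- residualize_gene(X, K, p$alpha)$residual
    }
    projections[[g]] <- apply_gene_model(model, X, restandardize)
  }
  phenotype_table(projections)
}
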