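# Per-gene PCA phenotyping: fit, apply, export.

MODEL_STORE_VERSION <- "ddpheno-store/1"

#' Filter genes by nonzero total coverage
#'
#' A gene is kept iff the fraction of samples with nonzero total raw binned
#' coverage is at least `min_nonzero_fraction` (inclusive). Applied both at
#' model fitting and again, on the target samples, at model application.
#'
#' @param raws named list of [binned_coverage()] at stage `raw_mean`.
#' @param min_nonzero_fraction inclusive threshold (default 0.5).
#' @return character vector of kept gene IDs.
#' @export
filter_genes <- function(raws, min_nonzero_fraction = 0.5) {
  keep <- vapply(raws, function(x) {
    check_stage(x, "raw_mean")
    mean(rowSums(x$values) > 0) >= min_nonzero_fraction
  }, logical(1))
  names(raws)[keep]
}

#' Fit a per-gene PCA model
#'
#' Bins are standardized with training mean and standard deviation
#' (zero-variance bins get sd = 1 so they contribute a constant 0), a PCA is
#' fitted, and components are retained up to the smallest number whose
#' cumulative explained-variance ratio reaches `variance_target`, capped at
#' `max_components` and at the rank bound `min(#bins, #samples - 1)`.
#' Each component's sign is fixed so that its largest-|loading| bin (ties:
#' lowest bin index) has a positive loading, making fits reproducible.
#'
#' @param X a [binned_coverage()] at stage `log2` or `residual`.
#' @param variance_target cumulative explained-variance target (default 0.80).
#' @param max_components retained-component cap (default 16).
#' @param flavor `"ddp"` (normalized coverage) or `"rddp"` (residualized).
#' @return object of class `GenePCAModel`.
#' @export
fit_gene_model <- function(X, variance_target = 0.80, max_components = 16L,
                           flavor = c("ddp", "rddp")) {
  flavor <- match.arg(flavor)
  check_stage(X, c("log2", "residual"))
  n <- length(X$sample_ids); p <- length(X$bin_ids)
  if (n < 2) stop("PCA requires >= 2 samples (gene ", X$gene_id, ")")
  if (p < 1) stop("no bins for gene ", X$gene_id)

  mu <- colMeans(X$values)
  sdv <- apply(X$values, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X$values, 2, mu), 2, sdv, "/")

  rank_bound <- min(p, n - 1L)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  if (total <= .Machine$double.eps * p) {
    # constant data: nothing to phenotype
    return(structure(list(
      gene_id = X$gene_id, bin_ids = X$bin_ids, train_mean = mu,
      train_sd = sdv, loadings = matrix(0, 0, p), explained_variance_ratio = numeric(0),
      n_components = 0L, variance_target = variance_target,
      max_components = as.integer(max_components), flavor = flavor),
      class = "GenePCAModel"))
  }
  evr <- ev / total
  k_var <- which(cumsum(evr) >= variance_target - 1e-12)[1]
  if (is.na(k_var)) k_var <- length(evr)
  k <- min(k_var, max_components, rank_bound)

  load <- t(pc$rotation[, seq_len(k), drop = FALSE])  # k x p
  for (c_i in seq_len(k)) {
    j <- which.max(abs(load[c_i, ]))   # ties -> lowest index
    if (load[c_i, j] < 0) load[c_i, ] <- -load[c_i, ]
  }
  dimnames(load) <- list(paste0("PC", seq_len(k)), X$bin_ids)
  structure(list(
    gene_id = X$gene_id, bin_ids = X$bin_ids,
    train_mean = stats::setNames(mu, X$bin_ids),
    train_sd = stats::setNames(sdv, X$bin_ids),
    loadings = load,
    explained_variance_ratio = evr[seq_len(k)],
    n_components = as.integer(k),
    variance_target = variance_target,
    max_components = as.integer(max_components),
    flavor = flavor), class = "GenePCAModel")
}

#' @export
print.GenePCAModel <- function(x, ...) {
  cat(sprintf("GenePCAModel %s (%s): %d bins -> %d components (cum EVR %.3f)\n",
              x$gene_id, x$flavor, length(x$bin_ids), x$n_components,
              sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project a dataset onto a fitted gene model
#'
#' Standardizes `X_new` with the *training* means and standard deviations
#' stored in the model (so phenotype dimensions correspond across datasets)
#' and projects onto the retained loadings. Optionally re-standardizes with
#' the new dataset's own parameters instead.
#'
#' @param model a [fit_gene_model()] result.
#' @param X_new a [binned_coverage()] at stage `log2` or `residual` whose
#'   `bin_ids` exactly equal the model's.
#' @param restandardize if TRUE, standardize with `X_new`'s own per-bin mean
#'   and sd instead of the training parameters (default FALSE).
#' @return samples x components numeric matrix of phenotype values.
#' @export
apply_gene_model <- function(model, X_new, restandardize = FALSE) {
  check_stage(X_new, c("log2", "residual"))
  if (!identical(model$bin_ids, X_new$bin_ids))
    stop("bin IDs of gene ", model$gene_id, " do not match the model; ",
         "re-bin the coverage with the stored bin scheme")
  if (model$n_components == 0L)
    return(matrix(0, length(X_new$sample_ids), 0,
                  dimnames = list(X_new$sample_ids, NULL)))
  if (restandardize) {
    mu <- colMeans(X_new$values)
    sdv <- apply(X_new$values, 2, stats::sd)
    sdv[sdv == 0] <- 1
  } else {
    mu <- model$train_mean
    sdv <- model$train_sd
  }
  Z <- sweep(sweep(X_new$values, 2, mu), 2, sdv, "/")
  proj <- Z %*% t(model$loadings)
  dimnames(proj) <- list(X_new$sample_ids, rownames(model$loadings))
  proj
}

#' Assemble per-gene projections into a phenotype table
#'
#' Phenotype IDs are `<gene_id>:PC<rank>` with ranks contiguous from 1;
#' the group ID is the gene ID.
#'
#' @param projections named list (by gene) of samples x components matrices
#'   from [apply_gene_model()].
#' @return object of class `PhenotypeTable`: list with `values`
#'   (phenotypes x samples), `phenotype_id`, `gene_id`, `rank`, `sample_ids`.
#' @export
phenotype_table <- function(projections) {
  projections <- projections[vapply(projections, ncol, 0L) > 0]
  if (!length(projections)) {
    return(structure(list(values = matrix(0, 0, 0), phenotype_id = character(0),
                          gene_id = character(0), rank = integer(0),
                          sample_ids = character(0)),
                     class = "PhenotypeTable"))
  }
  sample_ids <- rownames(projections[[1]])
  rows <- lapply(names(projections), function(g) {
    pr <- projections[[g]]
    if (!identical(rownames(pr), sample_ids))
      stop("inconsistent samples across genes in phenotype table")
    list(values = t(pr), gene_id = rep(g, ncol(pr)), rank = seq_len(ncol(pr)))
  })
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  gene_id <- unlist(lapply(rows, `[[`, "gene_id"))
  rank <- unlist(lapply(rows, `[[`, "rank"))
  phenotype_id <- paste0(gene_id, ":PC", rank)
  rownames(values) <- phenotype_id
  structure(list(values = values, phenotype_id = phenotype_id,
                 gene_id = gene_id, rank = as.integer(rank),
                 sample_ids = sample_ids),
            class = "PhenotypeTable")
}

#' @export
print.PhenotypeTable <- function(x, ...) {
  cat(sprintf("PhenotypeTable: %d phenotypes (%d genes) x %d samples\n",
              length(x$phenotype_id), length(unique(x$gene_id)),
              length(x$sample_ids)))
  invisible(x)
}

#' Export a phenotype table as grouped-phenotype BED
#'
#' Writes a tab-delimited BED with columns `#chr`, `start` (gene TSS), `end`
#' (TSS + 1), `phenotype_id`, then one column per sample, sorted by
#' chromosome then start then phenotype ID — the layout grouped cis-QTL
#' mappers consume. A companion two-column group file maps phenotype_id to
#' gene_id.
#'
#' @param table a [phenotype_table()].
#' @param regions named list of [gene_region()] providing chrom/TSS per gene.
#' @param path output BED path.
#' @param group_path companion group-file path (default `<path>.groups`).
#' @return `path`, invisibly.
#' @export
export_bed <- function(table, regions, path,
                       group_path = paste0(path, ".groups")) {
  missing <- setdiff(unique(table$gene_id), names(regions))
  if (length(missing))
    stop("no region metadata (chrom/TSS) for gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  n <- length(table$phenotype_id)
  chrom <- character(n); tss <- numeric(n)
  for (i in seq_len(n)) {
    rg <- regions[[table$gene_id[i]]]
    chrom[i] <- rg$chrom
    tss[i] <- tss_of(rg)
  }
  ord <- order(chrom, tss, table$phenotype_id)
  header <- paste(c("#chr", "start", "end", "phenotype_id", table$sample_ids),
                  collapse = "\t")
  body <- if (n) vapply(ord, function(i) {
    paste(c(chrom[i], format(tss[i], scientific = FALSE),
            format(tss[i] + 1, scientific = FALSE), table$phenotype_id[i],
            sprintf("%.15g", table$values[i, ])), collapse = "\t")
  }, "") else character(0)
  writeLines(c(header, body), path)
  writeLines(c("phenotype_id\tgroup_id",
               paste(table$phenotype_id[ord], table$gene_id[ord], sep = "\t")),
             group_path)
  invisible(path)
}

# --- model store ------------------------------------------------------------

#' Save a model store
#'
#' The store bundles bin schemes, per-gene PCA models and fitting parameters
#' into a single archive with an embedded format-version string. Reloading
#' reproduces projections bit-identically.
#'
#' @param store a model store as returned by [fit_ddp_models()] (or a list
#'   with `schemes` and `models`).
#' @param path output path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_models <- function(store, path) {
  store$format_version <- MODEL_STORE_VERSION
  saveRDS(store, path, version = 3)
  invisible(path)
}

#' Load a model store written by [save_models()]
#'
#' @param path input path.
#' @return the model store.
#' @export
load_models <- function(path) {
  store <- readRDS(path)
  if (!identical(store$format_version, MODEL_STORE_VERSION))
    stop("model store version mismatch: file has '",
         store$format_version %||% "<none>", "', this package reads '",
         MODEL_STORE_VERSION, "'")
  store
}
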