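# Two-pass removal of knowledge-driven phenotype (KDP) signal from
# normalized binned coverage, producing rDDP inputs.

# OLS with per-coefficient two-sided t-tests, via pivoted QR. Coefficients
# dropped at the rank boundary get p = 1 and are never retained.
ols_tests <- function(X, y) {
  n <- length(y)
  qrx <- qr(X)
  r <- qrx$rank
  coef <- qr.coef(qrx, y)            # NA for rank-dropped columns
  fitted <- qr.fitted(qrx, y)
  resid <- y - fitted
  df <- n - r
  p <- rep(1, ncol(X))
  se <- rep(NA_real_, ncol(X))
  if (df > 0 && r > 0) {
    sigma2 <- sum(resid^2) / df
    R <- qr.R(qrx)[seq_len(r), seq_len(r), drop = FALSE]
    cov_unscaled <- chol2inv(R)
    used <- qrx$pivot[seq_len(r)]
    se[used] <- sqrt(pmax(diag(cov_unscaled), 0) * sigma2)
    tstat <- coef[used] / se[used]   # exact fits: se = 0 -> t = +/-Inf -> p = 0
    pv <- 2 * stats::pt(-abs(tstat), df)
    pv[is.nan(pv)] <- 1              # 0/0: no evidence either way
    p[used] <- pv
  }
  list(coef = coef, se = se, p = p, fitted = fitted, resid = resid, df = df)
}

#' Two-pass residualization of one bin feature
#'
#' Pass 1 fits ordinary least squares of the bin's normalized coverage on an
#' intercept plus all of the gene's KDPs; KDPs whose two-sided coefficient
#' t-test p-value is below `alpha` are retained. Pass 2 refits on the
#' intercept plus the retained KDPs only, and the pass-2 fitted values are
#' subtracted from the response. With nothing retained the residual is the
#' centered response.
#'
#' @param y numeric response (one bin across samples).
#' @param K samples x KDPs numeric matrix (may have 0 columns); column names
#'   identify the KDPs.
#' @param alpha retention threshold on pass-1 p-values (default 0.01).
#' @return list with `residual`, `retained` (KDP column names), and
#'   `p_values` (pass-1, named by KDP).
#' @export
two_pass_residualize <- function(y, K, alpha = 0.01) {
  n <- length(y)
  K <- as.matrix(K)
  if (nrow(K) && nrow(K) != n) stop("KDP matrix and response length differ")
  if (n < 3) stop("residualization requires >= 3 samples")
  if (any(!is.finite(y)) || (ncol(K) && any(!is.finite(K))))
    stop("non-finite values in residualization input")
  if (ncol(K) == 0)
    return(list(residual = y - mean(y), retained = character(0),
                p_values = stats::setNames(numeric(0), character(0))))
  kdp_ids <- colnames(K) %||% paste0("K", seq_len(ncol(K)))

  fit1 <- ols_tests(cbind(`(Intercept)` = 1, K), y)
  p1 <- stats::setNames(fit1$p[-1], kdp_ids)
  retained <- kdp_ids[p1 < alpha]

  if (!length(retained)) {
    residual <- y - mean(y)
  } else {
    fit2 <- ols_tests(cbind(`(Intercept)` = 1,
                            K[, match(retained, kdp_ids), drop = FALSE]), y)
    residual <- fit2$resid
  }
  list(residual = residual, retained = retained, p_values = p1)
}

#' Residualize all of a gene's bin features against its KDPs
#'
#' Applies [two_pass_residualize()] independently to every bin of the gene's
#' normalized (stage `log2`) binned coverage. Samples with missing KDP values
#' are mean-imputed when they make up at most `max_missing` of the samples;
#' above that the gene is refused.
#'
#' @param X a [binned_coverage()] at stage `log2`.
#' @param K samples x KDPs matrix for the gene (rownames = sample IDs,
#'   colnames = KDP phenotype IDs), or NULL/0-column for no KDPs.
#' @param alpha retention threshold (default 0.01).
#' @param max_missing maximum tolerated fraction of samples with a missing
#'   KDP value (default 0.2).
#' @return list with `residual` (a `BinnedCoverage` at stage `residual`) and
#'   `report` (per bin: retained KDP IDs, pass-1 p-values, residual variance
#'   fraction).
#' @export
residualize_gene <- function(X, K, alpha = 0.01, max_missing = 0.2) {
  check_stage(X, "log2")
  if (is.null(K)) K <- matrix(0, length(X$sample_ids), 0,
                              dimnames = list(X$sample_ids, NULL))
  K <- as.matrix(K)
  if (ncol(K)) {
    if (is.null(rownames(K))) stop("KDP matrix must have sample rownames")
    if (!setequal(rownames(K), X$sample_ids))
      stop("KDP samples do not match coverage samples for gene ", X$gene_id)
    K <- K[X$sample_ids, , drop = FALSE]
    miss <- apply(K, 1, anyNA)
    if (mean(miss) > max_missing)
      stop(sprintf("gene %s: %.0f%% of samples have missing KDP values (> %.0f%% allowed)",
                   X$gene_id, 100 * mean(miss), 100 * max_missing))
    if (any(miss))
      for (j in seq_len(ncol(K))) {
        nas <- is.na(K[, j])
        if (any(nas)) K[nas, j] <- mean(K[!nas, j])
      }
  }
  res <- X$values
  report <- vector("list", length(X$bin_ids))
  names(report) <- X$bin_ids
  for (b in seq_along(X$bin_ids)) {
    y <- X$values[, b]
    rb <- two_pass_residualize(y, K, alpha)
    res[, b] <- rb$residual
    v0 <- stats::var(y)
    report[[b]] <- list(retained = rb$retained, p_values = rb$p_values,
                        residual_variance_fraction =
                          if (v0 > 0) stats::var(rb$residual) / v0 else NA_real_)
  }
  list(residual = binned_coverage(X$gene_id, X$bin_ids, X$sample_ids, res,
                                  stage = "residual"),
       report = report)
}

# --- KDP tables -------------------------------------------------------------

#' Read a KDP table
#'
#' Tab-delimited input with columns `gene_id`, `phenotype_id`, `modality`,
#' then one column per sample.
#'
#' @param path input path.
#' @return object of class `KDPTable`: list with `genes` (per gene a
#'   samples x KDPs matrix with phenotype-ID colnames), `modality` (named by
#'   phenotype_id), `sample_ids`.
#' @export
read_kdp_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("gene_id", "phenotype_id", "modality")
  if (!all(need %in% names(dt)[1:3]))
    stop("KDP table must start with columns gene_id, phenotype_id, modality")
  sample_ids <- names(dt)[-(1:3)]
  vals <- as.matrix(dt[, -(1:3), drop = FALSE])
  storage.mode(vals) <- "double"
  kdp_table(dt$gene_id, dt$phenotype_id, dt$modality, vals, sample_ids)
}

#' Construct a KDP table from parallel vectors
#'
#' @param gene_id,phenotype_id,modality per-KDP metadata vectors.
#' @param values KDPs x samples matrix.
#' @param sample_ids sample identifiers (columns of `values`).
#' @return a `KDPTable`.
#' @export
kdp_table <- function(gene_id, phenotype_id, modality, values, sample_ids) {
  stopifnot(length(gene_id) == nrow(values),
            length(phenotype_id) == nrow(values),
            length(modality) == nrow(values),
            length(sample_ids) == ncol(values))
  if (anyDuplicated(phenotype_id)) stop("duplicate KDP phenotype IDs")
  genes <- list()
  for (g in unique(gene_id)) {
    idx <- which(gene_id == g)
    m <- t(values[idx, , drop = FALSE])
    dimnames(m) <- list(sample_ids, phenotype_id[idx])
    genes[[g]] <- m
  }
  structure(list(genes = genes,
                 modality = stats::setNames(modality, phenotype_id),
                 sample_ids = sample_ids),
            class = "KDPTable")
}

#' Write a KDP table in the tab-delimited layout read by [read_kdp_table()]
#' @param kdps a `KDPTable`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_kdp_table <- function(kdps, path) {
  rows <- list()
  for (g in names(kdps$genes)) {
    m <- kdps$genes[[g]]
    for (j in seq_len(ncol(m))) {
      pid <- colnames(m)[j]
      rows[[length(rows) + 1]] <- c(g, pid, unname(kdps$modality[pid]),
                                    sprintf("%.15g", m[, j]))
    }
  }
  header <- c("gene_id", "phenotype_id", "modality", kdps$sample_ids)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  for (r in rows) writeLines(paste(r, collapse = "\t"), con)
  invisible(path)
}

#' Withhold one KDP modality
#'
#' Returns the table without the named modality's phenotypes, enabling
#' held-out-modality experiments (residualize on the remaining modalities and
#' check that the withheld signal reappears among the rDDPs).
#'
#' @param kdps a `KDPTable`.
#' @param modality modality label to withhold.
#' @return a `KDPTable` without that modality.
#' @export
holdout_modality <- function(kdps, modality) {
  labels <- unique(unname(kdps$modality))
  if (!modality %in% labels)
    stop("unknown modality '", modality, "'; available: ",
         paste(labels, collapse = ", "))
  keep_ids <- names(kdps$modality)[kdps$modality != modality]
  genes <- lapply(kdps$genes, function(m)
    m[, intersect(colnames(m), keep_ids), drop = FALSE])
  structure(list(genes = genes, modality = kdps$modality[keep_ids],
                 sample_ids = kdps$sample_ids),
            class = "KDPTable")
}
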