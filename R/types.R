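#' @importFrom stats median prcomp pt rnorm rpois runif sd var setNames
#' @importFrom utils head tail
NULL

# Internal coordinate convention: 0-based half-open intervals everywhere,
# matching bigWig; GTF's 1-based inclusive coordinates are converted on parse.

#' Gene phenotyping region
#'
#' A gene's span extended by a flank on each side, together with the exon
#' intervals of all *other* genes that intersect the extended region
#' (`foreign_exons`). Coverage bins overlapping those intervals are removed
#' during binning to limit contamination by neighbouring transcripts.
#'
#' All coordinates are 0-based half-open.
#'
#' @param gene_id,chrom,strand,biotype gene metadata; strand is `"+"` or `"-"`.
#' @param gene_start,gene_end gene span.
#' @param region_start,region_end flanked span (clipped to chromosome bounds).
#' @param foreign_exons two-column matrix (start, end) of disjoint, sorted
#'   intervals belonging to other genes.
#' @return An object of class `GeneRegion`.
#' @export
gene_region <- function(gene_id, chrom, strand, gene_start, gene_end,
                        region_start, region_end,
                        biotype = "protein_coding",
                        foreign_exons = matrix(numeric(0), ncol = 2L)) {
  stopifnot(region_start <= gene_start, gene_start < gene_end,
            gene_end <= region_end, strand %in% c("+", "-"))
  if (!is.matrix(foreign_exons)) foreign_exons <- matrix(foreign_exons, ncol = 2L)
  colnames(foreign_exons) <- c("start", "end")
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         gene_start = as.numeric(gene_start), gene_end = as.numeric(gene_end),
         region_start = as.numeric(region_start), region_end = as.numeric(region_end),
         biotype = biotype, foreign_exons = foreign_exons),
    class = "GeneRegion")
}

#' @export
print.GeneRegion <- function(x, ...) {
  cat(sprintf("GeneRegion %s (%s) %s:%s-%s [region %s-%s], %d foreign exon interval(s)\n",
              x$gene_id, x$biotype, x$chrom, x$gene_start, x$gene_end,
              x$region_start, x$region_end, nrow(x$foreign_exons)))
  invisible(x)
}

region_span <- function(region) region$region_end - region$region_start

#' Per-base coverage for one gene across samples
#'
#' @param gene_id gene identifier.
#' @param sample_ids character vector of sample identifiers.
#' @param values samples x bases matrix of non-negative coverage depth; the
#'   number of columns must equal the region span.
#' @return An object of class `CoverageStack`.
#' @export
coverage_stack <- function(gene_id, sample_ids, values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids))
  if (any(values < 0)) stop("coverage values must be non-negative")
  rownames(values) <- sample_ids
  structure(list(gene_id = gene_id, sample_ids = sample_ids, values = values),
            class = "CoverageStack")
}

#' Binned coverage matrix for one gene
#'
#' Samples x bins matrix at a named processing stage. Stages advance only as
#' `raw_mean -> scaled -> log2 -> residual`.
#'
#' @param gene_id gene identifier.
#' @param bin_ids ordered bin identifiers (`<gene>:<index>`).
#' @param sample_ids sample identifiers.
#' @param values samples x bins numeric matrix.
#' @param stage one of `"raw_mean"`, `"scaled"`, `"log2"`, `"residual"`.
#' @return An object of class `BinnedCoverage`.
#' @export
binned_coverage <- function(gene_id, bin_ids, sample_ids, values,
                            stage = c("raw_mean", "scaled", "log2", "residual")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(sample_ids), ncol(values) == length(bin_ids))
  if (stage %in% c("raw_mean", "scaled") && any(values < 0))
    stop("values must be non-negative at stage ", stage)
  dimnames(values) <- list(sample_ids, bin_ids)
  structure(list(gene_id = gene_id, bin_ids = bin_ids, sample_ids = sample_ids,
                 values = values, stage = stage),
            class = "BinnedCoverage")
}

#' @export
print.BinnedCoverage <- function(x, ...) {
  cat(sprintf("BinnedCoverage %s: %d samples x %d bins, stage=%s\n",
              x$gene_id, length(x$sample_ids), length(x$bin_ids), x$stage))
  invisible(x)
}

.stage_order <- c(raw_mean = 1L, scaled = 2L, log2 = 3L, residual = 4L)

check_stage <- function(x, expected) {
  if (!x$stage %in% expected)
    stop(sprintf("gene %s: expected stage %s, got %s",
                 x$gene_id, paste(expected, collapse = "/"), x$stage))
  invisible(x)
}

#' Bin scheme for one gene
#'
#' Ordered genomic bins produced by segmentation. Kept and removed bins
#' together tile the phenotyping region exactly.
#'
#' @param gene_id gene identifier.
#' @param chrom,strand location metadata for BED export.
#' @param bins two-column matrix of kept half-open intervals.
#' @param removed_bins intervals excluded for foreign-exon overlap.
#' @param threshold calibrated cumulative-variance cutoff (NA for uniform).
#' @param provenance list: method (`adaptive`/`uniform`), pseudocount,
#'   max_bin_size, seed, and any other parameters worth recording.
#' @return An object of class `BinScheme`.
#' @export
bin_scheme <- function(gene_id, chrom, strand, bins,
                       removed_bins = matrix(numeric(0), ncol = 2L),
                       threshold = NA_real_, provenance = list(method = "adaptive")) {
  bins <- matrix(as.numeric(bins), ncol = 2L)
  removed_bins <- matrix(as.numeric(removed_bins), ncol = 2L)
  colnames(bins) <- colnames(removed_bins) <- c("start", "end")
  if (nrow(bins) && any(bins[, 2] <= bins[, 1])) stop("empty bin in scheme")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 bins = bins, removed_bins = removed_bins,
                 threshold = threshold, provenance = provenance),
            class = "BinScheme")
}

#' @export
print.BinScheme <- function(x, ...) {
  cat(sprintf("BinScheme %s (%s): %d kept + %d removed bins, threshold=%s\n",
              x$gene_id, x$provenance$method %||% "adaptive",
              nrow(x$bins), nrow(x$removed_bins), format(x$threshold)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bin_ids_of <- function(scheme) {
  if (!nrow(scheme$bins)) return(character(0))
  # indices refer to position in the full (kept + removed) genomic partition
  all_bins <- rbind(scheme$bins, scheme$removed_bins)
  ord <- order(all_bins[, 1])
  idx_of_start <- setNames(seq_along(ord), as.character(all_bins[ord, 1]))
  paste0(scheme$gene_id, ":", idx_of_start[as.character(scheme$bins[, 1])])
}
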