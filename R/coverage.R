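# Base-level coverage access: bigWig-backed and in-memory sources.

resolve_chrom <- function(chrom, available, alias_chr_prefix = TRUE) {
  if (chrom %in% available) return(chrom)
  if (alias_chr_prefix) {
    alt <- if (startsWith(chrom, "chr")) sub("^chr", "", chrom) else paste0("chr", chrom)
    if (alt %in% available) return(alt)
  }
  stop(sprintf("chromosome '%s' not present in coverage file; available: %s",
               chrom, paste(utils::head(available, 10), collapse = ", ")))
}

#' Read per-base coverage for a gene region from a bigWig file
#'
#' Bases without data are returned as 0. Chromosome names may be aliased
#' between "chr"-prefixed and bare forms.
#'
#' @param bigwig_path path to an indexed bigWig file.
#' @param region a [gene_region()].
#' @param alias_chr_prefix try adding/stripping a "chr" prefix when the
#'   region's chromosome is absent from the file (default TRUE).
#' @return numeric vector of length `region_end - region_start`.
#' @export
read_coverage <- function(bigwig_path, region, alias_chr_prefix = TRUE) {
  bwf <- rtracklayer::BigWigFile(bigwig_path)
  avail <- GenomeInfoDb::seqnames(rtracklayer::seqinfo(bwf))
  chrom <- resolve_chrom(region$chrom, avail, alias_chr_prefix)
  gr <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(region$region_start + 1, region$region_end))
  v <- rtracklayer::import.bw(bwf, which = gr, as = "NumericList")[[1]]
  v <- as.numeric(v)
  v[is.na(v)] <- 0
  v
}

#' Assemble a coverage stack for one gene from per-sample bigWig files
#'
#' @param bigwig_paths named character vector (names = sample IDs) of bigWig
#'   paths.
#' @param region a [gene_region()].
#' @param alias_chr_prefix see [read_coverage()].
#' @return a [coverage_stack()] with one row per sample.
#' @export
read_coverage_stack <- function(bigwig_paths, region, alias_chr_prefix = TRUE) {
  if (is.null(names(bigwig_paths)) || any(names(bigwig_paths) == ""))
    stop("bigwig_paths must be named by sample ID")
  vals <- t(vapply(bigwig_paths, read_coverage, numeric(region_span(region)),
                   region = region, alias_chr_prefix = alias_chr_prefix))
  coverage_stack(region$gene_id, names(bigwig_paths), vals)
}

# --- coverage sources -------------------------------------------------------
# A coverage source abstracts "where coverage comes from" so calibration and
# model fitting can stream one gene at a time (GTEx-scale stacks do not fit
# in memory). It is a list with $sample_ids and $fetch(region, sample_ids).

#' Coverage source backed by per-sample bigWig files
#'
#' @param bigwig_paths named character vector (names = sample IDs).
#' @param alias_chr_prefix see [read_coverage()].
#' @return a `coverage_source` object usable by [calibrate_threshold()] and
#'   [fit_ddp_models()].
#' @export
bigwig_coverage_source <- function(bigwig_paths, alias_chr_prefix = TRUE) {
  force(bigwig_paths); force(alias_chr_prefix)
  structure(list(
    sample_ids = names(bigwig_paths),
    fetch = function(region, sample_ids = names(bigwig_paths)) {
      read_coverage_stack(bigwig_paths[sample_ids], region, alias_chr_prefix)
    }), class = "coverage_source")
}

#' Coverage source backed by in-memory stacks
#'
#' Mainly for tests and small simulations: wraps a named list of
#' [coverage_stack()] objects (one per gene).
#'
#' @param stacks named list of `CoverageStack` objects, names = gene IDs.
#' @return a `coverage_source` object.
#' @export
memory_coverage_source <- function(stacks) {
  sample_ids <- stacks[[1]]$sample_ids
  structure(list(
    sample_ids = sample_ids,
    fetch = function(region, sample_ids_use = sample_ids) {
      st <- stacks[[region$gene_id]]
      if (is.null(st)) stop("no coverage for gene ", region$gene_id)
      coverage_stack(st$gene_id, sample_ids_use,
                     st$values[sample_ids_use, , drop = FALSE])
    }), class = "coverage_source")
}

#' Mean coverage per bin per sample
#'
#' Summarizes a per-base coverage stack into the scheme's kept bins by
#' arithmetic mean, yielding stage `raw_mean` binned coverage.
#'
#' @param stack a [coverage_stack()].
#' @param scheme a [bin_scheme()]; bins must lie within the stack's region.
#' @param region the [gene_region()] the stack was read over.
#' @return a [binned_coverage()] at stage `raw_mean`.
#' @export
mean_coverage_per_bin <- function(stack, scheme, region) {
  stopifnot(stack$gene_id == scheme$gene_id)
  n_bins <- nrow(scheme$bins)
  vals <- matrix(0, nrow = length(stack$sample_ids), ncol = n_bins)
  off <- region$region_start
  L <- ncol(stack$values)
  for (b in seq_len(n_bins)) {
    s <- scheme$bins[b, 1] - off + 1
    e <- scheme$bins[b, 2] - off
    if (s < 1 || e > L) stop("bin outside region for gene ", stack$gene_id)
    vals[, b] <- if (s == e) stack$values[, s] else
      rowMeans(stack$values[, s:e, drop = FALSE])
  }
  binned_coverage(stack$gene_id, bin_ids_of(scheme), stack$sample_ids,
                  vals, stage = "raw_mean")
}
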