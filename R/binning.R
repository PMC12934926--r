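# Variance-adaptive gene segmentation.
#
# The segmentation signal is the per-base variance, across samples, of the
# first difference of log2(coverage + pseudocount). Greedy left-to-right
# accumulation of that signal up to a fixed threshold yields bins that are
# small where coverage varies across the population and large where it does
# not. The threshold is global, calibrated once per training set to hit a
# target mean bin count per gene.

#' Variance profile of a coverage stack
#'
#' Entry i is the variance across samples (denominator n-1) of the per-sample
#' difference of log2(coverage + pseudocount) between base i+1 and base i.
#'
#' @param stack a [coverage_stack()] with at least 2 samples.
#' @param pseudocount positive pseudocount added before log2 (default 8).
#' @return list with `gene_id` and `values` (length span - 1, all >= 0).
#' @export
variance_profile <- function(stack, pseudocount = 8) {
  stopifnot(pseudocount > 0)
  n <- nrow(stack$values)
  if (n < 2) stop("variance profile requires >= 2 samples (gene ",
                  stack$gene_id, ")")
  lg <- log2(stack$values + pseudocount)
  L <- ncol(lg)
  D <- lg[, 2:L, drop = FALSE] - lg[, 1:(L - 1), drop = FALSE]
  mu <- colMeans(D)
  v <- (colSums(D * D) - n * mu * mu) / (n - 1)
  v[v < 0] <- 0  # guard against tiny negative round-off
  list(gene_id = stack$gene_id, values = v)
}

#' Segment a region by cumulative variance
#'
#' Greedy scan: bases join the current bin until the running sum of variance
#' profile entries reaches `threshold`; the base whose entry triggers the
#' threshold closes the bin and the accumulator resets to zero. The final
#' partial bin is kept. Implemented by binary search on the cumulative profile
#' (entries are variances, hence non-negative), which reproduces the literal
#' greedy loop exactly.
#'
#' @param profile_values numeric vector of length span - 1 (from
#'   [variance_profile()]).
#' @param threshold positive cutoff.
#' @return two-column matrix of region-relative half-open bins `[start, end)`
#'   (0-based) tiling `[0, span)`.
#' @export
segment_region <- function(profile_values, threshold) {
  stopifnot(threshold > 0)
  L <- length(profile_values) + 1L
  cs <- cumsum(profile_values)
  starts <- numeric(0); ends <- numeric(0)
  pos <- 0L      # bases consumed (0-based start of current bin)
  base <- 0      # cumulative mass consumed at last boundary
  n_p <- L - 1L
  while (pos < L) {
    target <- base + threshold
    # smallest i with cs[i] >= target (left-open: counts cs[i] < target)
    i <- findInterval(target, cs, left.open = TRUE) + 1L
    if (i > n_p) { starts <- c(starts, pos); ends <- c(ends, L); break }
    end <- i + 1L                          # trigger base included in bin
    starts <- c(starts, pos); ends <- c(ends, end)
    pos <- end; base <- cs[i]
  }
  cbind(start = starts, end = ends)
}

#' Subdivide oversized bins
#'
#' Bins wider than `max_bin_size` are split into `ceiling(w / max_bin_size)`
#' contiguous near-equal parts (widths differ by at most one base, longer
#' parts first).
#'
#' @param bins two-column matrix of half-open intervals.
#' @param max_bin_size maximum allowed width (default 1024).
#' @return two-column matrix with every width in `[1, max_bin_size]`.
#' @export
subdivide_bins <- function(bins, max_bin_size = 1024L) {
  stopifnot(max_bin_size >= 1)
  out <- vector("list", nrow(bins))
  for (b in seq_len(nrow(bins))) {
    s <- bins[b, 1]; e <- bins[b, 2]; w <- e - s
    if (w <= max_bin_size) { out[[b]] <- c(s, e); next }
    k <- ceiling(w / max_bin_size)
    base_w <- w %/% k
    rem <- w - k * base_w
    widths <- c(rep(base_w + 1, rem), rep(base_w, k - rem))
    edges <- s + c(0, cumsum(widths))
    out[[b]] <- cbind(edges[-(k + 1)], edges[-1])
  }
  m <- do.call(rbind, lapply(out, function(x) matrix(x, ncol = 2L)))
  colnames(m) <- c("start", "end")
  m
}

#' Remove bins overlapping other genes' exons
#'
#' A bin is removed iff it shares at least one base with any interval in
#' `region$foreign_exons`.
#'
#' @param bins two-column matrix of half-open genomic intervals.
#' @param region a [gene_region()].
#' @return list with `kept` and `removed` bin matrices.
#' @export
exclude_foreign_exonic <- function(bins, region) {
  fe <- region$foreign_exons
  if (!nrow(fe) || !nrow(bins))
    return(list(kept = bins, removed = bins[0, , drop = FALSE]))
  bi <- IRanges::IRanges(start = bins[, 1] + 1, end = bins[, 2])
  fi <- IRanges::IRanges(start = fe[, 1] + 1, end = fe[, 2])
  hit <- IRanges::overlapsAny(bi, fi)
  list(kept = bins[!hit, , drop = FALSE], removed = bins[hit, , drop = FALSE])
}

#' Build the adaptive bin scheme for one gene
#'
#' Segments the variance profile at `threshold`, subdivides oversized bins,
#' applies foreign-exon exclusion, and shifts region-relative coordinates to
#' genomic coordinates.
#'
#' @param region a [gene_region()].
#' @param profile output of [variance_profile()] for this gene.
#' @param threshold calibrated cumulative-variance cutoff.
#' @param max_bin_size maximum bin width after subdivision (default 1024).
#' @param pseudocount recorded in provenance.
#' @param seed recorded in provenance.
#' @return a [bin_scheme()].
#' @export
adaptive_bin_scheme <- function(region, profile, threshold,
                                max_bin_size = 1024L, pseudocount = 8,
                                seed = NA_integer_) {
  bins <- segment_region(profile$values, threshold)
  bins <- subdivide_bins(bins, max_bin_size)
  bins <- bins + region$region_start
  split <- exclude_foreign_exonic(bins, region)
  bin_scheme(region$gene_id, region$chrom, region$strand,
             bins = split$kept, removed_bins = split$removed,
             threshold = threshold,
             provenance = list(method = "adaptive", pseudocount = pseudocount,
                               max_bin_size = max_bin_size, seed = seed))
}

#' Uniform fixed-width bin scheme (benchmarking alternative)
#'
#' Contiguous bins of `bin_width` over the whole phenotyping region, the last
#' bin possibly shorter; foreign-exon exclusion is applied the same way as in
#' the adaptive path.
#'
#' @param region a [gene_region()].
#' @param bin_width width in bases (>= 1).
#' @return a [bin_scheme()] with provenance method `uniform`.
#' @export
uniform_bins <- function(region, bin_width) {
  stopifnot(bin_width >= 1)
  span <- region_span(region)
  edges <- unique(c(seq(0, span, by = bin_width), span))
  bins <- cbind(start = edges[-length(edges)], end = edges[-1]) + region$region_start
  split <- exclude_foreign_exonic(bins, region)
  bin_scheme(region$gene_id, region$chrom, region$strand,
             bins = split$kept, removed_bins = split$removed,
             threshold = NA_real_,
             provenance = list(method = "uniform", bin_width = bin_width))
}

#' Calibrate the global segmentation threshold
#'
#' Draws up to `n_calibration_genes` genes and `n_binning_samples` samples
#' (seeded), computes their variance profiles once, and bisects on
#' log10(threshold) until the mean pre-subdivision, pre-exclusion bin count
#' per calibration gene is within `tol` of `target_mean_bins` (or `max_iter`
#' iterations elapse). Bin count is non-increasing in the threshold, so
#' bisection converges.
#'
#' @param regions list of [gene_region()] objects.
#' @param source a coverage source ([bigwig_coverage_source()] or similar).
#' @param target_mean_bins desired mean bins per gene (default 256).
#' @param n_calibration_genes genes to sample (default 128).
#' @param n_binning_samples samples to draw coverage for (default 256).
#' @param pseudocount pseudocount for the variance profile (default 8).
#' @param seed RNG seed controlling both gene and sample draws.
#' @param tol relative tolerance on the mean bin count (default 0.02).
#' @param max_iter bisection iteration cap (default 40).
#' @return the threshold (numeric scalar) with attributes `mean_bins`,
#'   `calibration_genes`, `calibration_samples`, and `profiles` (the cached
#'   calibration profiles, reusable for scheme construction).
#' @export
calibrate_threshold <- function(regions, source, target_mean_bins = 256L,
                                n_calibration_genes = 128L,
                                n_binning_samples = 256L,
                                pseudocount = 8, seed = 1L,
                                tol = 0.02, max_iter = 40L) {
  stopifnot(length(regions) >= 1, length(source$sample_ids) >= 2)
  set.seed(seed %% .Machine$integer.max)
  gene_ids <- names(regions) %||% vapply(regions, `[[`, "", "gene_id")
  cal_genes <- if (length(regions) > n_calibration_genes)
    sort(sample(seq_along(regions), n_calibration_genes)) else seq_along(regions)
  samp <- source$sample_ids
  cal_samples <- if (length(samp) > n_binning_samples)
    sort(sample(seq_along(samp), n_binning_samples)) else seq_along(samp)
  cal_samples <- samp[cal_samples]

  profiles <- lapply(regions[cal_genes], function(rg) {
    st <- source$fetch(rg, cal_samples)
    variance_profile(st, pseudocount)
  })
  masses <- vapply(profiles, function(p) sum(p$values), 0)
  if (all(masses == 0))
    stop("all calibration genes have all-zero variance profiles; ",
         "check the input coverage")

  mean_bins_at <- function(th)
    mean(vapply(profiles, function(p) nrow(segment_region(p$values, th)), 0))

  lo <- log10(1e-8); hi <- log10(max(masses))
  th <- NA_real_; mb <- NA_real_
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    th <- 10^mid
    mb <- mean_bins_at(th)
    if (abs(mb / target_mean_bins - 1) <= tol) break
    if (mb > target_mean_bins) lo <- mid else hi <- mid
  }
  structure(th, mean_bins = mb,
            calibration_genes = gene_ids[cal_genes],
            calibration_samples = cal_samples,
            profiles = profiles)
}

# --- BED6+ scheme serialization --------------------------------------------

#' Write bin schemes as BED6+
#'
#' One row per bin (kept and removed): chrom, start, end,
#' name=`gene_id:bin_index`, score=0, strand, status (kept/removed). Scheme
#' provenance (threshold, pseudocount, max bin size, method, seed) is stored
#' in per-gene `#scheme` header comment lines so that
#' `read_scheme(write_scheme(x)) == x`.
#'
#' @param schemes named list of [bin_scheme()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(schemes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sc in schemes) {
    pv <- sc$provenance
    writeLines(sprintf(
      "#scheme gene_id=%s method=%s threshold=%s pseudocount=%s max_bin_size=%s bin_width=%s seed=%s",
      sc$gene_id, pv$method %||% "adaptive", format_num(sc$threshold),
      format_num(pv$pseudocount), format_num(pv$max_bin_size),
      format_num(pv$bin_width), format_num(pv$seed)), con)
    all_bins <- rbind(cbind(sc$bins, status = rep(1, nrow(sc$bins))),
                      cbind(sc$removed_bins, status = rep(0, nrow(sc$removed_bins))))
    if (!nrow(all_bins)) next
    ord <- order(all_bins[, 1])
    all_bins <- all_bins[ord, , drop = FALSE]
    writeLines(sprintf("%s\t%d\t%d\t%s:%d\t0\t%s\t%s",
                       sc$chrom, as.integer(all_bins[, 1]),
                       as.integer(all_bins[, 2]), sc$gene_id,
                       seq_len(nrow(all_bins)), sc$strand,
                       ifelse(all_bins[, 3] == 1, "kept", "removed")), con)
  }
  invisible(path)
}

format_num <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "NA" else sprintf("%.17g", as.numeric(x))
}

parse_num <- function(x) if (x == "NA") NA_real_ else as.numeric(x)

#' Read bin schemes from BED6+ written by [write_scheme()]
#'
#' @param path input path.
#' @return named list of [bin_scheme()] objects.
#' @export
read_scheme <- function(path) {
  lines <- readLines(path)
  schemes <- list()
  cur <- NULL
  flush_cur <- function(cur) {
    if (is.null(cur)) return(NULL)
    kept <- do.call(rbind, cur$kept) %||% matrix(numeric(0), ncol = 2L)
    removed <- do.call(rbind, cur$removed) %||% matrix(numeric(0), ncol = 2L)
    pv <- list(method = cur$meta[["method"]])
    for (k in c("pseudocount", "max_bin_size", "bin_width", "seed")) {
      v <- parse_num(cur$meta[[k]])
      if (!is.na(v)) pv[[k]] <- v
    }
    if (!is.null(pv$max_bin_size)) pv$max_bin_size <- as.integer(pv$max_bin_size)
    if (!is.null(pv$seed)) pv$seed <- as.integer(pv$seed)
    if (is.null(pv$seed) && cur$meta[["method"]] == "adaptive") pv$seed <- NA_integer_
    bin_scheme(cur$meta[["gene_id"]], cur$chrom, cur$strand, kept, removed,
               threshold = parse_num(cur$meta[["threshold"]]), provenance = pv)
  }
  for (ln in lines) {
    if (startsWith(ln, "#scheme ")) {
      sc <- flush_cur(cur)
      if (!is.null(sc)) schemes[[sc$gene_id]] <- sc
      kv <- strsplit(strsplit(sub("^#scheme ", "", ln), " ")[[1]], "=")
      meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
      cur <- list(meta = meta, kept = list(), removed = list(),
                  chrom = NA_character_, strand = NA_character_)
    } else if (nzchar(ln)) {
      if (is.null(cur)) stop("malformed scheme BED: data before #scheme header")
      f <- strsplit(ln, "\t")[[1]]
      if (length(f) != 7) stop("malformed scheme BED row: ", ln)
      cur$chrom <- f[1]; cur$strand <- f[6]
      iv <- c(as.numeric(f[2]), as.numeric(f[3]))
      if (f[7] == "kept") cur$kept[[length(cur$kept) + 1]] <- iv
      else if (f[7] == "removed") cur$removed[[length(cur$removed) + 1]] <- iv
      else stop("malformed scheme BED status: ", f[7])
    }
  }
  sc <- flush_cur(cur)
  if (!is.null(sc)) schemes[[sc$gene_id]] <- sc
  schemes
}
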