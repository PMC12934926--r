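# Shared fixture builders. Everything is generated in code; no binary files.

# minimal GTF text for hand-placed genes
# genes: list of list(id, chrom, start1, end1 (1-based inclusive), strand,
#                     biotype, exons = matrix of 1-based inclusive rows)
toy_gtf <- function(genes, path = tempfile(fileext = ".gtf"),
                    biotype_key = "gene_type") {
  lines <- unlist(lapply(genes, function(g) {
    attr_g <- sprintf('gene_id "%s"; %s "%s";', g$id, biotype_key, g$biotype)
    out <- sprintf("%s\ttoy\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   g$chrom, g$start1, g$end1, g$strand, attr_g)
    if (!is.null(g$exons)) {
      tid <- paste0(g$id, ".t1")
      out <- c(out, sprintf(
        "%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t%s transcript_id \"%s\";",
        g$chrom, g$exons[, 1], g$exons[, 2], g$strand, attr_g, tid))
    }
    out
  }))
  writeLines(lines, path)
  path
}

toy_region <- function(gene_id = "g1", span = 100, region_start = 0,
                       strand = "+", foreign_exons = matrix(numeric(0), ncol = 2),
                       flank = 10) {
  gene_region(gene_id, "chr1", strand,
              gene_start = region_start + flank,
              gene_end = region_start + span - flank,
              region_start = region_start, region_end = region_start + span,
              foreign_exons = foreign_exons)
}

toy_stack <- function(values, gene_id = "g1") {
  coverage_stack(gene_id, sprintf("s%02d", seq_len(nrow(values))), values)
}

rand_binned <- function(n_samples, n_bins, gene_id = "g1", stage = "log2",
                        seed = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(n_samples * n_bins), n_samples, n_bins)
  binned_coverage(gene_id, paste0(gene_id, ":", seq_len(n_bins)),
                  sprintf("s%03d", seq_len(n_samples)), vals, stage = stage)
}

# literal greedy scan from the segmentation definition; the independent
# oracle for segment_region()
greedy_segment_oracle <- function(p, threshold) {
  L <- length(p) + 1
  starts <- c(); ends <- c()
  acc <- 0; start <- 0
  i <- 1
  while (i <= length(p)) {
    acc <- acc + p[i]
    if (acc >= threshold) {
      starts <- c(starts, start); ends <- c(ends, i + 1)
      start <- i + 1; acc <- 0
      if (start >= L) { start <- L; break }
    }
    i <- i + 1
  }
  if (start < L) { starts <- c(starts, start); ends <- c(ends, L) }
  cbind(start = starts, end = ends)
}

expect_partition <- function(scheme, region) {
  all_bins <- rbind(scheme$bins, scheme$removed_bins)
  all_bins <- all_bins[order(all_bins[, 1]), , drop = FALSE]
  expect_equal(unname(all_bins[1, 1]), region$region_start)
  expect_equal(unname(all_bins[nrow(all_bins), 2]), region$region_end)
  if (nrow(all_bins) > 1)
    expect_equal(all_bins[-1, 1], all_bins[-nrow(all_bins), 2],
                 ignore_attr = TRUE)
}
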