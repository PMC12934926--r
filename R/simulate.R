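# Synthetic population RNA-seq coverage with known latent structure.
#
# The generator emulates what the pipeline sees in real cohorts: per-gene
# isoform mixtures where a per-sample expression factor e_s scales total
# output, a usage factor u_s shifts isoform proportions through a softmax
# link, a per-sample depth multiplier d_s ~ LogNormal mimics library size,
# and observed per-base coverage is Poisson around its expectation.

#' Simulation configuration
#'
#' Defaults describe a small but realistic cohort: genes of 5-50 kb with
#' 4-12 exons and a cassette exon whose inclusion responds to the usage
#' factor; unit-variance latent factors; depth multipliers with ~25%
#' coefficient of variation; baseline exonic depth around 20x.
#'
#' @param n_genes number of genes (default 10).
#' @param n_samples number of samples (default 100).
#' @param span_range gene span range in bases (default c(5000, 50000)).
#' @param n_exons_range exons per gene (default c(4, 12)).
#' @param baseline_depth mean exonic coverage depth at e = 0, d = 1
#'   (default 20).
#' @param sigma_e sd of the per-sample expression factor (default 1).
#' @param sigma_u sd of the per-sample isoform-usage factor (default 1).
#' @param sigma_d sdlog of the per-sample depth multiplier (default 0.25).
#' @param usage_sensitivity per-gene softmax slope on the usage factor
#'   (default 1.5).
#' @param overlapping_pair if TRUE, the first two genes overlap so that
#'   foreign-exon exclusion is exercised (default TRUE when n_genes >= 2).
#' @param noise one of "poisson" (default) or "none" (coverage equals its
#'   expectation).
#' @param lnc_fraction fraction of genes labelled lncRNA (default 0.2).
#' @param seed RNG seed (default 1).
#' @return a `SimConfig` list.
#' @export
sim_config <- function(n_genes = 10L, n_samples = 100L,
                       span_range = c(5000L, 50000L),
                       n_exons_range = c(4L, 12L),
                       baseline_depth = 20,
                       sigma_e = 1, sigma_u = 1, sigma_d = 0.25,
                       usage_sensitivity = 1.5,
                       overlapping_pair = n_genes >= 2,
                       noise = c("poisson", "none"),
                       lnc_fraction = 0.2, seed = 1L) {
  noise <- match.arg(noise)
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 span_range = span_range, n_exons_range = n_exons_range,
                 baseline_depth = baseline_depth, sigma_e = sigma_e,
                 sigma_u = sigma_u, sigma_d = sigma_d,
                 usage_sensitivity = usage_sensitivity,
                 overlapping_pair = overlapping_pair, noise = noise,
                 lnc_fraction = lnc_fraction, seed = as.integer(seed)),
            class = "SimConfig")
}

# deterministic per-(seed, gene, purpose) sub-seeds, kept below 2^31
sub_seed <- function(seed, i, salt = 0L) {
  as.integer((as.numeric(seed) * 48271 + i * 9973 + salt * 131071) %% 2147483647)
}

#' Simulate a toy gene annotation
#'
#' Places genes on one chromosome with 10 kb gaps; each gene has two
#' isoforms: the full exon chain and a variant skipping one internal cassette
#' exon. With `overlapping_pair`, gene 2 starts inside gene 1's flank region
#' so both acquire foreign exons. Writes syntactically valid GTF (1-based
#' inclusive) with gene/transcript/exon records.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (per-gene definition: span, exon matrix 0-based
#'   half-open, isoform exon index sets, biotype, strand, baselines),
#'   `chrom`, `chrom_length`, and `gtf` (character vector of GTF lines).
#' @export
simulate_annotation <- function(config) {
  set.seed(sub_seed(config$seed, 0L, 1L))
  chrom <- "chr1"
  genes <- vector("list", config$n_genes)
  cursor <- 10000
  for (i in seq_len(config$n_genes)) {
    span <- round(runif(1, config$span_range[1], config$span_range[2]))
    n_ex <- sample(seq(config$n_exons_range[1], config$n_exons_range[2]), 1)
    # exon starts spread over the span; widths 100-1000 bp, clipped to span
    width <- pmin(round(runif(n_ex, 100, 1000)), floor(span / n_ex) - 10)
    width <- pmax(width, 50)
    gap_total <- span - sum(width)
    gaps <- c(0, sort(round(runif(n_ex - 1, 0, gap_total))))
    gaps <- diff(c(0, gaps[-1], gap_total))
    starts <- cumsum(c(0, width[-n_ex])) + cumsum(c(0, gaps[-1]))
    starts <- starts - starts[1]
    scale_fit <- (span - width[n_ex]) / max(starts[n_ex], 1)
    if (n_ex > 1) starts <- round(starts * min(1, scale_fit))
    exons <- cbind(start = starts, end = starts + width)
    exons <- exons[order(exons[, 1]), , drop = FALSE]
    # drop accidental overlaps between consecutive exons
    keep <- c(TRUE, exons[-1, 1] >= exons[-nrow(exons), 2])
    exons <- exons[keep, , drop = FALSE]
    n_ex <- nrow(exons)
    cassette <- if (n_ex >= 3) sample(2:(n_ex - 1), 1) else NA_integer_
    if (i == 2 && config$overlapping_pair) {
      # start inside gene 1's downstream flank
      g1 <- genes[[1]]
      cursor <- g1$gene_start + round(0.9 * (g1$gene_end - g1$gene_start))
    }
    gene_start <- cursor
    genes[[i]] <- list(
      gene_id = sprintf("SIMG%04d", i),
      chrom = chrom, strand = if (runif(1) < 0.5) "+" else "-",
      gene_start = gene_start, gene_end = gene_start + span,
      exons = exons + gene_start,
      cassette = cassette,
      iso1 = seq_len(n_ex),
      iso2 = if (is.na(cassette)) seq_len(n_ex) else setdiff(seq_len(n_ex), cassette),
      biotype = if (runif(1) < config$lnc_fraction) "lncRNA" else "protein_coding",
      baseline = config$baseline_depth * 2^runif(1, -1, 1),
      # gene-specific responsiveness to the shared expression factor; with a
      # uniform loading the factor would be removed exactly by median depth
      # scaling, which no real cohort exhibits
      expr_loading = runif(1, 0.5, 1.5))
    cursor <- gene_start + span + 10000
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  gtf <- unlist(lapply(genes, function(g) {
    attr_g <- sprintf('gene_id "%s"; gene_type "%s";', g$gene_id, g$biotype)
    rows <- sprintf("%s\tddpheno_sim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    g$chrom, g$gene_start + 1, g$gene_end, g$strand, attr_g)
    for (iso in c(1, 2)) {
      idx <- if (iso == 1) g$iso1 else g$iso2
      tid <- sprintf("%s.t%d", g$gene_id, iso)
      tr_attr <- sprintf('%s transcript_id "%s";', attr_g, tid)
      ex <- g$exons[idx, , drop = FALSE]
      rows <- c(rows,
        sprintf("%s\tddpheno_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, min(ex[, 1]) + 1, max(ex[, 2]), g$strand, tr_attr),
        sprintf("%s\tddpheno_sim\texon\t%d\t%d\t.\t%s\t.\t%s",
                g$chrom, ex[, 1] + 1, ex[, 2], g$strand, tr_attr))
    }
    rows
  }), use.names = FALSE)
  list(genes = genes, chrom = chrom, chrom_length = cursor + 10000, gtf = gtf)
}

#' Draw per-sample latent factors
#'
#' @param config a [sim_config()].
#' @return data.frame with sample_id, e (expression factor), u (usage
#'   factor), d (depth multiplier).
#' @export
simulate_factors <- function(config) {
  set.seed(sub_seed(config$seed, 0L, 2L))
  n <- config$n_samples
  data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    e = rnorm(n, 0, config$sigma_e),
    u = rnorm(n, 0, config$sigma_u),
    d = exp(rnorm(n, 0, config$sigma_d)))
}

# expected per-base coverage over [from, to) for one gene, one sample set
expected_gene_coverage <- function(gene, factors, config, from, to) {
  L <- to - from
  n <- nrow(factors)
  # softmax over the two isoforms; usage factor pushes toward isoform 1
  eta1 <- config$usage_sensitivity * factors$u
  w1 <- exp(eta1) / (exp(eta1) + 1)
  scale_s <- factors$d * 2^(gene$expr_loading * factors$e) * gene$baseline
  lam <- matrix(0, n, L)
  for (iso in c(1, 2)) {
    idx <- if (iso == 1) gene$iso1 else gene$iso2
    w <- if (iso == 1) w1 else 1 - w1
    mask <- rep(0, L)
    for (e_i in idx) {
      s <- max(gene$exons[e_i, 1], from) - from
      e <- min(gene$exons[e_i, 2], to) - from
      if (e > s) mask[(s + 1):e] <- 1
    }
    if (any(mask > 0)) lam <- lam + (scale_s * w) %o% mask
  }
  lam
}

# one gene's observed coverage stack over its region, all samples;
# shared by simulate_coverage() and sim_coverage_source() so both are
# bit-identical for the same config
sim_gene_stack <- function(ann, factors, config, regions, gene_idx) {
  g <- ann$genes[[gene_idx]]
  rg <- regions[[g$gene_id]]
  lam <- expected_gene_coverage(g, factors, config,
                                rg$region_start, rg$region_end)
  for (j in seq_along(ann$genes)) {     # overlapping neighbours
    if (j == gene_idx) next
    og <- ann$genes[[j]]
    if (og$gene_end <= rg$region_start || og$gene_start >= rg$region_end) next
    lam <- lam + expected_gene_coverage(og, factors, config,
                                        rg$region_start, rg$region_end)
  }
  vals <- if (config$noise == "poisson") {
    set.seed(sub_seed(config$seed, gene_idx, 3L))
    matrix(rpois(length(lam), lam), nrow = nrow(lam))
  } else lam
  coverage_stack(g$gene_id, factors$sample_id, vals)
}

#' Streaming coverage source over a simulated dataset
#'
#' Generates each gene's coverage stack on demand (deterministically, from
#' the config seed) instead of materializing the whole cohort, so large
#' simulated genomes fit in memory. Produces exactly the same values as
#' [simulate_coverage()] for the same config.
#'
#' @param config a [sim_config()].
#' @param flank_bp region flank (default 1000).
#' @return a `coverage_source`, with the simulation attached as attributes
#'   `regions`, `truth`, and `annotation`.
#' @export
sim_coverage_source <- function(config, flank_bp = 1000L) {
  ann <- simulate_annotation(config)
  factors <- simulate_factors(config)
  regions <- regions_from_sim(ann, flank_bp)
  idx_of <- stats::setNames(seq_along(ann$genes), names(ann$genes))
  src <- structure(list(
    sample_ids = factors$sample_id,
    fetch = function(region, sample_ids = factors$sample_id) {
      st <- sim_gene_stack(ann, factors, config, regions,
                           idx_of[[region$gene_id]])
      coverage_stack(st$gene_id, sample_ids,
                     st$values[sample_ids, , drop = FALSE])
    }), class = "coverage_source")
  attr(src, "regions") <- regions
  attr(src, "truth") <- list(factors = factors, genes = ann$genes,
                             config = config)
  attr(src, "annotation") <- ann
  src
}

#' Simulate a population coverage dataset
#'
#' Returns per-gene coverage stacks over each gene's phenotyping region
#' (gene span +/- `flank_bp`) plus the ground truth needed to recompute
#' expectations. Expected per-base coverage for sample s is
#' `d_s * 2^(e_s) * sum_i w_i(u_s) * baseline * [base in exons of isoform i]`
#' with softmax usage weights; observed coverage is Poisson around that
#' (or exactly equal, with `noise = "none"`). Overlapping genes contribute
#' additively to each other's regions.
#'
#' @param config a [sim_config()].
#' @param flank_bp region flank (default 1000).
#' @return list with `stacks` (named list of [coverage_stack()]), `regions`
#'   (named list of [gene_region()], foreign exons included), `truth`
#'   (factors, gene definitions, config), and `annotation` (from
#'   [simulate_annotation()]).
#' @export
simulate_coverage <- function(config, flank_bp = 1000L) {
  ann <- simulate_annotation(config)
  factors <- simulate_factors(config)
  regions <- regions_from_sim(ann, flank_bp)
  stacks <- lapply(seq_along(ann$genes), function(i)
    sim_gene_stack(ann, factors, config, regions, i))
  names(stacks) <- names(ann$genes)
  list(stacks = stacks, regions = regions,
       truth = list(factors = factors, genes = ann$genes, config = config),
       annotation = ann)
}

# GeneRegion list (with foreign exons) straight from a simulated annotation
regions_from_sim <- function(ann, flank_bp = 1000L) {
  regions <- list()
  for (g in ann$genes) {
    rs <- max(0, g$gene_start - flank_bp)
    re <- min(ann$chrom_length, g$gene_end + flank_bp)
    fe <- matrix(numeric(0), ncol = 2L)
    others <- ann$genes[names(ann$genes) != g$gene_id]
    iv <- do.call(rbind, lapply(others, function(og) og$exons))
    if (!is.null(iv)) {
      hit <- iv[, 2] > rs & iv[, 1] < re
      iv <- iv[hit, , drop = FALSE]
      if (nrow(iv)) {
        ir <- IRanges::reduce(IRanges::IRanges(iv[, 1] + 1, iv[, 2]))
        fe <- cbind(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
      }
    }
    regions[[g$gene_id]] <- gene_region(g$gene_id, g$chrom, g$strand,
                                        g$gene_start, g$gene_end, rs, re,
                                        g$biotype, fe)
  }
  regions
}

#' Write simulated coverage as per-sample bigWig files
#'
#' Builds each sample's genome-wide per-base coverage (all genes summed, so
#' overlapping genes mix as they would in alignment output) and exports one
#' bigWig per sample at single-base resolution.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return named character vector of bigWig paths (names = sample IDs), with
#'   the simulation attached as attribute `sim`.
#' @export
simulate_bigwigs <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- simulate_annotation(config)
  factors <- simulate_factors(config)
  L <- ann$chrom_length
  lam_all <- matrix(0, config$n_samples, L)
  for (g in ann$genes)
    lam_all[, (g$gene_start + 1):g$gene_end] <-
      lam_all[, (g$gene_start + 1):g$gene_end] +
      expected_gene_coverage(g, factors, config, g$gene_start, g$gene_end)
  paths <- character(config$n_samples)
  for (s in seq_len(config$n_samples)) {
    vals <- if (config$noise == "poisson") {
      set.seed(sub_seed(config$seed, s, 4L))
      rpois(L, lam_all[s, ])
    } else lam_all[s, ]
    covl <- IRanges::RleList(S4Vectors::Rle(as.numeric(vals)))
    names(covl) <- ann$chrom
    paths[s] <- file.path(dir, paste0(factors$sample_id[s], ".bw"))
    rtracklayer::export.bw(covl, paths[s])
  }
  names(paths) <- factors$sample_id
  attr(paths, "sim") <- list(annotation = ann, truth =
    list(factors = factors, genes = ann$genes, config = config))
  paths
}

#' Simulate knowledge-driven phenotypes matched to a simulation
#'
#' For each gene: an `expression` KDP (log2 of the sample's total expected
#' gene coverage) and an `isoform_ratio` KDP (the softmax weight of isoform
#' 1), each plus Normal noise of sd `noise_sd`.
#'
#' @param truth the `truth` element of [simulate_coverage()].
#' @param modalities subset of `c("expression", "isoform_ratio")`.
#' @param noise_sd measurement-noise sd added to each KDP (default 0.1).
#' @return a [kdp_table()].
#' @export
simulate_kdps <- function(truth, modalities = c("expression", "isoform_ratio"),
                          noise_sd = 0.1) {
  config <- truth$config
  factors <- truth$factors
  set.seed(sub_seed(config$seed, 0L, 5L))
  gene_id <- character(0); phen_id <- character(0); modality <- character(0)
  rows <- list()
  for (g in truth$genes) {
    lam <- expected_gene_coverage(g, factors, config, g$gene_start, g$gene_end)
    if ("expression" %in% modalities) {
      v <- log2(rowSums(lam) + 1) + rnorm(nrow(factors), 0, noise_sd)
      gene_id <- c(gene_id, g$gene_id)
      phen_id <- c(phen_id, paste0(g$gene_id, ":expr"))
      modality <- c(modality, "expression")
      rows[[length(rows) + 1]] <- v
    }
    if ("isoform_ratio" %in% modalities) {
      eta1 <- config$usage_sensitivity * factors$u
      w1 <- exp(eta1) / (exp(eta1) + 1)
      v <- w1 + rnorm(nrow(factors), 0, noise_sd)
      gene_id <- c(gene_id, g$gene_id)
      phen_id <- c(phen_id, paste0(g$gene_id, ":iso"))
      modality <- c(modality, "isoform_ratio")
      rows[[length(rows) + 1]] <- v
    }
  }
  kdp_table(gene_id, phen_id, modality, do.call(rbind, rows),
            factors$sample_id)
}
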