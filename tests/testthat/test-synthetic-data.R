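# Synthetic data generator: annotation validity, coverage model, KDPs,
# and latent-factor recovery through the full pipeline.

test_that("simulated annotation round-trips through the GTF parser", {
  cfg <- sim_config(n_genes = 20, n_samples = 2, span_range = c(5000, 15000),
                    seed = 61)
  ann <- simulate_annotation(cfg)
  gtf <- withr::local_tempfile(lines = ann$gtf, fileext = ".gtf")
  regions <- parse_gene_regions(gtf, flank_bp = 1000)
  expect_length(regions, 20)
  for (g in ann$genes) {
    rg <- regions[[g$gene_id]]
    expect_equal(rg$gene_start, g$gene_start)
    expect_equal(rg$gene_end, g$gene_end)
    expect_equal(rg$biotype, g$biotype)
  }
  # the overlapping pair acquires foreign exons on both sides
  expect_gt(nrow(regions[[1]]$foreign_exons), 0)
  expect_gt(nrow(regions[[2]]$foreign_exons), 0)
  # parser-derived foreign exons equal the simulator's own computation
  sim_regions <- simulate_coverage(
    sim_config(n_genes = 20, n_samples = 2, span_range = c(5000, 15000),
               seed = 61))$regions
  for (g in names(regions))
    expect_equal(regions[[g]]$foreign_exons, sim_regions[[g]]$foreign_exons,
                 ignore_attr = TRUE)
})

test_that("zero-variance config gives identical samples; gene filtered path works", {
  cfg <- sim_config(n_genes = 3, n_samples = 6, span_range = c(4000, 6000),
                    sigma_e = 0, sigma_u = 0, sigma_d = 0, noise = "none",
                    seed = 62)
  sim <- simulate_coverage(cfg)
  st <- sim$stacks[[3]]
  for (s in 2:6) expect_equal(st$values[s, ], st$values[1, ])
  # identical samples -> constant bins -> 0-component model, handled cleanly
  region <- sim$regions[[3]]
  sch <- uniform_bins(region, 500)
  raw <- mean_coverage_per_bin(st, sch, region)
  lg <- log_transform(apply_scaling(raw, scaling_factors(list(raw))), 8)
  m <- fit_gene_model(lg)
  expect_equal(m$n_components, 0L)
})

test_that("mean observed coverage approaches its expectation (LLN)", {
  cfg <- sim_config(n_genes = 2, n_samples = 500, span_range = c(4000, 5000),
                    sigma_e = 0, sigma_u = 0, sigma_d = 0, seed = 63)
  sim <- simulate_coverage(cfg)
  cfg0 <- sim_config(n_genes = 2, n_samples = 500, span_range = c(4000, 5000),
                     sigma_e = 0, sigma_u = 0, sigma_d = 0, noise = "none",
                     seed = 63)
  sim0 <- simulate_coverage(cfg0)
  g <- names(sim$stacks)[2]
  lam <- sim0$stacks[[g]]$values[1, ]
  covered <- lam > 5
  obs_mean <- colMeans(sim$stacks[[g]]$values)
  expect_lt(max(abs(obs_mean[covered] / lam[covered] - 1)), 0.2)
  # aggregate mean over all covered bases within 2%
  expect_lt(abs(mean(obs_mean[covered]) / mean(lam[covered]) - 1), 0.02)
})

test_that("determinism: identical seeds give identical datasets", {
  cfg <- sim_config(n_genes = 3, n_samples = 5, span_range = c(4000, 6000),
                    seed = 64)
  s1 <- simulate_coverage(cfg)
  s2 <- simulate_coverage(cfg)
  expect_identical(s1$stacks[[2]]$values, s2$stacks[[2]]$values)
  expect_identical(s1$truth$factors, s2$truth$factors)
  s3 <- simulate_coverage(sim_config(n_genes = 3, n_samples = 5,
                                     span_range = c(4000, 6000), seed = 65))
  expect_false(identical(s1$stacks[[2]]$values, s3$stacks[[2]]$values))
})

test_that("expression factor dominates DDP1 when usage variance is small", {
  cfg <- sim_config(n_genes = 10, n_samples = 150, span_range = c(5000, 10000),
                    sigma_e = 1, sigma_u = 0.1, seed = 66)
  sim <- simulate_coverage(cfg)
  src <- memory_coverage_source(sim$stacks)
  store <- fit_ddp_models(sim$regions, src,
                          params = list(target_mean_bins = 64, seed = 66))
  tab <- apply_ddp_models(store, src)
  cors <- vapply(names(store$models), function(g)
    abs(cor(tab$values[paste0(g, ":PC1"), ], sim$truth$factors$e)), 0)
  expect_gte(stats::median(cors), 0.8)
})

test_that("usage factor surfaces in a retained DDP when it dominates", {
  cfg <- sim_config(n_genes = 8, n_samples = 200, span_range = c(6000, 12000),
                    sigma_e = 0.1, sigma_u = 2, usage_sensitivity = 2,
                    seed = 67)
  sim <- simulate_coverage(cfg)
  src <- memory_coverage_source(sim$stacks)
  store <- fit_ddp_models(sim$regions, src,
                          params = list(target_mean_bins = 64, seed = 67))
  tab <- apply_ddp_models(store, src)
  # among genes with a cassette exon, some DDP must carry the usage factor
  cassette_genes <- names(Filter(function(g) !is.na(g$cassette),
                                 sim$truth$genes))
  cassette_genes <- intersect(cassette_genes, names(store$models))
  best <- vapply(cassette_genes, function(g) {
    idx <- which(tab$gene_id == g)
    max(abs(cor(t(tab$values[idx, , drop = FALSE]), sim$truth$factors$u)))
  }, 0)
  expect_gte(max(best), 0.6)
})

test_that("simulated KDPs track their latent drivers", {
  cfg <- sim_config(n_genes = 4, n_samples = 300, span_range = c(5000, 8000),
                    seed = 68)
  sim <- simulate_coverage(cfg)
  kdps <- simulate_kdps(sim$truth, noise_sd = 1e-4)
  g <- names(sim$stacks)[3]
  expr <- kdps$genes[[g]][, paste0(g, ":expr")]
  iso <- kdps$genes[[g]][, paste0(g, ":iso")]
  expect_gte(abs(cor(expr, sim$truth$factors$e)), 0.9)
  expect_gte(abs(cor(iso, sim$truth$factors$u)), 0.9)
  # modality labels round-trip through holdout
  held <- holdout_modality(kdps, "isoform_ratio")
  expect_setequal(unname(held$modality), "expression")
})

test_that("residualizing on zero-noise expression KDPs collapses bin r2", {
  cfg <- sim_config(n_genes = 6, n_samples = 200, span_range = c(5000, 9000),
                    sigma_u = 0.1, seed = 69)
  sim <- simulate_coverage(cfg)
  src <- memory_coverage_source(sim$stacks)
  schemes <- define_bins(sim$regions, src,
                         params = list(target_mean_bins = 48, seed = 69))
  norm <- bin_and_normalize(sim$regions, schemes, src)
  kdps <- simulate_kdps(sim$truth, modalities = "expression", noise_sd = 0)
  r2_with <- function(vals, k) suppressWarnings(
    max(apply(vals, 2, function(b) cor(b, k)^2), na.rm = TRUE))
  before <- after <- numeric(0)
  for (g in names(norm$normalized)) {
    K <- kdps$genes[[g]]
    res <- residualize_gene(norm$normalized[[g]], K)$residual
    before[g] <- r2_with(norm$normalized[[g]]$values, K[, 1])
    after[g] <- r2_with(res$values, K[, 1])
  }
  # most genes start strongly coupled to the expression KDP (genes whose
  # expression loading sits at the depth-scaling mean lose signal upstream)
  expect_gte(median(before), 0.5)
  # ... and residualization collapses the coupling for every gene
  expect_true(all(after < 0.05))
})

test_that("withholding a modality lets rDDPs re-acquire the withheld factor", {
  cfg <- sim_config(n_genes = 6, n_samples = 250, span_range = c(6000, 10000),
                    sigma_e = 1, sigma_u = 2, usage_sensitivity = 2, seed = 70)
  sim <- simulate_coverage(cfg)
  src <- memory_coverage_source(sim$stacks)
  kdps <- simulate_kdps(sim$truth, noise_sd = 0.01)
  fit_with <- function(k) fit_ddp_models(
    sim$regions, src, params = list(target_mean_bins = 48, seed = 70), kdps = k)
  max_iso_cor <- function(store) {
    tab <- apply_ddp_models(store, src,
      kdps = if (store$models[[1]]$flavor == "rddp") kdps_used[[1]] else NULL)
    vapply(intersect(names(store$models), cassette_genes), function(g) {
      idx <- which(tab$gene_id == g)
      if (!length(idx)) return(0)
      max(abs(cor(t(tab$values[idx, , drop = FALSE]), sim$truth$factors$u)))
    }, 0)
  }
  cassette_genes <- names(Filter(function(g) !is.na(g$cassette),
                                 sim$truth$genes))
  # full KDP set: isoform signal regressed away
  kdps_used <- list(kdps)
  store_full <- fit_with(kdps)
  cor_full <- max_iso_cor(store_full)
  # withhold the isoform-ratio modality: signal must reappear
  held <- holdout_modality(kdps, "isoform_ratio")
  kdps_used <- list(held)
  store_held <- fit_with(held)
  cor_held <- max_iso_cor(store_held)
  expect_gte(max(cor_held), 0.5)
  expect_gt(max(cor_held), max(cor_full))
})
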