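# The orchard, genotype, phenotype and spectra generators.

test_that("genotype simulation is deterministic, shaped and in range", {
  a <- simulate_genotypes(10, 100, seed = 7)
  b <- simulate_genotypes(10, 100, seed = 7)
  expect_identical(a$dosages, b$dosages)
  expect_false(identical(a$dosages,
                         simulate_genotypes(10, 100, seed = 8)$dosages))
  tiny <- simulate_genotypes(2, 1, seed = 1)
  expect_equal(dim(tiny$dosages), c(2L, 1L))
  expect_true(all(tiny$dosages %in% c(0L, 1L, 2L)))
  expect_error(simulate_genotypes(0, 10), "n_clones")
  expect_error(simulate_genotypes(5, 0), "n_snps")
})

test_that("dosages match binomial moments at a fixed allele frequency", {
  g <- simulate_genotypes(50, 10000, maf_distribution = 0.5, seed = 11)
  # E[dosage] = 2p = 1, Var = 2p(1-p) = 0.5
  mc_se <- sqrt(0.5 / length(g$dosages))
  expect_lt(abs(mean(g$dosages) - 1), 3 * mc_se)
  # per-SNP frequencies are proper frequencies
  p_hat <- colMeans(g$dosages) / 2
  expect_true(all(p_hat >= 0 & p_hat <= 1))
})

test_that("beta-sampled allele frequencies stay inside the (0.02, 0.5) window", {
  g <- simulate_genotypes(400, 2000, maf_distribution = c(0.5, 0.5), seed = 3)
  p_hat <- colMeans(g$dosages) / 2
  # sampling noise around the truncated support; generous slack at n = 400
  expect_true(all(p_hat > 0.001 & p_hat < 0.6))
})

test_that("orchard design covers clones, keeps cells distinct, errors on capacity", {
  cfg <- sim_config(n_clones = 31, ramets_per_site = 200,
                    grid_rows = 20, grid_cols = 15, seed = 5)
  d <- simulate_orchard_design(cfg)
  expect_equal(nrow(d), 200L)
  expect_equal(anyDuplicated(paste(d$site, d$row, d$col)), 0L)
  expect_true(all(seq_len(31) %in% d$clone))
  one <- simulate_orchard_design(sim_config(n_clones = 1, ramets_per_site = 1,
                                            grid_rows = 1, grid_cols = 1))
  expect_equal(nrow(one), 1L)
  expect_true(one$row == 1 && one$col == 1)
  expect_error(sim_config(n_clones = 10, ramets_per_site = 100,
                          grid_rows = 5, grid_cols = 5),
               "capacity")
  d2 <- simulate_orchard_design(cfg)
  expect_identical(as.data.frame(d), as.data.frame(d2))
})

test_that("degenerate variances give exactly the mean; perfect correlation
           duplicates site values", {
  K <- diag(8)
  cfg <- sim_config(n_clones = 8, ramets_per_site = 16, mean = 5,
                    genetic_variance = 0, spatial_variance = 0, nugget = 0,
                    seed = 2)
  st <- simulate_phenotypes(simulate_orchard_design(cfg), K, cfg)
  expect_equal(st$phenotypes$y, rep(5, 16))
  cfg2 <- sim_config(n_clones = 8, n_sites = 2, ramets_per_site = c(12, 12),
                     genetic_variance = c(0.4, 0.4),
                     cross_site_genetic_correlation = 1,
                     spatial_variance = 0, nugget = 0, seed = 3)
  st2 <- simulate_phenotypes(simulate_orchard_design(cfg2), diag(8), cfg2)
  expect_equal(st2$true_clonal_values[, 1], st2$true_clonal_values[, 2],
               tolerance = 1e-10)
})

test_that("clone values recover their generative variance (moment check)", {
  n <- 6000
  cfg <- sim_config(n_clones = n, ramets_per_site = n,
                    grid_rows = 80, grid_cols = 82,
                    genetic_variance = 1, spatial_variance = 0, nugget = 0,
                    seed = 9)
  st <- simulate_phenotypes(simulate_orchard_design(cfg), diag(n), cfg)
  v <- var(st$phenotypes$y)
  mc_se <- sqrt(2 / (n - 1))  # var of a sample variance of N(0,1)
  expect_lt(abs(v - 1), 3 * mc_se)
})

test_that("phenotypes decompose exactly into stored truth components", {
  qs <- quick_study(n_clones = 12, n_ramets = 50, seed = 13)
  st <- qs$study
  recomposed <- st$truth$fixed + st$truth$genetic + st$truth$spatial +
    st$truth$nugget
  expect_equal(st$phenotypes$y, recomposed, tolerance = 1e-12)
  # and the same seed reproduces the study byte-for-byte
  st2 <- simulate_phenotypes(st$design, qs$K, qs$cfg)
  expect_identical(st$phenotypes, st2$phenotypes)
})

test_that("pure spatial field shows the configured lag-1 row correlation", {
  rho <- 0.6
  cfg <- sim_config(n_clones = 2, ramets_per_site = 2400,
                    grid_rows = 48, grid_cols = 50,
                    genetic_variance = 0, spatial_variance = 1, nugget = 0,
                    rho_col = 0.3, rho_row = rho, seed = 17)
  st <- simulate_phenotypes(simulate_orchard_design(cfg), diag(2), cfg)
  ph <- st$phenotypes
  key <- paste(ph$row, ph$col)
  up <- match(paste(ph$row + 1, ph$col), key)
  ok <- !is.na(up)
  r_hat <- cor(ph$y[ok], ph$y[up[ok]])
  expect_lt(abs(r_hat - rho), 0.06)
})

test_that("GRM that is not positive semi-definite is rejected", {
  K <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  cfg <- sim_config(n_clones = 2, ramets_per_site = 4, seed = 1)
  expect_error(simulate_phenotypes(simulate_orchard_design(cfg), K, cfg),
               "positive semi-definite")
})

test_that("spectra have the requested bands and band-smooth genetic signal", {
  K <- diag(150)
  cfg <- sim_config(n_clones = 150, ramets_per_site = 150, n_bands = 220,
                    band_correlation_length = 15, band_h2 = 0.95, seed = 4)
  sp <- simulate_spectra(simulate_orchard_design(cfg), K, cfg)
  expect_s3_class(sp, "spectra_table")
  expect_equal(ncol(sp$reflectance), 220L)
  # adjacent bands more correlated than distant ones
  r_adj <- cor(sp$reflectance[, 10], sp$reflectance[, 11])
  r_far <- cor(sp$reflectance[, 10], sp$reflectance[, 150])
  expect_gt(r_adj, r_far + 0.3)
  # infinite-bandwidth limit: one shared signal across all bands
  cfg2 <- sim_config(n_clones = 150, ramets_per_site = 150, n_bands = 12,
                     band_correlation_length = 1e7, band_h2 = 0.99, seed = 5)
  sp2 <- simulate_spectra(simulate_orchard_design(cfg2), K, cfg2)
  expect_gt(cor(sp2$reflectance[, 1], sp2$reflectance[, 12]), 0.95)
  cfg_bad <- cfg
  cfg_bad$band_correlation_length <- 0
  expect_error(simulate_spectra(simulate_orchard_design(cfg), K, cfg_bad),
               "band_correlation_length")
})

test_that("trait pairs honor their generative correlations at scale", {
  K <- diag(800)
  cfg <- sim_config(n_clones = 800, ramets_per_site = 800, seed = 6)
  d <- simulate_orchard_design(cfg)
  tp <- simulate_trait_pair(d, K, gvar = c(1, 1), gcor = 0.8,
                            evar = c(0.01, 0.01), ecor = 0, seed = 8)
  expect_lt(abs(cor(tp$true_clonal_values[, 1],
                    tp$true_clonal_values[, 2]) - 0.8), 0.05)
  expect_error(simulate_trait_pair(d, K, gvar = c(1, 1), gcor = 1.4,
                                   evar = c(1, 1), ecor = 0),
               "invalid")
})
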