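# Parameter-recovery replicates: one synthetic study is generated under a
# known truth and analyzed exactly as real data would be. Used to validate
# the estimator and to calibrate expectations for orchard-scale designs.

#' One single-site heritability recovery replicate
#'
#' Simulates an orchard of `n_clones` clones and `n_ramets` ramets with a
#' genomic relationship matrix built from freshly simulated SNPs, true
#' broad-sense heritability `true_h2` (phenotypic variance 1; the
#' non-genetic part split equally between the AR1 x AR1 spatial field and
#' the nugget), fits the univariate genomic mixed model by REML and returns
#' the heritability estimate.
#'
#' @param n_clones,n_ramets orchard scale.
#' @param true_h2 generative heritability in (0, 1).
#' @param n_snps SNPs for the relationship matrix (default 5000).
#' @param grid_rows,grid_cols planting grid (defaults sized to fit).
#' @param rho spatial AR1 correlation used in both directions (default 0.5).
#' @param seed replicate seed.
#' @param test run the genetic-variance LRT (default FALSE).
#' @return list with `h2`, `se`, `p_value`, `fit`.
#' @export
recover_heritability_single <- function(n_clones, n_ramets, true_h2,
                                        n_snps = 5000, grid_rows = NULL,
                                        grid_cols = NULL, rho = 0.5,
                                        seed = 1L, test = FALSE) {
  stopifnot(true_h2 > 0, true_h2 < 1)
  cfg <- sim_config(
    n_clones = n_clones, n_sites = 1L, ramets_per_site = n_ramets,
    grid_rows = grid_rows, grid_cols = grid_cols, n_snps = n_snps,
    genetic_variance = true_h2,
    spatial_variance = (1 - true_h2) / 2, nugget = (1 - true_h2) / 2,
    rho_col = rho, rho_row = rho, seed = seed)
  geno <- simulate_genotypes(n_clones, n_snps, seed = derive_seed(seed, 21L))
  K <- stabilize_psd(grm_yang(snp_summaries(geno)))
  design <- simulate_orchard_design(cfg)
  study <- simulate_phenotypes(design, K, cfg)
  fit <- fit_reml(model_data(study$phenotypes, "y", K),
                  control = list(restarts = 0L))
  h <- heritability(fit, "site_1", test = test)
  list(h2 = h$H2, se = h$se, p_value = h$p_value, fit = fit)
}

#' One two-site recovery replicate (pooled heritability and type B)
#'
#' Simulates two sites with partially overlapping clone sets (mirroring a
#' pair of orchards sharing a subset of genotypes), per-site heritability
#' `per_site_h2` and cross-site genetic correlation `r_gen`; fits the
#' multi-site model plus the two single-site models and returns the pooled
#' heritability, the type B correlation and the three SEs.
#'
#' @param n_clones per-site clone counts (default c(31, 29)).
#' @param shared number of clones present at both sites (default 24).
#' @param ramets per-site ramet counts (default c(200, 148)).
#' @param per_site_h2 generative heritability at each site (scalar or
#'   length 2).
#' @param r_gen cross-site genetic correlation.
#' @param n_snps,rho,seed as in [recover_heritability_single()].
#' @param single_site_fits also fit each site separately (for SE
#'   comparison; default TRUE).
#' @return list with `pooled_h2`, `pooled_se`, `type_b`, `type_b_se`,
#'   `site_h2`, `site_se`, `fit`.
#' @export
recover_two_site <- function(n_clones = c(31L, 29L), shared = 24L,
                             ramets = c(200L, 148L), per_site_h2,
                             r_gen, n_snps = 5000, rho = 0.5, seed = 1L,
                             single_site_fits = TRUE) {
  per_site_h2 <- rep_len(per_site_h2, 2L)
  n_total <- sum(n_clones) - shared
  cl1 <- seq_len(n_clones[1])
  cl2 <- seq.int(n_clones[1] - shared + 1L, n_total)
  gr <- ceiling(sqrt(ramets * 1.08))
  gc <- ceiling(ramets * 1.08 / gr)
  cfg <- sim_config(
    n_clones = n_total, n_sites = 2L, ramets_per_site = ramets,
    clones_per_site = list(cl1, cl2), grid_rows = gr, grid_cols = gc,
    n_snps = n_snps, genetic_variance = per_site_h2,
    cross_site_genetic_correlation = r_gen,
    spatial_variance = (1 - per_site_h2) / 2,
    nugget = (1 - per_site_h2) / 2,
    rho_col = rho, rho_row = rho, seed = seed)
  geno <- simulate_genotypes(n_total, n_snps, seed = derive_seed(seed, 22L))
  K <- stabilize_psd(grm_yang(snp_summaries(geno)))
  design <- simulate_orchard_design(cfg)
  study <- simulate_phenotypes(design, K, cfg)
  fit <- fit_reml(model_data(study$phenotypes, "y", K),
                  control = list(restarts = 0L))
  hp <- heritability(fit, "pooled", test = FALSE)
  tb <- type_b_correlation(fit, test = FALSE)
  site_h2 <- site_se <- rep(NA_real_, 2L)
  if (single_site_fits) {
    for (s in 1:2) {
      sub <- study$phenotypes[study$phenotypes$site == s, , drop = FALSE]
      fs <- fit_reml(model_data(sub, "y", K), control = list(restarts = 0L))
      hs <- heritability(fs, "site_1", test = FALSE)
      site_h2[s] <- hs$H2; site_se[s] <- hs$se
    }
  }
  list(pooled_h2 = hp$H2, pooled_se = hp$se,
       type_b = tb$value, type_b_se = tb$se,
       site_h2 = site_h2, site_se = site_se, fit = fit)
}

#' One bivariate (trait-pair / year-to-year) recovery replicate
#'
#' Simulates the same clones measured twice (two years, or two traits) with
#' per-response heritability `h2`, true genetic correlation `gcor` and
#' residual correlation `ecor`; fits the bivariate genomic model and
#' returns the estimated genetic correlation.
#'
#' @param n_clones,n_ramets scale of the single orchard.
#' @param h2 per-response heritability (phenotypic variance 1).
#' @param gcor,ecor generative genetic and residual correlations.
#' @param n_snps,seed as in [recover_heritability_single()].
#' @return list with `gcor`, `se`, `boundary`, `fit`.
#' @export
recover_trait_pair <- function(n_clones = 67L, n_ramets = 900L, h2 = 0.25,
                               gcor, ecor = 0.3, n_snps = 5000, seed = 1L) {
  geno <- simulate_genotypes(n_clones, n_snps, seed = derive_seed(seed, 23L))
  K <- stabilize_psd(grm_yang(snp_summaries(geno)))
  gr <- ceiling(sqrt(n_ramets * 1.05))
  cfg <- sim_config(n_clones = n_clones, ramets_per_site = n_ramets,
                    grid_rows = gr,
                    grid_cols = ceiling(n_ramets * 1.05 / gr),
                    n_snps = n_snps, seed = seed)
  design <- simulate_orchard_design(cfg)
  tp <- simulate_trait_pair(design, K, gvar = c(h2, h2), gcor = gcor,
                            evar = c(1 - h2, 1 - h2), ecor = ecor,
                            seed = derive_seed(seed, 24L))
  fit <- fit_reml(model_data_bivariate(tp$phenotypes, c("y1", "y2"), K),
                  control = list(restarts = 0L))
  ce <- trait_pair_correlation(fit, "year_to_year", test = FALSE)
  list(gcor = ce$value, se = ce$se, boundary = ce$boundary, fit = fit)
}
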