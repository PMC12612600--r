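# Heritability, genetic correlations, per-wavelength scans.

# A hand-built fit object for pure-arithmetic checks.
fake_fit <- function(est, n_sites = 1L, include_spatial = TRUE,
                     site_idx = NULL, vcov = NULL) {
  nm <- names(est)
  if (is.null(vcov)) vcov <- diag(1e-4, length(est),
                                  length(est)) |>
      `dimnames<-`(list(nm, nm))
  structure(list(
    estimates = est,
    spec = list(names = nm, types = ifelse(grepl("cov", nm), "cov",
                                           ifelse(grepl("rho", nm), "rho",
                                                  "var")),
                model = "univariate", include_spatial = include_spatial,
                n_sites = n_sites, genetic = TRUE),
    boundary = setNames(rep(FALSE, length(est)), nm),
    vcov = vcov, se = sqrt(diag(vcov)), loglik = -1,
    data = list(site_idx = site_idx %||% rep(1L, 10))),
    class = "vc_fit")
}

test_that("heritability is the genetic fraction of phenotypic variance", {
  f <- fake_fit(c(gvar_s1 = 1, svar_s1 = 1, rho_col_s1 = 0.2,
                  rho_row_s1 = 0.2, nugget_s1 = 2))
  h <- heritability(f, "site_1", test = FALSE)
  expect_equal(h$H2, 0.25)
  f0 <- fake_fit(c(gvar_s1 = 0, svar_s1 = 1, rho_col_s1 = 0.2,
                   rho_row_s1 = 0.2, nugget_s1 = 2))
  expect_equal(heritability(f0, test = FALSE)$H2, 0)
  # pooled scope: ramet-weighted mean of per-site values
  f2 <- fake_fit(c(gvar_s1 = 1, gvar_s2 = 3, gcov = 1,
                   svar_s1 = 1, rho_col_s1 = 0, rho_row_s1 = 0,
                   svar_s2 = 3, rho_col_s2 = 0, rho_row_s2 = 0,
                   nugget_s1 = 2, nugget_s2 = 4),
                 n_sites = 2L, site_idx = rep(1:2, c(30, 10)))
  hp <- heritability(f2, "pooled", test = FALSE)
  expect_equal(hp$H2, 0.75 * 0.25 + 0.25 * 0.3)
})

test_that("delta-method SE agrees with a numeric-gradient recomputation", {
  res <- recover_heritability_single(18, 90, true_h2 = 0.35, n_snps = 1200,
                                     seed = 5)
  fit <- res$fit
  nm <- c("gvar_s1", "svar_s1", "nugget_s1")
  # mirror the reporting policy: components pinned at zero are fixed, so
  # they drop out of the gradient
  nm <- nm[!fit$boundary[nm]]
  idx <- match(nm, fit$spec$names)
  phi_all <- fit$estimates[c("gvar_s1", "svar_s1", "nugget_s1")]
  h_of <- function(phi) {
    full <- phi_all; full[nm] <- phi
    full["gvar_s1"] / sum(full)
  }
  phi <- fit$estimates[nm]
  eps <- 1e-6
  grad <- sapply(seq_along(phi), function(j) {
    up <- phi; up[j] <- up[j] + eps
    dn <- phi; dn[j] <- dn[j] - eps
    (h_of(up) - h_of(dn)) / (2 * eps)
  })
  se_num <- sqrt(drop(t(grad) %*% fit$vcov[idx, idx, drop = FALSE] %*% grad))
  expect_equal(res$se, se_num, tolerance = 1e-2)
})

test_that("type B correlation arithmetic, boundary and degenerate cases", {
  f <- fake_fit(c(gvar_s1 = 2, gvar_s2 = 0.5, gcov = 0.72,
                  nugget_s1 = 1, nugget_s2 = 1),
                n_sites = 2L, include_spatial = FALSE)
  tb <- type_b_correlation(f, test = FALSE)
  expect_equal(tb$value, 0.72)
  expect_false(tb$boundary)
  fb <- fake_fit(c(gvar_s1 = 1, gvar_s2 = 4, gcov = 2,
                   nugget_s1 = 1, nugget_s2 = 1),
                 n_sites = 2L, include_spatial = FALSE)
  tbb <- type_b_correlation(fb, test = FALSE)
  expect_equal(tbb$value, 1)
  expect_true(tbb$boundary)
  expect_true(is.na(tbb$se))
  f0 <- fake_fit(c(gvar_s1 = 1, gvar_s2 = 1, gcov = 0,
                   nugget_s1 = 1, nugget_s2 = 1),
                 n_sites = 2L, include_spatial = FALSE)
  expect_equal(type_b_correlation(f0, test = FALSE)$value, 0)
  fz <- fake_fit(c(gvar_s1 = 0, gvar_s2 = 1, gcov = 0,
                   nugget_s1 = 1, nugget_s2 = 1),
                 n_sites = 2L, include_spatial = FALSE)
  fz$boundary["gvar_s1"] <- TRUE
  expect_true(type_b_correlation(fz, test = FALSE)$undefined)
})

test_that("a trait paired with itself sits at the correlation boundary", {
  K <- test_grm(15, n_snps = 800, seed = 71)
  qs <- quick_study(n_clones = 15, n_ramets = 75, h2 = 0.5,
                    spatial = FALSE, seed = 72, K = K)
  ph <- qs$study$phenotypes
  ph$y1 <- ph$y; ph$y2 <- ph$y
  md <- model_data_bivariate(ph, c("y1", "y2"), K)
  ce <- trait_pair_correlation(md, "type_A", test = FALSE)
  expect_gt(ce$value, 0.99)
  expect_true(ce$boundary)
  expect_true(is.na(ce$se))
})

test_that("swapping the two sites leaves type B unchanged", {
  rep1 <- recover_two_site(n_clones = c(14, 12), shared = 9,
                           ramets = c(70, 60), per_site_h2 = 0.35,
                           r_gen = 0.7, n_snps = 1200, seed = 81,
                           single_site_fits = FALSE)
  # relabel the sites and refit
  fit <- rep1$fit
  ph <- as.data.frame(fit$data$design)
  ph$y <- fit$data$y
  ph$site <- 3L - ph$site
  fit_sw <- fit_reml(model_data(ph, "y", fit$data$K),
                     control = list(restarts = 0))
  tb1 <- type_b_correlation(fit, test = FALSE)
  tb2 <- type_b_correlation(fit_sw, test = FALSE)
  expect_equal(tb1$value, tb2$value, tolerance = 5e-3)
  if (!is.na(tb1$se) && !is.na(tb2$se))
    expect_equal(tb1$se, tb2$se, tolerance = 0.05)
})

test_that("wavelength scans are complete, deterministic, flat under a
           shared genetic signal, and collapse under permutation", {
  K <- test_grm(22, n_snps = 1000, seed = 91)
  cfg <- sim_config(n_clones = 22, ramets_per_site = 88, n_bands = 6,
                    band_correlation_length = 1e6, band_h2 = 0.4, seed = 92)
  design <- simulate_orchard_design(cfg)
  sp <- simulate_spectra(design, K, cfg)
  tab <- wavelength_scan(sp, design, K, include_spatial = FALSE,
                         test = FALSE)
  expect_equal(nrow(tab), 6L)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$H2 >= 0 & tab$H2 <= 1))
  # one shared genetic signal: per-band H2 varies only through band noise
  expect_lt(max(tab$H2) - min(tab$H2), 0.25)
  tab2 <- wavelength_scan(sp, design, K, include_spatial = FALSE,
                          test = FALSE)
  expect_identical(tab, tab2)
  # permuting clone labels breaks the genotype-phenotype link
  design_perm <- design
  design_perm$clone <- sample(design$clone)
  tab_perm <- wavelength_scan(sp, design_perm, K, include_spatial = FALSE,
                              test = FALSE)
  expect_lt(median(tab_perm$H2), median(tab$H2))
  expect_lt(median(tab_perm$H2), 0.1)
})

test_that("single-band correlation tables have one row and sane columns", {
  K <- test_grm(15, n_snps = 800, seed = 93)
  cfg <- sim_config(n_clones = 15, ramets_per_site = 60, n_bands = 2,
                    band_correlation_length = 5, band_h2 = 0.5, seed = 94)
  design <- simulate_orchard_design(cfg)
  sp <- simulate_spectra(design, K, cfg)
  one_band <- spectra_table(sp$ramet_ids, sp$wavelengths[1],
                            sp$reflectance[, 1, drop = FALSE])
  nft <- data.frame(ramet = design$ramet,
                    EWT = sp$reflectance[, 2] * 3 + rnorm(60, 0, 0.01))
  tab <- correlation_with_nft(one_band, nft, "EWT", design, K, test = FALSE)
  expect_equal(nrow(tab), 1L)
  expect_true(all(c("wavelength", "correlation", "se", "p_value") %in%
                    names(tab)))
  expect_true(is.na(tab$error) || abs(tab$correlation) <= 1)
})
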