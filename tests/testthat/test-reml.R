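# The REML engine: likelihood correctness, invariances, fitting, LRT, BLUPs.

test_that("restricted likelihood reduces to the iid closed form", {
  set.seed(4)
  n <- 25
  y <- rnorm(n, 3, 1.7)
  d <- data.frame(site = 1, row = 1:n, col = 1, clone = rep(1:5, 5))
  ph <- d; ph$y <- y
  md <- model_data(ph, "y", diag(5))
  s2 <- 1.3
  ll <- restricted_loglik(md, genetic_covariance(0),
                          residual_covariance(0, 0, 0, s2))
  S <- sum((y - mean(y))^2)
  ll_closed <- -0.5 * ((n - 1) * log(2 * pi * s2) + log(n) + S / s2)
  expect_equal(ll, ll_closed, tolerance = 1e-10)
})

test_that("restricted likelihood is invariant to fixed-effect translations
           and ramet permutations", {
  qs <- quick_study(n_clones = 8, n_ramets = 30, seed = 21)
  ph <- qs$study$phenotypes
  md <- model_data(ph, "y", qs$K)
  g <- genetic_covariance(0.4)
  r <- residual_covariance(0.3, 0.35, 0.5, 0.25)
  ll <- restricted_loglik(md, g, r)
  ph2 <- ph; ph2$y <- ph2$y + 17.3       # shift along the intercept column
  expect_equal(restricted_loglik(model_data(ph2, "y", qs$K), g, r), ll,
               tolerance = 1e-8)
  perm <- sample(nrow(ph))
  expect_equal(restricted_loglik(model_data(ph[perm, ], "y", qs$K), g, r),
               ll, tolerance = 1e-8)
})

test_that("restricted likelihood equals the naive from-definition oracle
           across randomized instances", {
  set.seed(9)
  K <- test_grm(6, n_snps = 300, seed = 77)
  for (i in 1:10) {
    n <- sample(10:30, 1)
    d <- data.frame(site = 1, row = sample(1:8, n, TRUE),
                    col = rep(1:n))  # distinct cells via unique cols
    d$clone <- sample(1:6, n, TRUE)
    ph <- d; ph$y <- rnorm(n)
    md <- model_data(ph, "y", K)
    g <- genetic_covariance(runif(1, 0.05, 1))
    r <- residual_covariance(runif(1, 0, 1), runif(1, -0.8, 0.8),
                             runif(1, -0.8, 0.8), runif(1, 0.1, 1))
    V <- assemble_genetic_covariance(matrix(g$variances), K)[
      md$u_idx, md$u_idx] +
      assemble_residual_covariance(d, r$spatial_variance, r$rho_col,
                                   r$rho_row, r$nugget)
    expect_equal(restricted_loglik(md, g, r),
                 naive_reml_loglik(md$y, md$X, V), tolerance = 1e-8)
  }
})

test_that("zero spatial correlation collapses onto the nugget-only model", {
  qs <- quick_study(n_clones = 8, n_ramets = 30, seed = 22)
  md <- model_data(qs$study$phenotypes, "y", qs$K)
  g <- genetic_covariance(0.3)
  ll_split <- restricted_loglik(md, g, residual_covariance(0.4, 0, 0, 0.2))
  ll_merged <- restricted_loglik(md, g, residual_covariance(0, 0, 0, 0.6))
  expect_equal(ll_split, ll_merged, tolerance = 1e-9)
})

test_that("the rotated bivariate likelihood equals the dense evaluation", {
  K <- test_grm(7, n_snps = 300, seed = 55)
  cfg <- sim_config(n_clones = 7, ramets_per_site = 24, seed = 12)
  d <- simulate_orchard_design(cfg)
  tp <- simulate_trait_pair(d, K, gvar = c(0.3, 0.5), gcor = 0.6,
                            evar = c(0.7, 0.4), ecor = 0.2, seed = 13)
  md <- model_data_bivariate(tp$phenotypes, c("y1", "y2"), K)
  rs <- orchardspec:::rotated_setup(md)
  for (i in 1:5) {
    set.seed(100 + i)
    ga <- runif(2, 0.05, 0.8); gc <- runif(1, -0.9, 0.9) * sqrt(prod(ga))
    ev <- runif(2, 0.2, 1); ec <- runif(1, -0.8, 0.8) * sqrt(prod(ev))
    dense <- restricted_loglik(md, genetic_covariance(ga, gc),
                               residual_covariance_bivariate(ev, ec))
    rot <- orchardspec:::rotated_loglik(rs, ga[1], ga[2], gc,
                                        ev[1], ev[2], ec)
    expect_equal(rot, dense, tolerance = 1e-8)
  }
})

test_that("a bivariate model with zero covariances separates into the two
           univariate likelihoods", {
  K <- test_grm(6, n_snps = 300, seed = 56)
  cfg <- sim_config(n_clones = 6, ramets_per_site = 20, seed = 14)
  d <- simulate_orchard_design(cfg)
  tp <- simulate_trait_pair(d, K, gvar = c(0.4, 0.3), gcor = 0.5,
                            evar = c(0.6, 0.5), ecor = 0.1, seed = 15)
  md2 <- model_data_bivariate(tp$phenotypes, c("y1", "y2"), K)
  ll_biv <- restricted_loglik(md2, genetic_covariance(c(0.4, 0.3), 0),
                              residual_covariance_bivariate(c(0.6, 0.5), 0))
  ll_uni <- 0
  for (tr in c("y1", "y2")) {
    md1 <- model_data(tp$phenotypes, tr, K)
    gv <- if (tr == "y1") 0.4 else 0.3
    ev <- if (tr == "y1") 0.6 else 0.5
    ll_uni <- ll_uni + restricted_loglik(md1, genetic_covariance(gv),
                                         residual_covariance(0, 0, 0, ev))
  }
  expect_equal(ll_biv, ll_uni, tolerance = 1e-6)
})

test_that("REML estimates on toy data match a grid + polish oracle", {
  K <- test_grm(10, n_snps = 600, seed = 61)
  cfg <- sim_config(n_clones = 10, ramets_per_site = 20,
                    genetic_variance = 0.5, spatial_variance = 0,
                    nugget = 0.5, seed = 23)
  d <- simulate_orchard_design(cfg)
  st <- simulate_phenotypes(d, K, cfg)
  md <- model_data(st$phenotypes, "y", K)
  fit <- fit_reml(md, include_spatial = FALSE)
  # oracle: coarse grid over (log gvar, log nugget), then Nelder-Mead on
  # the naive dense likelihood
  obj <- function(lp) {
    V <- exp(lp[1]) * K$values[md$clone_map, md$clone_map] +
      exp(lp[2]) * diag(length(md$y))
    -naive_reml_loglik(md$y, md$X, V)
  }
  grid <- as.matrix(expand.grid(seq(-4, 1, 0.5), seq(-4, 1, 0.5)))
  v0 <- grid[which.min(apply(grid, 1, obj)), ]
  polish <- optim(v0, obj, method = "Nelder-Mead",
                  control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$estimates["gvar_s1"]),
               unname(exp(polish$par[1])), tolerance = 2e-3)
  expect_equal(unname(fit$estimates["nugget_s1"]),
               unname(exp(polish$par[2])), tolerance = 2e-3)
  expect_equal(fit$loglik, -polish$value, tolerance = 1e-6)
})

test_that("near-zero genetic variance lands on the boundary with a
           non-significant LRT", {
  K <- diag(40)
  cfg <- sim_config(n_clones = 40, ramets_per_site = 160,
                    genetic_variance = 0, spatial_variance = 0,
                    nugget = 1, seed = 31)
  d <- simulate_orchard_design(cfg)
  st <- simulate_phenotypes(d, K, cfg)
  md <- model_data(st$phenotypes, "y", K)
  full <- fit_reml(md, include_spatial = FALSE, control = list(restarts = 0))
  null <- fit_reml(md, include_spatial = FALSE, genetic = FALSE)
  out <- lrt(full, null, "variance_on_boundary")
  expect_lt(full$estimates["gvar_s1"], 0.05)
  expect_gt(out$p_value, 0.05)
})

test_that("the boundary-mixture and chi-square LRT references give textbook
           p-values", {
  expect_equal(lrt(-100, -100, "variance_on_boundary")$statistic, 0)
  expect_equal(lrt(-100, -100, "variance_on_boundary")$p_value, 1)
  expect_equal(lrt(-100, -100 - 2.71 / 2, "variance_on_boundary")$p_value,
               0.05, tolerance = 5e-3)
  expect_equal(lrt(-100, -100 - 3.84 / 2, "covariance_zero")$p_value,
               0.05, tolerance = 5e-3)
  expect_error(lrt(-105, -100, "covariance_zero"), "optimizer")
})

test_that("BLUPs match the direct mixed-model formula", {
  K <- test_grm(5, n_snps = 300, seed = 62)
  cfg <- sim_config(n_clones = 5, ramets_per_site = 18,
                    genetic_variance = 0.5, spatial_variance = 0,
                    nugget = 0.5, seed = 41)
  d <- simulate_orchard_design(cfg)
  st <- simulate_phenotypes(d, K, cfg)
  md <- model_data(st$phenotypes, "y", K)
  g <- genetic_covariance(0.45)
  r <- residual_covariance(0, 0, 0, 0.55)
  u <- orchardspec:::compute_blups(md, g, r)
  # direct dense formula: u = G Z' V^-1 (y - X beta_gls)
  G <- 0.45 * K$values
  Z <- matrix(0, length(md$y), 5)
  Z[cbind(seq_along(md$y), md$clone_map)] <- 1
  V <- Z %*% G %*% t(Z) + 0.55 * diag(length(md$y))
  Vi <- solve(V)
  X <- md$X
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% md$y)
  u_direct <- G %*% t(Z) %*% Vi %*% (md$y - X %*% beta)
  expect_equal(unname(u[, 1]), unname(drop(u_direct)), tolerance = 1e-6)
})

test_that("clonal rankings sort by BLUP and flag zero-variance fits", {
  K <- test_grm(12, n_snps = 500, seed = 63)
  qs <- quick_study(n_clones = 12, n_ramets = 60, h2 = 0.5,
                    spatial = FALSE, seed = 43, K = K)
  fit <- fit_reml(model_data(qs$study$phenotypes, "y", K),
                  include_spatial = FALSE)
  rk <- clonal_rankings(fit)
  r1 <- rk$rankings[[1]]
  expect_true(all(diff(r1$blup) <= 1e-12))
  expect_false(rk$non_informative)
  # with the genotype-phenotype link broken, variance hits the boundary
  ph <- qs$study$phenotypes
  set.seed(1); ph$y <- rnorm(nrow(ph))
  fit0 <- fit_reml(model_data(ph, "y", K), include_spatial = FALSE,
                   control = list(restarts = 0))
  if (fit0$boundary["gvar_s1"]) {
    expect_true(clonal_rankings(fit0)$non_informative)
  }
})

test_that("fits are reproducible and spatial parameters are recovered on a
           larger field", {
  res <- recover_heritability_single(25, 150, true_h2 = 0.35,
                                     n_snps = 1500, seed = 99)
  res2 <- recover_heritability_single(25, 150, true_h2 = 0.35,
                                      n_snps = 1500, seed = 99)
  expect_identical(res$h2, res2$h2)
  expect_true(res$h2 >= 0 && res$h2 <= 1)
  expect_true(is.finite(res$fit$loglik))
})
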