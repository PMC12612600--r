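# Phenotype, trait-pair and spectra generators: the generative inverse of the
# genomic mixed models fitted downstream. Clone values are drawn from
# N(0, Sigma_site (x) K), spatial residuals from a separable AR1 x AR1 field
# realized exactly through the covariance square root on the full grid, and
# the nugget independently per ramet.

# Symmetric square root via eigendecomposition; errors if meaningfully
# non-PSD, clamps harmless negative round-off.
mat_sqrt <- function(M, label = "covariance") {
  e <- eigen(M, symmetric = TRUE)
  tol <- -1e-8 * max(abs(e$values), 1)
  if (min(e$values) < tol)
    stop_bad_arg(label, " is not positive semi-definite (min eigenvalue ",
                 format(min(e$values)), ")")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

site_gen_cov <- function(gvar, r) {
  sd <- sqrt(gvar)
  n <- length(gvar)
  C <- diag(1, n)
  if (n == 2L) C[1, 2] <- C[2, 1] <- r
  (sd %o% sd) * C
}

# Draw clone-by-group matrix U with cov(vec(U)) = Sigma (x) K.
draw_clone_values <- function(K, Sigma) {
  A <- mat_sqrt(K, "GRM")
  B <- mat_sqrt(Sigma, "genetic group covariance")
  N <- matrix(stats::rnorm(nrow(K) * nrow(Sigma)), nrow(K), nrow(Sigma))
  A %*% N %*% t(B)
}

# Exact draw of a separable AR1 x AR1 field on the full grid, subset to the
# occupied cells of one site.
draw_spatial_field <- function(rows, cols, n_rows, n_cols, rho_row, rho_col) {
  Crow <- ar1_correlation(rho_row, seq_len(n_rows))
  Ccol <- ar1_correlation(rho_col, seq_len(n_cols))
  Lr <- mat_sqrt(Crow, "AR1 row correlation")
  Lc <- mat_sqrt(Ccol, "AR1 column correlation")
  field <- Lr %*% matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols) %*% t(Lc)
  field[cbind(rows, cols)]
}

grm_for_design <- function(grm, design) {
  K <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  n_clones <- max(design$clone)
  if (nrow(K) < n_clones)
    stop_bad_arg("GRM dimension ", nrow(K), " smaller than number of clones ",
                 n_clones, " in the design")
  K[seq_len(n_clones), seq_len(n_clones), drop = FALSE]
}

#' Simulate ramet phenotypes under the genomic mixed model
#'
#' Each ramet's value decomposes exactly as overall mean + site effect +
#' population-within-site effect + clone genetic value + spatial residual +
#' nugget; every component is stored so the decomposition can be checked.
#' Clone values across sites follow `N(0, Sigma (x) K)` where `Sigma` holds
#' the per-site genetic variances and their covariance and `K` is the
#' genomic relationship matrix.
#'
#' @param design an `orchard_design`.
#' @param grm a `grm` (or plain matrix) over at least the design's clones.
#' @param config a [sim_config()] supplying variance components and fixed
#'   effects.
#' @param seed integer; defaults to a stream derived from `config$seed`.
#' @param trait_name column name for the phenotype.
#' @return a `sim_study` list: `design`, `phenotypes` (design columns plus
#'   the trait), `true_clonal_values` (clone x site), `truth` (config and the
#'   realized spatial/nugget components).
#' @export
simulate_phenotypes <- function(design, grm, config,
                                seed = NULL, trait_name = "y") {
  validate_design(design)
  stopifnot(inherits(config, "sim_config"))
  K <- grm_for_design(grm, design)
  Sigma <- site_gen_cov(config$genetic_variance,
                        config$cross_site_genetic_correlation)
  if (is.null(seed)) seed <- derive_seed(config$seed, 2L)
  with_seed(seed, {
    U <- draw_clone_values(K, Sigma)
    n <- nrow(design)
    spatial <- numeric(n)
    for (s in seq_len(config$n_sites)) {
      idx <- which(design$site == s)
      if (!length(idx)) next
      if (config$spatial_variance[s] > 0) {
        f <- draw_spatial_field(design$row[idx], design$col[idx],
                                config$grid_rows[s], config$grid_cols[s],
                                config$rho_row[s], config$rho_col[s])
        spatial[idx] <- sqrt(config$spatial_variance[s]) * f
      }
    }
    nugget <- stats::rnorm(n) * sqrt(config$nugget[design$site])
    pop <- design$population %||% rep(1L, n)
    fixed <- config$mean + config$site_effects[design$site] +
      config$pop_effects[cbind(pop, design$site)]
    genetic <- U[cbind(design$clone, design$site)]
    phen <- as.data.frame(design)
    phen[[trait_name]] <- fixed + genetic + spatial + nugget
    structure(list(
      design = design,
      phenotypes = phen,
      true_clonal_values = U,
      truth = list(config = config, fixed = fixed, genetic = genetic,
                   spatial = spatial, nugget = nugget)),
      class = "sim_study")
  })
}

#' Simulate two correlated responses on the same ramets
#'
#' A bivariate generator for trait-pair studies: the same trait in two years,
#' or two different traits, measured on every ramet. Clone values follow
#' `N(0, Sigma_a (x) K)` with genetic correlation `gcor`; residuals are
#' bivariate normal per ramet with correlation `ecor` (no spatial field, as
#' in the bivariate model's identity-residual structure).
#'
#' @param design an `orchard_design` (single- or multi-site; sites only
#'   contribute a fixed effect here).
#' @param grm a `grm` or matrix over the design's clones.
#' @param gvar length-2 genetic variances; `gcor` genetic correlation.
#' @param evar length-2 residual variances; `ecor` residual correlation.
#' @param mean length-2 per-response means.
#' @param seed integer seed.
#' @return a `sim_study` with `phenotypes` containing `y1`, `y2` and
#'   `true_clonal_values` clone x 2.
#' @export
simulate_trait_pair <- function(design, grm, gvar, gcor, evar, ecor,
                                mean = c(10, 10), seed = 1L) {
  validate_design(design)
  if (any(gvar < 0) || any(evar < 0) || abs(gcor) > 1 || abs(ecor) > 1)
    stop_bad_arg("invalid variance/correlation parameters")
  K <- grm_for_design(grm, design)
  Sa <- site_gen_cov(gvar, gcor)
  Se <- site_gen_cov(evar, ecor)
  with_seed(seed, {
    U <- draw_clone_values(K, Sa)
    n <- nrow(design)
    E <- matrix(stats::rnorm(2 * n), n, 2) %*% t(mat_sqrt(Se, "residual covariance"))
    phen <- as.data.frame(design)
    phen$y1 <- mean[1] + U[design$clone, 1] + E[, 1]
    phen$y2 <- mean[2] + U[design$clone, 2] + E[, 2]
    structure(list(design = design, phenotypes = phen,
                   true_clonal_values = U,
                   truth = list(gvar = gvar, gcor = gcor,
                                evar = evar, ecor = ecor, residuals = E)),
              class = "sim_study")
  })
}

#' Simulate a hyperspectral reflectance table with band-smooth genetics
#'
#' Per-band phenotypes are generated as in [simulate_phenotypes()] (without a
#' spatial field), with the genetic signal correlated across bands through a
#' Gaussian kernel in band distance: adjacent wavelengths share almost the
#' same genetic basis, distant ones decay towards independence. In the
#' infinite-bandwidth limit all bands carry a single genetic signal.
#'
#' @param design an `orchard_design`.
#' @param grm a `grm` or matrix.
#' @param config a [sim_config()] with `n_bands >= 2`,
#'   `band_correlation_length > 0` and `band_h2`.
#' @param wavelengths optional nm grid (default 400 + 2*(0:(n_bands-1))).
#' @param total_variance per-band phenotypic variance in reflectance
#'   units^2 (default 0.004, i.e. SD ~6 percentage points of reflectance).
#' @param base_level mean reflectance level (default 0.45).
#' @param seed integer seed.
#' @return a `spectra_table`.
#' @export
simulate_spectra <- function(design, grm, config, wavelengths = NULL,
                             total_variance = 0.004, base_level = 0.45,
                             seed = NULL) {
  validate_design(design)
  stopifnot(inherits(config, "sim_config"))
  B <- config$n_bands
  if (B < 2L) stop_bad_arg("'n_bands' must be >= 2 for spectra simulation")
  if (config$band_correlation_length <= 0)
    stop_bad_arg("'band_correlation_length' must be > 0")
  if (is.null(wavelengths)) wavelengths <- 400 + 2 * (seq_len(B) - 1)
  if (length(wavelengths) != B || is.unsorted(wavelengths, strictly = TRUE))
    stop_bad_arg("'wavelengths' must be strictly increasing, one per band")
  K <- grm_for_design(grm, design)
  gvar <- config$band_h2 * total_variance
  evar <- (1 - config$band_h2) * total_variance
  d <- outer(seq_len(B), seq_len(B), "-")
  Cb <- gvar * exp(-(d^2) / (2 * config$band_correlation_length^2))
  if (is.null(seed)) seed <- derive_seed(config$seed, 3L)
  with_seed(seed, {
    U <- draw_clone_values(K, Cb)                       # clones x bands
    n <- nrow(design)
    E <- matrix(stats::rnorm(n * B, sd = sqrt(evar)), n, B)
    refl <- base_level + U[design$clone, , drop = FALSE] + E
    spectra_table(design$ramet %||% seq_len(n), wavelengths, refl,
                  level = "canopy")
  })
}
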