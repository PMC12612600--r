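#' Simulation configuration for a synthetic clonal seed orchard study
#'
#' Collects every generative parameter of the synthetic orchard: layout
#' (clones, ramets, row/column grids per site), marker panel, fixed effects,
#' per-site genetic variances with a cross-site genetic correlation, and the
#' spatially autocorrelated plus independent ("nugget") residual structure
#' that field-trial models assume.
#'
#' @param n_clones number of distinct genotypes (clones).
#' @param n_sites number of sites, 1 or 2.
#' @param ramets_per_site integer vector (length `n_sites`): total ramets
#'   planted per site. Ramets are allocated to clones as evenly as possible,
#'   mimicking "up to k ramets per clone" sampling.
#' @param clones_per_site optional list of clone indices present at each
#'   site; defaults to all clones at every site. Overlap between sites
#'   controls how much information the cross-site genetic correlation has.
#' @param grid_rows,grid_cols integer vectors (length `n_sites`): planting
#'   grid dimensions; `grid_rows * grid_cols` must cover the site's ramets.
#' @param n_snps number of biallelic SNPs on the simulated array.
#' @param maf_distribution either a pair of Beta shape parameters for allele
#'   frequencies (rescaled to (0.02, 0.5)) or a single frequency in (0, 1)
#'   used for every SNP.
#' @param n_populations number of source populations for the clones;
#'   populations shift allele frequencies (Balding-Nichols style) and may
#'   carry fixed effects.
#' @param pop_fst differentiation parameter for population allele-frequency
#'   shifts (ignored when `n_populations == 1`).
#' @param mean overall trait mean.
#' @param site_effects fixed site effects (length `n_sites`).
#' @param pop_effects fixed population-within-site effects: matrix
#'   `n_populations x n_sites`, or 0.
#' @param genetic_variance per-site additive-genetic variance (trait units^2).
#' @param cross_site_genetic_correlation genetic correlation of clone values
#'   between the two sites, in \[-1, 1\].
#' @param spatial_variance per-site variance of the spatially dependent
#'   residual field.
#' @param rho_col,rho_row per-site first-order autoregressive correlations in
#'   the column and row directions, each in (-1, 1).
#' @param nugget per-site independent residual (nugget) variance; never zero
#'   in fitted models, may be zero in simulation.
#' @param n_bands number of spectral bands for reflectance simulation.
#' @param band_correlation_length bandwidth (in band-index units) of the
#'   Gaussian kernel governing how smoothly the genetic signal varies across
#'   wavelengths; larger values mean adjacent bands share more genetic signal.
#' @param band_h2 per-band heritability used when simulating spectra.
#' @param seed single integer; all sub-generators derive their streams
#'   from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_clones,
                       n_sites = 1L,
                       ramets_per_site = n_clones * 4L,
                       clones_per_site = NULL,
                       grid_rows = NULL,
                       grid_cols = NULL,
                       n_snps = 5000L,
                       maf_distribution = c(0.5, 0.5),
                       n_populations = 1L,
                       pop_fst = 0.02,
                       mean = 10,
                       site_effects = rep(0, n_sites),
                       pop_effects = 0,
                       genetic_variance = rep(0.3, n_sites),
                       cross_site_genetic_correlation = 0.9,
                       spatial_variance = rep(0.35, n_sites),
                       rho_col = rep(0.5, n_sites),
                       rho_row = rep(0.5, n_sites),
                       nugget = rep(0.35, n_sites),
                       n_bands = 0L,
                       band_correlation_length = 20,
                       band_h2 = 0.25,
                       seed = 1L) {
  n_clones <- check_scalar_count(n_clones, "n_clones", min = 1L)
  n_sites <- check_scalar_count(n_sites, "n_sites", min = 1L)
  if (n_sites > 2L) stop_bad_arg("'n_sites' must be 1 or 2")
  ramets_per_site <- as.integer(rep_len(ramets_per_site, n_sites))
  if (any(ramets_per_site < 1L)) stop_bad_arg("each site needs >= 1 ramet")
  if (is.null(clones_per_site)) clones_per_site <- rep(list(seq_len(n_clones)), n_sites)
  if (length(clones_per_site) != n_sites)
    stop_bad_arg("'clones_per_site' must have one entry per site")
  for (s in seq_len(n_sites)) {
    cl <- clones_per_site[[s]]
    if (anyDuplicated(cl) || any(cl < 1L) || any(cl > n_clones))
      stop_bad_arg("invalid clone indices in 'clones_per_site'")
  }
  if (is.null(grid_rows)) grid_rows <- ceiling(sqrt(ramets_per_site * 1.1))
  if (is.null(grid_cols)) grid_cols <- ceiling(ramets_per_site * 1.1 / grid_rows)
  grid_rows <- as.integer(rep_len(grid_rows, n_sites))
  grid_cols <- as.integer(rep_len(grid_cols, n_sites))
  if (any(grid_rows * grid_cols < ramets_per_site))
    stop_bad_arg(sprintf(
      "grid capacity exceeded at site %s: %d cells < %d ramets",
      paste(which(grid_rows * grid_cols < ramets_per_site), collapse = ","),
      min((grid_rows * grid_cols)[grid_rows * grid_cols < ramets_per_site]),
      max(ramets_per_site[grid_rows * grid_cols < ramets_per_site])))
  n_snps <- check_scalar_count(n_snps, "n_snps", min = 1L)
  n_populations <- check_scalar_count(n_populations, "n_populations", min = 1L)
  if (!length(maf_distribution) %in% c(1L, 2L) || any(maf_distribution <= 0))
    stop_bad_arg("'maf_distribution' must be one fixed frequency or two positive shapes")
  if (length(maf_distribution) == 1L && maf_distribution >= 1)
    stop_bad_arg("a fixed allele frequency must lie in (0, 1)")
  genetic_variance <- rep_len(as.numeric(genetic_variance), n_sites)
  spatial_variance <- rep_len(as.numeric(spatial_variance), n_sites)
  nugget <- rep_len(as.numeric(nugget), n_sites)
  if (any(c(genetic_variance, spatial_variance, nugget) < 0))
    stop_bad_arg("variances must be >= 0")
  if (abs(cross_site_genetic_correlation) > 1)
    stop_bad_arg("'cross_site_genetic_correlation' must lie in [-1, 1]")
  rho_col <- rep_len(as.numeric(rho_col), n_sites)
  rho_row <- rep_len(as.numeric(rho_row), n_sites)
  if (any(abs(c(rho_col, rho_row)) >= 1))
    stop_bad_arg("spatial AR1 correlations must lie in (-1, 1)")
  site_effects <- rep_len(as.numeric(site_effects), n_sites)
  if (is.matrix(pop_effects)) {
    if (nrow(pop_effects) != n_populations || ncol(pop_effects) != n_sites)
      stop_bad_arg("'pop_effects' matrix must be n_populations x n_sites")
  } else {
    pop_effects <- matrix(rep_len(as.numeric(pop_effects), n_populations * n_sites),
                          n_populations, n_sites)
  }
  if (n_bands > 0 && band_correlation_length <= 0)
    stop_bad_arg("'band_correlation_length' must be > 0")
  structure(list(
    n_clones = n_clones, n_sites = n_sites,
    ramets_per_site = ramets_per_site, clones_per_site = clones_per_site,
    grid_rows = grid_rows, grid_cols = grid_cols,
    n_snps = n_snps, maf_distribution = as.numeric(maf_distribution),
    n_populations = n_populations, pop_fst = pop_fst,
    mean = mean, site_effects = site_effects, pop_effects = pop_effects,
    genetic_variance = genetic_variance,
    cross_site_genetic_correlation = cross_site_genetic_correlation,
    spatial_variance = spatial_variance,
    rho_col = rho_col, rho_row = rho_row, nugget = nugget,
    n_bands = as.integer(n_bands),
    band_correlation_length = band_correlation_length,
    band_h2 = band_h2,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Orchard simulation config: %d clones, %d site(s), %s ramets\n",
              x$n_clones, x$n_sites, paste(x$ramets_per_site, collapse = "+")))
  cat(sprintf("  genetic variance %s, cross-site r = %.2f\n",
              paste(format(x$genetic_variance), collapse = "/"),
              x$cross_site_genetic_correlation))
  cat(sprintf("  spatial %s (rho col/row %s / %s), nugget %s, seed %d\n",
              paste(format(x$spatial_variance), collapse = "/"),
              paste(format(x$rho_col), collapse = "/"),
              paste(format(x$rho_row), collapse = "/"),
              paste(format(x$nugget), collapse = "/"), x$seed))
  invisible(x)
}
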