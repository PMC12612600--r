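# Covariance structure assembly for the genomic mixed models.

#' First-order autoregressive correlation matrix
#'
#' Entry (i, j) equals `rho^|coord_i - coord_j|`; unit diagonal. For
#' consecutive coordinates 1..n the determinant has the closed form
#' `(1 - rho^2)^(n-1)`.
#'
#' @param rho autocorrelation in (-1, 1).
#' @param coords integer positions (need not be consecutive; gaps from
#'   mortality simply enter through larger lags).
#' @return correlation matrix.
#' @export
ar1_correlation <- function(rho, coords) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop_bad_arg("'rho' must lie in (-1, 1)")
  if (any(!is.finite(coords)) || any(coords != floor(coords)))
    stop_bad_arg("'coords' must be finite integers")
  rho^abs(outer(coords, coords, "-"))
}

#' Genetic covariance of clone-by-group effects
#'
#' Kronecker product of the small group covariance (sites, traits or years)
#' with the genomic relationship matrix: effect (g, clone) x (g', clone')
#' covariance is `Sigma[g, g'] * K[clone, clone']`. Group index varies
#' slowest.
#'
#' @param sigma group covariance matrix (1x1 or 2x2): variances on the
#'   diagonal, genetic covariance off it.
#' @param K a `grm` or plain relationship matrix.
#' @return covariance matrix of dimension `nrow(sigma) * n_clones`.
#' @export
assemble_genetic_covariance <- function(sigma, K) {
  sigma <- as.matrix(sigma)
  if (any(diag(sigma) < 0)) stop_bad_arg("genetic variances must be >= 0")
  if (nrow(sigma) == 2L) {
    den <- sqrt(prod(diag(sigma)))
    if (den > 0 && abs(sigma[1, 2] / den) > 1 + 1e-8)
      stop_bad_arg("implied genetic correlation outside [-1, 1]")
  }
  Kv <- if (inherits(K, "grm")) K$values else as.matrix(K)
  kronecker(sigma, Kv)
}

#' Spatial plus nugget residual covariance over ramets
#'
#' Within each site, entry (a, b) is
#' `spatial_variance * rho_col^|col_a - col_b| * rho_row^|row_a - row_b|`
#' plus the nugget on the diagonal; ramets in different sites have zero
#' residual covariance (block-diagonal by site).
#'
#' @param design an `orchard_design` (or data.frame with site/row/col).
#' @param spatial_variance,rho_col,rho_row,nugget per-site parameters
#'   (recycled across sites).
#' @return residual covariance matrix in the design's row order.
#' @export
assemble_residual_covariance <- function(design, spatial_variance,
                                         rho_col, rho_row, nugget) {
  validate_design(design)
  sites <- sort(unique(design$site))
  ns <- length(sites)
  spatial_variance <- rep_len(spatial_variance, ns)
  rho_col <- rep_len(rho_col, ns)
  rho_row <- rep_len(rho_row, ns)
  nugget <- rep_len(nugget, ns)
  if (any(c(spatial_variance, nugget) < 0) || any(abs(c(rho_col, rho_row)) >= 1))
    stop_bad_arg("invalid residual parameters")
  n <- nrow(design)
  R <- matrix(0, n, n)
  for (k in seq_along(sites)) {
    idx <- which(design$site == sites[k])
    if (spatial_variance[k] > 0) {
      Cc <- rho_col[k]^abs(outer(design$col[idx], design$col[idx], "-"))
      Cr <- rho_row[k]^abs(outer(design$row[idx], design$row[idx], "-"))
      R[idx, idx] <- spatial_variance[k] * Cc * Cr
    }
    R[cbind(idx, idx)] <- R[cbind(idx, idx)] + nugget[k]
  }
  R
}
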