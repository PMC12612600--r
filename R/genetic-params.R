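# Heritabilities, genetic correlations and per-wavelength scans derived
# from fitted variance components.

# Delta-method SE of f(phi) given gradient and the parameter covariance.
delta_se <- function(grad, vcov, idx) {
  if (any(is.na(vcov[idx, idx]))) return(NA_real_)
  v <- drop(t(grad) %*% vcov[idx, idx, drop = FALSE] %*% grad)
  if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
}

#' Broad-sense heritability from a fitted genomic mixed model
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_spatial + sigma2_nugget)` for the
#' requested site; the pooled scope is the ramet-count-weighted mean of the
#' per-site values from the joint fit. Standard errors come from the delta
#' method on the inverse average-information matrix, and are reported as
#' `NA` when any involved component is boundary-pinned. Significance is a
#' likelihood ratio test of the no-genetics null with the boundary mixture
#' reference `0.5 chi2_0 + 0.5 chi2_1`.
#'
#' @param fit a univariate `vc_fit`.
#' @param scope `"site_1"`, `"site_2"` or `"pooled"`.
#' @param alpha significance level for the `significant` flag.
#' @param test run the LRT (refits the null model); set `FALSE` to skip.
#' @param null_fit optional pre-computed no-genetics `vc_fit`.
#' @return a `heritability_estimate`: `H2`, `se`, `scope`, `components`,
#'   `p_value`, `significant`, `boundary`.
#' @export
heritability <- function(fit, scope = c("site_1", "site_2", "pooled"),
                         alpha = 0.05, test = TRUE, null_fit = NULL) {
  stopifnot(inherits(fit, "vc_fit"), fit$spec$model == "univariate")
  scope <- match.arg(scope)
  S <- fit$spec$n_sites
  if (scope == "site_2" && S < 2L) stop_bad_arg("fit has a single site")
  est <- fit$estimates
  comp_names <- function(s) {
    c(paste0("gvar_s", s),
      if (fit$spec$include_spatial) paste0("svar_s", s),
      paste0("nugget_s", s))
  }
  h2_site <- function(s) {
    a <- pick(est, paste0("gvar_s", s))
    x <- pick(est, paste0("svar_s", s))
    e <- pick(est, paste0("nugget_s", s))
    tot <- a + x + e
    if (tot <= 0) stop_bad_arg("zero phenotypic variance at site ", s)
    c(h2 = a / tot, a = a, x = x, e = e, tot = tot)
  }
  grad_site <- function(hs) {
    # d h2 / d(a, x, e): ((x+e)/tot^2, -a/tot^2, -a/tot^2)
    g <- c((hs["x"] + hs["e"]) / hs["tot"]^2,
           -hs["a"] / hs["tot"]^2, -hs["a"] / hs["tot"]^2)
    if (fit$spec$include_spatial) g else g[c(1, 3)]
  }
  # Delta-method SE over the free (non-pinned) components: a spatial or
  # nugget variance pinned at zero is treated as structurally absent; the
  # SE is NA only when the genetic variance itself sits on the boundary.
  se_over_free <- function(nm, grad) {
    bd <- fit$boundary[nm]
    if (any(bd[grep("^gvar", nm)])) return(NA_real_)
    keep <- !bd
    if (!any(keep)) return(NA_real_)
    delta_se(grad[keep], fit$vcov, match(nm[keep], fit$spec$names))
  }
  if (scope != "pooled") {
    s <- if (scope == "site_1") 1L else 2L
    hs <- h2_site(s)
    nm <- comp_names(s)
    se <- se_over_free(nm, grad_site(hs))
    h2 <- unname(hs["h2"])
    used <- list(genetic = unname(hs["a"]), spatial = unname(hs["x"]),
                 nugget = unname(hs["e"]))
    bnd <- any(fit$boundary[nm])
  } else {
    n_s <- vapply(seq_len(S), function(s) sum(fit$data$site_idx == s),
                  numeric(1))
    w <- n_s / sum(n_s)
    hss <- lapply(seq_len(S), h2_site)
    h2 <- sum(w * vapply(hss, `[`, numeric(1), "h2"))
    nm <- unlist(lapply(seq_len(S), comp_names))
    grad <- unlist(lapply(seq_len(S), function(s) w[s] * grad_site(hss[[s]])))
    se <- se_over_free(nm, grad)
    used <- lapply(hss, function(hs)
      list(genetic = unname(hs["a"]), spatial = unname(hs["x"]),
           nugget = unname(hs["e"])))
    bnd <- any(fit$boundary[nm])
  }
  p <- NA_real_
  if (test) {
    if (is.null(null_fit))
      null_fit <- fit_reml(fit$data, include_spatial = fit$spec$include_spatial,
                           genetic = FALSE)
    p <- lrt(fit, null_fit, "variance_on_boundary")$p_value
  }
  structure(list(H2 = h2, se = se, scope = scope, components = used,
                 p_value = p, significant = isTRUE(p < alpha),
                 boundary = bnd, alpha = alpha),
            class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H2 (%s) = %.3f (SE %s)%s\n", x$scope, x$H2,
              if (is.na(x$se)) "NA" else sprintf("%.3f", x$se),
              if (is.na(x$p_value)) "" else if (x$significant)
                sprintf(", p = %.3g", x$p_value) else
                  sprintf(", NS (p = %.3g)", x$p_value)))
  invisible(x)
}

correlation_estimate <- function(kind, value, se, boundary, p_value,
                                 undefined = FALSE) {
  structure(list(kind = kind, value = value, se = se, boundary = boundary,
                 p_value = p_value, undefined = undefined),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s genetic correlation: undefined (zero genetic variance)\n",
                x$kind))
  } else {
    cat(sprintf("%s genetic correlation = %.3f (SE %s)%s%s\n", x$kind,
                x$value, if (is.na(x$se)) "NA" else sprintf("%.3f", x$se),
                if (x$boundary) " [boundary]" else "",
                if (is.na(x$p_value)) "" else sprintf(", p = %.3g", x$p_value)))
  }
  invisible(x)
}

# Shared correlation-from-fit computation for type B / type A estimates.
gen_corr_from_fit <- function(fit, kind, names3, test, null_fit) {
  est <- fit$estimates
  v1 <- pick(est, names3[1]); v2 <- pick(est, names3[2])
  cv <- pick(est, names3[3])
  if (v1 <= 0 || v2 <= 0 || any(fit$boundary[names3[1:2]]))
    return(correlation_estimate(kind, NA_real_, NA_real_, TRUE, NA_real_,
                                undefined = TRUE))
  r <- cv / sqrt(v1 * v2)
  boundary <- abs(r) > 0.999 || isTRUE(fit$boundary[names3[3]])
  idx <- match(names3, fit$spec$names)
  grad <- c(-cv / (2 * v1^1.5 * sqrt(v2)),
            -cv / (2 * v2^1.5 * sqrt(v1)),
            1 / sqrt(v1 * v2))
  se <- if (boundary) NA_real_ else delta_se(grad, fit$vcov, idx)
  p <- NA_real_
  if (test) {
    if (is.null(null_fit))
      null_fit <- fit_reml(fit$data, include_spatial = fit$spec$include_spatial,
                           fix_gcov = TRUE)
    p <- lrt(fit, null_fit, "covariance_zero")$p_value
  }
  correlation_estimate(kind, min(max(r, -1), 1), se, boundary, p)
}

#' Type B (cross-site) genetic correlation
#'
#' `r_B = cov_a(S1, S2) / sqrt(var_a(S1) var_a(S2))` from a two-site fit; a
#' value pinned at +-1 is boundary-flagged with `NA` SE, mirroring how such
#' estimates are reported in clonal trials. The p-value tests the
#' zero-covariance null by LRT.
#'
#' @param fit a two-site univariate `vc_fit`.
#' @param test,null_fit as in [heritability()].
#' @return a `correlation_estimate`.
#' @export
type_b_correlation <- function(fit, test = TRUE, null_fit = NULL) {
  stopifnot(inherits(fit, "vc_fit"), fit$spec$model == "univariate")
  if (fit$spec$n_sites != 2L) stop_bad_arg("type B requires a two-site fit")
  gen_corr_from_fit(fit, "type B", c("gvar_s1", "gvar_s2", "gcov"),
                    test, null_fit)
}

#' Genetic correlation between two traits or years
#'
#' Fits the bivariate genomic model and returns
#' `r = cov_a(T1, T2) / sqrt(var_a(T1) var_a(T2))`. Two years of the same
#' trait are handled identically (`kind = "year_to_year"`).
#'
#' @param data a bivariate `model_data`, or a `vc_fit` of one.
#' @param kind `"type_A"` or `"year_to_year"` (labeling only).
#' @param test,null_fit as in [heritability()].
#' @return a `correlation_estimate` with the `fit` attached as attribute.
#' @export
trait_pair_correlation <- function(data, kind = c("type_A", "year_to_year"),
                                   test = TRUE, null_fit = NULL) {
  kind <- match.arg(kind)
  fit <- if (inherits(data, "vc_fit")) data else fit_reml(data)
  stopifnot(fit$spec$model == "bivariate")
  out <- gen_corr_from_fit(fit, sub("_", " ", kind),
                           c("gvar_t1", "gvar_t2", "gcov"), test, null_fit)
  attr(out, "fit") <- fit
  out
}

#' Per-wavelength heritability scan
#'
#' Fits one independent univariate genomic model per band and tabulates
#' heritability, its SE and LRT significance. Bands whose fit fails are
#' recorded with the failure reason rather than dropped.
#'
#' @param spectra a `spectra_table` whose ramet ids match `design$ramet`.
#' @param design an `orchard_design`.
#' @param grm a `grm`.
#' @param scope heritability scope per band.
#' @param include_spatial fit the spatial residual per band.
#' @param test per-band LRT (doubles the fits).
#' @param alpha significance level.
#' @param p_adjust `"none"` (per-band significance, the default) or
#'   `"bonferroni"` across bands.
#' @return a `gp_table` data.frame: wavelength, H2, se, p_value,
#'   significant, n_ramets, n_clones, error.
#' @export
wavelength_scan <- function(spectra, design, grm,
                            scope = "site_1", include_spatial = TRUE,
                            test = TRUE, alpha = 0.05,
                            p_adjust = c("none", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(spectra, "spectra_table"))
  validate_design(design)
  m <- match(design$ramet, spectra$ramet_ids)
  if (anyNA(m))
    stop_bad_arg("ramets missing from spectra: ",
                 paste(utils::head(design$ramet[is.na(m)], 5), collapse = ", "))
  rows <- lapply(seq_along(spectra$wavelengths), function(b) {
    ph <- as.data.frame(design)
    ph$band <- spectra$reflectance[m, b]
    res <- tryCatch({
      md <- model_data(ph, "band", grm)
      fit <- fit_reml(md, include_spatial = include_spatial)
      h <- heritability(fit, scope, alpha = alpha, test = test)
      data.frame(wavelength = spectra$wavelengths[b], H2 = h$H2, se = h$se,
                 p_value = h$p_value, significant = h$significant,
                 n_ramets = length(md$y),
                 n_clones = length(unique(md$clone_map)),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(wavelength = spectra$wavelengths[b], H2 = NA_real_,
                 se = NA_real_, p_value = NA_real_, significant = NA,
                 n_ramets = NA_integer_, n_clones = NA_integer_,
                 error = conditionMessage(e))
    })
    res
  })
  out <- do.call(rbind, rows)
  if (all(!is.na(out$error)))
    stop_bad_arg("every band failed; first error: ", out$error[1])
  if (p_adjust == "bonferroni") {
    out$p_value <- stats::p.adjust(out$p_value, "bonferroni")
    out$significant <- !is.na(out$p_value) & out$p_value < alpha
  }
  class(out) <- c("gp_table", "data.frame")
  out
}

#' Per-wavelength genetic correlation with a needle functional trait
#'
#' For each band, fits the bivariate genomic model of (band reflectance,
#' trait) and tabulates the genetic correlation with SE and LRT p-value.
#'
#' @param spectra a `spectra_table`.
#' @param nft data.frame with columns `ramet` and the trait, or a numeric
#'   vector aligned with `design`.
#' @param trait trait column name when `nft` is a data.frame.
#' @param design an `orchard_design`.
#' @param grm a `grm`.
#' @param test per-band LRT of the zero-covariance null.
#' @param alpha significance level.
#' @return a `gp_table` data.frame: wavelength, correlation, se, boundary,
#'   p_value, significant, error.
#' @export
correlation_with_nft <- function(spectra, nft, trait = NULL, design, grm,
                                 test = TRUE, alpha = 0.05) {
  stopifnot(inherits(spectra, "spectra_table"))
  validate_design(design)
  m <- match(design$ramet, spectra$ramet_ids)
  if (anyNA(m)) stop_bad_arg("ramets missing from spectra")
  tv <- if (is.data.frame(nft)) {
    if (is.null(trait)) stop_bad_arg("'trait' required with a data.frame nft")
    nft[[trait]][match(design$ramet, nft$ramet)]
  } else as.numeric(nft)
  rows <- lapply(seq_along(spectra$wavelengths), function(b) {
    ph <- as.data.frame(design)
    ph$band <- spectra$reflectance[m, b]
    ph$trait <- tv
    tryCatch({
      md <- model_data_bivariate(ph, c("band", "trait"), grm)
      ce <- trait_pair_correlation(md, "type_A", test = test)
      data.frame(wavelength = spectra$wavelengths[b],
                 correlation = ce$value, se = ce$se, boundary = ce$boundary,
                 p_value = ce$p_value,
                 significant = isTRUE(ce$p_value < alpha),
                 error = NA_character_)
    }, error = function(e) {
      data.frame(wavelength = spectra$wavelengths[b], correlation = NA_real_,
                 se = NA_real_, boundary = NA, p_value = NA_real_,
                 significant = NA, error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  class(out) <- c("gp_table", "data.frame")
  out
}

#' Plot a per-wavelength parameter scan
#'
#' Draws the heritability or genetic-correlation profile across wavelengths
#' with an SE ribbon. Requires ggplot2.
#'
#' @param tab a `gp_table`.
#' @param value column to plot (default picks `H2` or `correlation`).
#' @return a ggplot object.
#' @export
plot_scan <- function(tab, value = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_bad_arg("ggplot2 is required for plotting")
  if (is.null(value)) value <- if ("H2" %in% names(tab)) "H2" else "correlation"
  df <- as.data.frame(tab)
  df$.y <- df[[value]]
  df$.lo <- df$.y - df$se
  df$.hi <- df$.y + df$se
  ggplot2::ggplot(df, ggplot2::aes(x = .data$wavelength, y = .data$.y)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$.lo, ymax = .data$.hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = value)
}
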