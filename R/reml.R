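# The REML engine: restricted log-likelihood for the genomic mixed models
# (univariate multi-site with separable AR1 x AR1 + nugget residuals, and
# bivariate trait-pair models), maximized over transformed parameters, with
# an average-information matrix at the optimum for standard errors.

#' Genetic covariance parameters
#'
#' @param variances per-group (site/trait/year) additive genetic variances.
#' @param covariance genetic covariance between the two groups (0 for a
#'   single group).
#' @return a `genetic_covariance`.
#' @export
genetic_covariance <- function(variances, covariance = 0) {
  if (any(variances < 0)) stop_bad_arg("genetic variances must be >= 0")
  if (length(variances) == 2L) {
    den <- sqrt(prod(variances))
    if (den > 0 && abs(covariance) > den * (1 + 1e-8))
      stop_bad_arg("genetic covariance implies |correlation| > 1")
  }
  structure(list(variances = as.numeric(variances),
                 covariance = as.numeric(covariance)),
            class = "genetic_covariance")
}

#' Residual covariance parameters (spatial + nugget, per site)
#'
#' @param spatial_variance,rho_col,rho_row,nugget per-site values.
#' @return a `residual_covariance`.
#' @export
residual_covariance <- function(spatial_variance, rho_col, rho_row, nugget) {
  if (any(spatial_variance < 0) || any(nugget < 0))
    stop_bad_arg("residual variances must be >= 0")
  if (any(abs(c(rho_col, rho_row)) >= 1))
    stop_bad_arg("AR1 correlations must lie in (-1, 1)")
  structure(list(type = "spatial",
                 spatial_variance = as.numeric(spatial_variance),
                 rho_col = as.numeric(rho_col),
                 rho_row = as.numeric(rho_row),
                 nugget = as.numeric(nugget)),
            class = "residual_covariance")
}

#' Residual covariance parameters for a bivariate fit
#'
#' @param variances per-trait residual variances.
#' @param covariance residual covariance between co-observed responses.
#' @return a `residual_covariance`.
#' @export
residual_covariance_bivariate <- function(variances, covariance = 0) {
  if (any(variances < 0)) stop_bad_arg("residual variances must be >= 0")
  structure(list(type = "bivariate", variances = as.numeric(variances),
                 covariance = as.numeric(covariance)),
            class = "residual_covariance")
}

# Dense restricted log-likelihood from Cholesky factors; returns -Inf when V
# (or X'V^-1 X) is not positive definite instead of erroring.
reml_loglik_dense <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(-Inf)
  logdetV <- 2 * sum(log(diag(cv)))
  Viy <- backsolve(cv, backsolve(cv, y, transpose = TRUE))
  ViX <- backsolve(cv, backsolve(cv, X, transpose = TRUE))
  XtViX <- crossprod(X, ViX)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(-Inf)
  XtViy <- crossprod(X, Viy)
  beta <- backsolve(cx, backsolve(cx, XtViy, transpose = TRUE))
  ytPy <- sum(y * Viy) - sum(XtViy * beta)
  -0.5 * (logdetV + 2 * sum(log(diag(cx))) + ytPy + (n - p) * log(2 * pi))
}

# Build the marginal covariance V = Z G Z' + R for a model_data object.
build_V <- function(data, g, r) {
  Sigma <- site_gen_cov_from(g, if (data$model == "univariate")
    data$n_sites else 2L)
  G <- kronecker(Sigma, data$K)
  V <- G[data$u_idx, data$u_idx, drop = FALSE]
  V + build_R(data, r)
}

site_gen_cov_from <- function(g, n_groups) {
  S <- diag(rep_len(g$variances, n_groups), n_groups)
  if (n_groups == 2L) S[1, 2] <- S[2, 1] <- g$covariance
  S
}

build_R <- function(data, r) {
  if (r$type == "spatial") {
    assemble_residual_covariance(data$design, r$spatial_variance,
                                 r$rho_col, r$rho_row, r$nugget)
  } else {
    n_obs <- length(data$y)
    R <- diag(rep_len(r$variances, 2L)[data$trait_idx], n_obs)
    if (r$covariance != 0) {
      i1 <- which(data$trait_idx == 1L)
      i2 <- which(data$trait_idx == 2L)
      m <- match(data$ramet_idx[i1], data$ramet_idx[i2])
      co <- which(!is.na(m))
      R[cbind(i1[co], i2[m[co]])] <- r$covariance
      R[cbind(i2[m[co]], i1[co])] <- r$covariance
    }
    R
  }
}

#' Restricted log-likelihood of a genomic mixed model
#'
#' Evaluates the restricted (residual) log-likelihood
#' `-0.5 [log|V| + log|X' V^-1 X| + y' P y + (n - p) log 2 pi]` with
#' `V = Z G Z' + R` built from the supplied genetic and residual parameter
#' sets. Errors when V is not positive definite, naming the parameters.
#'
#' @param data a `model_data`.
#' @param g a [genetic_covariance()].
#' @param r a [residual_covariance()] or [residual_covariance_bivariate()].
#' @return log-likelihood in nats.
#' @export
restricted_loglik <- function(data, g, r) {
  stopifnot(inherits(data, "model_data"))
  ll <- reml_loglik_dense(data$y, data$X, build_V(data, g, r))
  if (!is.finite(ll))
    stop_bad_arg("V is not positive definite at g = (",
                 paste(signif(c(g$variances, g$covariance), 4), collapse = ", "),
                 "), residual type ", r$type)
  ll
}

## ---- parameter packing -----------------------------------------------

# Free-parameter specification: names, types ("var", "cov", "rho") and how
# to build (g, r) from the natural-scale vector phi. `genetic = FALSE` drops
# the genetic term entirely (the no-genetics null model); `fix_gcov = TRUE`
# pins the genetic covariance at zero (the zero-correlation null model).
param_spec <- function(data, include_spatial = TRUE, genetic = TRUE,
                       fix_gcov = FALSE) {
  if (data$model == "univariate") {
    S <- data$n_sites
    nm <- if (genetic) paste0("gvar_s", seq_len(S)) else character()
    ty <- rep("var", length(nm))
    if (genetic && S == 2L && !fix_gcov) { nm <- c(nm, "gcov"); ty <- c(ty, "cov") }
    if (include_spatial) {
      for (s in seq_len(S)) {
        nm <- c(nm, paste0(c("svar_s", "rho_col_s", "rho_row_s"), s))
        ty <- c(ty, "var", "rho", "rho")
      }
    }
    nm <- c(nm, paste0("nugget_s", seq_len(S)))
    ty <- c(ty, rep("var", S))
  } else {
    nm <- ty <- character()
    if (genetic) {
      nm <- c("gvar_t1", "gvar_t2", if (!fix_gcov) "gcov")
      ty <- c("var", "var", if (!fix_gcov) "cov")
    }
    nm <- c(nm, "evar_t1", "evar_t2")
    ty <- c(ty, "var", "var")
    has_co <- any(data$trait_idx == 1L & data$ramet_idx %in%
                    data$ramet_idx[data$trait_idx == 2L])
    if (has_co) { nm <- c(nm, "ecov"); ty <- c(ty, "cov") }
  }
  list(names = nm, types = ty, model = data$model,
       include_spatial = include_spatial, genetic = genetic,
       n_sites = if (data$model == "univariate") data$n_sites else 2L)
}

pick <- function(v, nm, default = 0) {
  out <- rep(default, length(nm))
  hit <- nm %in% names(v)
  out[hit] <- v[nm[hit]]
  out
}

phi_to_gr <- function(phi, spec) {
  v <- stats::setNames(phi, spec$names)
  if (spec$model == "univariate") {
    S <- spec$n_sites
    g <- genetic_covariance(pick(v, paste0("gvar_s", seq_len(S))),
                            if (S == 2L) pick(v, "gcov") else 0)
    if (spec$include_spatial) {
      r <- residual_covariance(v[paste0("svar_s", seq_len(S))],
                               v[paste0("rho_col_s", seq_len(S))],
                               v[paste0("rho_row_s", seq_len(S))],
                               v[paste0("nugget_s", seq_len(S))])
    } else {
      r <- residual_covariance(rep(0, S), rep(0, S), rep(0, S),
                               v[paste0("nugget_s", seq_len(S))])
    }
  } else {
    g <- genetic_covariance(pick(v, c("gvar_t1", "gvar_t2")),
                            pick(v, "gcov"))
    r <- residual_covariance_bivariate(
      v[c("evar_t1", "evar_t2")], pick(v, "ecov"))
  }
  list(g = g, r = r)
}

# Transformed scale: log for variances, atanh of the implied correlation for
# covariances, atanh for AR1 rho. Covariance entries reference the two
# variances preceding their group.
trans_to_phi <- function(par, spec) {
  v <- stats::setNames(numeric(length(par)), spec$names)
  for (k in seq_along(par)) {
    v[k] <- switch(spec$types[k],
                   var = exp(par[k]),
                   rho = to_corr(par[k]),
                   cov = NA_real_)
  }
  for (k in which(spec$types == "cov")) {
    nm <- spec$names[k]
    pair <- if (nm == "gcov") {
      if (spec$model == "univariate") c("gvar_s1", "gvar_s2")
      else c("gvar_t1", "gvar_t2")
    } else c("evar_t1", "evar_t2")
    v[k] <- to_corr(par[k]) * sqrt(prod(v[pair]))
  }
  v
}

phi_to_trans <- function(phi, spec) {
  v <- stats::setNames(phi, spec$names)
  par <- numeric(length(phi))
  for (k in seq_along(phi)) {
    par[k] <- switch(spec$types[k],
                     var = log(max(phi[k], 1e-12)),
                     rho = from_corr(phi[k]),
                     cov = {
                       nm <- spec$names[k]
                       pair <- if (nm == "gcov") {
                         if (spec$model == "univariate") c("gvar_s1", "gvar_s2")
                         else c("gvar_t1", "gvar_t2")
                       } else c("evar_t1", "evar_t2")
                       den <- sqrt(prod(v[pair]))
                       from_corr(if (den > 0) phi[k] / den else 0)
                     })
  }
  par
}

trans_bounds <- function(spec, var_y) {
  lo <- hi <- numeric(length(spec$types))
  lo[spec$types == "var"] <- log(var_y * 1e-8)
  hi[spec$types == "var"] <- log(var_y * 1e4)
  lo[spec$types == "cov"] <- -7; hi[spec$types == "cov"] <- 7
  lo[spec$types == "rho"] <- -4; hi[spec$types == "rho"] <- 4
  list(lower = lo, upper = hi)
}

## ---- fast rotated bivariate likelihood --------------------------------

# For balanced bivariate data (both responses on every ramet) the marginal
# covariance is Sigma_a (x) M + Sigma_e (x) I with M = Z K Z'. Rotating by
# the eigenvectors of M turns each likelihood evaluation into n independent
# 2x2 blocks: O(n) per evaluation instead of O(n^3).
rotated_setup <- function(data) {
  n <- data$n_ramets
  M <- data$K[data$clone_map[seq_len(n)], data$clone_map[seq_len(n)],
              drop = FALSE]
  e <- eigen(M, symmetric = TRUE)
  U <- e$vectors
  list(d = pmax(e$values, 0),
       y1 = drop(crossprod(U, data$y[seq_len(n)])),
       y2 = drop(crossprod(U, data$y[n + seq_len(n)])),
       X1 = crossprod(U, data$X[seq_len(n), , drop = FALSE]),
       X2 = crossprod(U, data$X[n + seq_len(n), , drop = FALSE]),
       n = n, p = ncol(data$X))
}

rotated_loglik <- function(rs, ga1, ga2, gc, e1, e2, ec) {
  b11 <- ga1 * rs$d + e1
  b22 <- ga2 * rs$d + e2
  b12 <- gc * rs$d + ec
  det <- b11 * b22 - b12^2
  if (any(b11 <= 0) || any(det <= 0)) return(-Inf)
  i11 <- b22 / det; i22 <- b11 / det; i12 <- -b12 / det
  ip <- function(u1, u2, v1, v2)
    sum(i11 * u1 * v1 + i12 * (u1 * v2 + u2 * v1) + i22 * u2 * v2)
  p <- rs$p
  XtViX <- matrix(0, p, p)
  XtViy <- numeric(p)
  for (a in seq_len(p)) {
    XtViy[a] <- ip(rs$X1[, a], rs$X2[, a], rs$y1, rs$y2)
    for (b in a:p)
      XtViX[a, b] <- XtViX[b, a] <- ip(rs$X1[, a], rs$X2[, a],
                                       rs$X1[, b], rs$X2[, b])
  }
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(-Inf)
  beta <- backsolve(cx, backsolve(cx, XtViy, transpose = TRUE))
  ytViy <- ip(rs$y1, rs$y2, rs$y1, rs$y2)
  ytPy <- ytViy - sum(XtViy * beta)
  -0.5 * (sum(log(det)) + 2 * sum(log(diag(cx))) + ytPy +
            (2 * rs$n - p) * log(2 * pi))
}

## ---- fast univariate objective ----------------------------------------

# Precompute everything reusable across likelihood evaluations: integer lag
# matrices per site (AR1 powers then become table lookups) and the genetic
# index map.
uni_setup <- function(data) {
  S <- data$n_sites
  sites <- lapply(seq_len(S), function(s) which(data$site_idx == s))
  lags <- lapply(seq_len(S), function(s) {
    i <- sites[[s]]
    list(dc = abs(outer(data$design$col[i], data$design$col[i], "-")) + 1L,
         dr = abs(outer(data$design$row[i], data$design$row[i], "-")) + 1L,
         maxc = max(abs(outer(data$design$col[i], data$design$col[i], "-"))),
         maxr = max(abs(outer(data$design$row[i], data$design$row[i], "-"))))
  })
  list(S = S, sites = sites, lags = lags, n = length(data$y))
}

# V for the univariate model from a named natural-parameter vector, using
# the cached setup; identical to build_V but ~4x faster per evaluation.
uni_build_V <- function(data, us, v) {
  S <- us$S
  Sg <- diag(pick(v, paste0("gvar_s", seq_len(S))), S)
  if (S == 2L) Sg[1, 2] <- Sg[2, 1] <- pick(v, "gcov")
  G <- kronecker(Sg, data$K)
  V <- G[data$u_idx, data$u_idx, drop = FALSE]
  for (s in seq_len(S)) {
    i <- us$sites[[s]]
    sv <- pick(v, paste0("svar_s", s))
    if (sv > 0) {
      lg <- us$lags[[s]]
      pc <- pick(v, paste0("rho_col_s", s))^(0:lg$maxc)
      pr <- pick(v, paste0("rho_row_s", s))^(0:lg$maxr)
      V[i, i] <- V[i, i] + sv * (pc[lg$dc] * pr[lg$dr])
    }
    V[cbind(i, i)] <- V[cbind(i, i)] + pick(v, paste0("nugget_s", s))
  }
  V
}

## ---- starting values --------------------------------------------------

start_values <- function(data, spec) {
  phi <- stats::setNames(numeric(length(spec$names)), spec$names)
  set_if <- function(nm, val) if (nm %in% names(phi)) phi[nm] <<- val
  if (spec$model == "univariate") {
    S <- spec$n_sites
    cm_list <- vector("list", S)
    for (s in seq_len(S)) {
      i <- which(data$site_idx == s)
      cm <- tapply(data$y[i], data$clone_map[i], mean)
      cm_list[[s]] <- cm
      vc <- if (length(cm) > 1) stats::var(cm) else stats::var(data$y[i])
      wr <- mean(tapply(data$y[i], data$clone_map[i], function(z)
        if (length(z) > 1) stats::var(z) else NA), na.rm = TRUE)
      if (!is.finite(wr)) wr <- stats::var(data$y[i])
      set_if(paste0("gvar_s", s), max(vc / 2, 0.02 * stats::var(data$y[i])))
      if (spec$include_spatial) {
        set_if(paste0("svar_s", s), wr / 2)
        set_if(paste0("rho_col_s", s), 0.1)
        set_if(paste0("rho_row_s", s), 0.1)
        set_if(paste0("nugget_s", s), wr / 2)
      } else {
        set_if(paste0("nugget_s", s), wr)
      }
    }
    if (S == 2L && all(c("gvar_s1", "gvar_s2", "gcov") %in% names(phi))) {
      shared <- intersect(names(cm_list[[1]]), names(cm_list[[2]]))
      r0 <- if (length(shared) > 2)
        stats::cor(cm_list[[1]][shared], cm_list[[2]][shared]) else 0.5
      r0 <- min(max(r0, -0.9), 0.9)
      phi["gcov"] <- r0 * sqrt(phi["gvar_s1"] * phi["gvar_s2"])
    }
  } else {
    for (t in 1:2) {
      i <- which(data$trait_idx == t)
      cm <- tapply(data$y[i], data$clone_map[i], mean)
      wr <- mean(tapply(data$y[i], data$clone_map[i], function(z)
        if (length(z) > 1) stats::var(z) else NA), na.rm = TRUE)
      if (!is.finite(wr)) wr <- stats::var(data$y[i])
      set_if(paste0("gvar_t", t), max(stats::var(cm) / 2,
                                      0.02 * stats::var(data$y[i])))
      set_if(paste0("evar_t", t), wr)
    }
    if (all(c("gvar_t1", "gvar_t2", "gcov") %in% names(phi)))
      phi["gcov"] <- 0.3 * sqrt(phi["gvar_t1"] * phi["gvar_t2"])
  }
  phi
}

## ---- the fitter -------------------------------------------------------

#' Fit a genomic mixed model by REML
#'
#' Maximizes the restricted likelihood over all free variance parameters —
#' log-scale variances, correlations and AR1 autocorrelations through a
#' tanh bijection onto their open intervals — with a quasi-Newton optimizer
#' under box bounds, restarting from perturbed values if the first attempt
#' fails to improve. At the optimum the average-information matrix is
#' computed on the natural scale (derivatives of V obtained numerically)
#' and inverted for parameter standard errors; parameters pinned at a
#' boundary are flagged and excluded from SE reporting. BLUPs of clone
#' effects are returned per group.
#'
#' For balanced bivariate data the likelihood is evaluated in an
#' eigen-rotated basis (exactly equal to the dense evaluation, but linear
#' in the number of ramets).
#'
#' @param data a `model_data` from [model_data()] or
#'   [model_data_bivariate()].
#' @param start optional named natural-scale starting values (see
#'   `fit$spec$names`).
#' @param include_spatial fit the AR1 x AR1 spatial component (univariate
#'   models only). With `FALSE` the residual collapses to the nugget.
#' @param genetic with `FALSE`, drop the genetic term entirely — the
#'   no-genetics null model for likelihood ratio tests of the genetic
#'   variance.
#' @param fix_gcov pin the genetic covariance at zero — the null model for
#'   likelihood ratio tests of a genetic correlation.
#' @param control list: `tol` (log-likelihood change, default 1e-8),
#'   `max_iter`, `restarts`.
#' @return a `vc_fit`: estimates (natural scale, named as in `spec$names`),
#'   `loglik`, `ai` (average-information matrix), `vcov`, `se`,
#'   `boundary` flags, `blups` (clones x groups), convergence info.
#' @export
fit_reml <- function(data, start = NULL, include_spatial = TRUE,
                     genetic = TRUE, fix_gcov = FALSE, control = list()) {
  stopifnot(inherits(data, "model_data"))
  ctl <- utils::modifyList(list(tol = 1e-8, max_iter = 500L, restarts = 2L),
                           control)
  spec <- param_spec(data, include_spatial, genetic, fix_gcov)
  var_y <- stats::var(data$y)
  bounds <- trans_bounds(spec, var_y)
  use_rot <- data$model == "bivariate" && isTRUE(data$balanced)
  rs <- if (use_rot) rotated_setup(data) else NULL
  us <- if (data$model == "univariate") uni_setup(data) else NULL
  negll <- function(par) {
    phi <- trans_to_phi(par, spec)
    ll <- if (use_rot) {
      rotated_loglik(rs, pick(phi, "gvar_t1"), pick(phi, "gvar_t2"),
                     pick(phi, "gcov"), phi["evar_t1"], phi["evar_t2"],
                     pick(phi, "ecov"))
    } else if (data$model == "univariate") {
      reml_loglik_dense(data$y, data$X, uni_build_V(data, us, phi))
    } else {
      gr <- phi_to_gr(phi, spec)
      reml_loglik_dense(data$y, data$X, build_V(data, gr$g, gr$r))
    }
    if (!is.finite(ll)) 1e10 else -ll
  }
  phi0 <- start_values(data, spec)
  # two-site fits start from per-site univariate prefits: much closer to
  # the joint optimum than the moment-based defaults
  if (is.null(start) && genetic && data$model == "univariate" &&
      data$n_sites == 2L) {
    pre <- tryCatch({
      ph <- as.data.frame(data$design)
      ph$.y <- data$y
      lapply(1:2, function(s) {
        sub <- ph[data$site_idx == s, , drop = FALSE]
        fit_reml(model_data(sub, ".y", data$K),
                 include_spatial = include_spatial,
                 control = list(restarts = 0L))$estimates
      })
    }, error = function(e) NULL)
    if (!is.null(pre)) {
      r0 <- if ("gcov" %in% names(phi0)) {
        den <- sqrt(phi0["gvar_s1"] * phi0["gvar_s2"])
        if (den > 0) phi0["gcov"] / den else 0.5
      } else 0
      for (s in 1:2) {
        est <- pre[[s]]
        names(est) <- sub("_s1$", paste0("_s", s), names(est))
        hit <- intersect(names(est), names(phi0))
        phi0[hit] <- pmax(est[hit], 1e-8)
        rn <- grep("^rho", hit, value = TRUE)
        phi0[rn] <- est[rn]
      }
      if ("gcov" %in% names(phi0))
        phi0["gcov"] <- min(max(r0, -0.9), 0.9) *
          sqrt(phi0["gvar_s1"] * phi0["gvar_s2"])
    }
  }
  if (!is.null(start)) phi0[names(start)] <- start
  par0 <- pmin(pmax(phi_to_trans(phi0, spec), bounds$lower), bounds$upper)
  best <- NULL
  tries <- list(par0)
  for (k in seq_len(ctl$restarts)) {
    jit <- par0
    jit[spec$types == "var"] <- jit[spec$types == "var"] +
      c(-0.7, 0.7)[1 + k %% 2]
    tries[[k + 1L]] <- pmin(pmax(jit, bounds$lower), bounds$upper)
  }
  for (p0 in tries) {
    opt <- tryCatch(
      stats::nlminb(p0, negll, lower = bounds$lower, upper = bounds$upper,
                    control = list(iter.max = ctl$max_iter, eval.max = 4000,
                                   rel.tol = 1e-12, abs.tol = ctl$tol)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$objective < 1e9 &&
        (is.null(best) || opt$objective < best$objective - 1e-9)) best <- opt
    if (!is.null(best) && best$convergence == 0 &&
        identical(p0, tries[[1]])) break
  }
  if (is.null(best) || best$objective >= 1e9)
    stop_bad_arg("REML did not converge: no positive-definite parameter ",
                 "point found (model ", data$model, ")")
  phi <- trans_to_phi(best$par, spec)
  boundary <- boundary_flags(phi, best$par, spec, bounds, var_y)
  ai <- average_information(data, phi, spec, rs = rs)
  vcov <- tryCatch(solve(ai), error = function(e)
    matrix(NA_real_, length(phi), length(phi),
           dimnames = list(spec$names, spec$names)))
  se <- sqrt(pmax(diag(vcov), 0))
  se[boundary] <- NA_real_
  gr <- phi_to_gr(phi, spec)
  structure(list(
    estimates = phi, spec = spec, loglik = -best$objective,
    ai = ai, vcov = vcov, se = stats::setNames(se, spec$names),
    boundary = stats::setNames(boundary, spec$names),
    blups = compute_blups(data, gr$g, gr$r),
    convergence = list(code = best$convergence,
                       iterations = best$iterations,
                       message = best$message),
    data = data, var_y = var_y),
    class = "vc_fit")
}

boundary_flags <- function(phi, par, spec, bounds, var_y) {
  flag <- logical(length(phi))
  flag[spec$types == "var"] <- phi[spec$types == "var"] < var_y * 1e-5 |
    par[spec$types == "var"] <= bounds$lower[spec$types == "var"] + 1e-6
  for (k in which(spec$types == "cov")) {
    nm <- spec$names[k]
    pair <- if (nm == "gcov") {
      if (spec$model == "univariate") c("gvar_s1", "gvar_s2")
      else c("gvar_t1", "gvar_t2")
    } else c("evar_t1", "evar_t2")
    den <- sqrt(prod(phi[pair]))
    flag[k] <- den <= 0 || abs(phi[k] / den) > 0.999
  }
  flag[spec$types == "rho"] <- abs(phi[spec$types == "rho"]) > 0.995
  flag
}

# Average-information matrix on the natural scale at phi:
# AI_ij = 0.5 * (dV_i P y)' P (dV_j P y), with dV/dphi obtained by central
# differences (V is cheap to assemble at desk scale).
average_information <- function(data, phi, spec, rs = NULL) {
  gr <- phi_to_gr(phi, spec)
  V <- build_V(data, gr$g, gr$r)
  y <- data$y; X <- data$X
  cv <- tryCatch(chol(V + diag(1e-10 * mean(diag(V)), nrow(V))),
                 error = function(e) NULL)
  if (is.null(cv)) {
    k <- length(phi)
    return(matrix(NA_real_, k, k, dimnames = list(spec$names, spec$names)))
  }
  Vsolve <- function(z) backsolve(cv, backsolve(cv, z, transpose = TRUE))
  ViX <- Vsolve(X)
  XtViX <- crossprod(X, ViX)
  Pfun <- function(z) {
    Viz <- Vsolve(z)
    Viz - ViX %*% solve(XtViX, crossprod(X, Viz))
  }
  Py <- Pfun(y)
  k <- length(phi)
  a <- matrix(0, length(y), k)
  for (j in seq_len(k)) {
    h <- if (spec$types[j] == "rho") 1e-4 else
      max(abs(phi[j]) * 1e-4, stats::var(y) * 1e-7)
    up <- phi; up[j] <- up[j] + h
    dn <- phi; dn[j] <- dn[j] - h
    gu <- phi_to_gr(clip_phi(up, spec), spec)
    gd <- phi_to_gr(clip_phi(dn, spec), spec)
    dV <- (build_V(data, gu$g, gu$r) - build_V(data, gd$g, gd$r)) / (2 * h)
    a[, j] <- dV %*% Py
  }
  Pa <- apply(a, 2, Pfun)
  AI <- 0.5 * crossprod(a, Pa)
  AI <- (AI + t(AI)) / 2
  dimnames(AI) <- list(spec$names, spec$names)
  AI
}

# Keep perturbed natural parameters inside their admissible region so the
# finite-difference evaluation of V stays valid.
clip_phi <- function(phi, spec) {
  phi[spec$types == "var"] <- pmax(phi[spec$types == "var"], 0)
  phi[spec$types == "rho"] <- pmin(pmax(phi[spec$types == "rho"], -0.9999),
                                   0.9999)
  for (k in which(spec$types == "cov")) {
    nm <- spec$names[k]
    pair <- if (nm == "gcov") {
      if (spec$model == "univariate") c("gvar_s1", "gvar_s2")
      else c("gvar_t1", "gvar_t2")
    } else c("evar_t1", "evar_t2")
    nms <- stats::setNames(phi, spec$names)
    den <- sqrt(prod(nms[pair]))
    if (den > 0) phi[k] <- sign(phi[k]) * min(abs(phi[k]), den)
  }
  phi
}

compute_blups <- function(data, g, r) {
  V <- build_V(data, g, r)
  cv <- tryCatch(chol(V + diag(1e-10 * mean(diag(V)), nrow(V))),
                 error = function(e) NULL)
  if (is.null(cv)) return(NULL)
  Vsolve <- function(z) backsolve(cv, backsolve(cv, z, transpose = TRUE))
  ViX <- Vsolve(data$X)
  beta <- solve(crossprod(data$X, ViX), crossprod(data$X, Vsolve(data$y)))
  resid <- Vsolve(data$y - data$X %*% beta)
  n_groups <- if (data$model == "univariate") data$n_sites else 2L
  Sigma <- site_gen_cov_from(g, n_groups)
  G <- kronecker(Sigma, data$K)
  u <- drop(G[, data$u_idx, drop = FALSE] %*% resid)
  matrix(u, nrow = nrow(data$K), ncol = n_groups,
         dimnames = list(data$clone_ids,
                         if (data$model == "univariate")
                           paste0("site_", seq_len(n_groups))
                         else paste0("trait_", seq_len(n_groups))))
}

#' @export
print.vc_fit <- function(x, ...) {
  cat(sprintf("REML fit (%s): logLik = %.4f, %d free parameters\n",
              x$spec$model, x$loglik, length(x$estimates)))
  est <- data.frame(estimate = signif(x$estimates, 5),
                    se = signif(x$se, 3),
                    boundary = x$boundary)
  print(est)
  invisible(x)
}

#' Likelihood ratio test with boundary-aware reference distribution
#'
#' Statistic `2 (logLik_full - logLik_reduced)` clipped at zero. For a
#' single variance tested on its boundary the null is the equal mixture
#' `0.5 chi2_0 + 0.5 chi2_1`; for an interior covariance fixed at zero it is
#' `chi2_1`.
#'
#' @param full,reduced `vc_fit` objects (or raw log-likelihoods).
#' @param constraint `"variance_on_boundary"` or `"covariance_zero"`.
#' @return list with `statistic` and `p_value`.
#' @export
lrt <- function(full, reduced,
                constraint = c("variance_on_boundary", "covariance_zero")) {
  constraint <- match.arg(constraint)
  ll_f <- if (inherits(full, "vc_fit")) full$loglik else as.numeric(full)
  ll_r <- if (inherits(reduced, "vc_fit")) reduced$loglik else as.numeric(reduced)
  stat <- 2 * (ll_f - ll_r)
  if (stat < -1e-4 * max(1, abs(ll_f)))
    stop_bad_arg("reduced model has higher likelihood than the full model ",
                 "(statistic ", signif(stat, 4), "): optimizer failure")
  stat <- max(stat, 0)
  p <- if (constraint == "variance_on_boundary") {
    if (stat == 0) 1 else 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(statistic = stat, p_value = p)
}

#' Rank clones by their predicted genetic values
#'
#' @param fit a `vc_fit`.
#' @return a `clonal_ranking`: per-group data.frames sorted by BLUP
#'   (descending, ties broken by clone id) plus the Spearman rank
#'   correlation between groups and a flag when the genetic variance sits on
#'   the boundary (ranking non-informative).
#' @export
clonal_rankings <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  b <- fit$blups
  groups <- colnames(b)
  rk <- lapply(groups, function(g) {
    ord <- order(-b[, g], rownames(b))
    data.frame(rank = seq_len(nrow(b)), clone = rownames(b)[ord],
               blup = b[ord, g], row.names = NULL)
  })
  names(rk) <- groups
  rho <- if (length(groups) == 2L)
    stats::cor(b[, 1], b[, 2], method = "spearman") else NA_real_
  gb <- fit$boundary[grep("^gvar", names(fit$boundary))]
  structure(list(rankings = rk, spearman = rho,
                 non_informative = any(gb)),
            class = "clonal_ranking")
}
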