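# SNP quality control and the genomic relationship matrix.

#' Construct a SNP dosage matrix object
#'
#' @param dosages clones x SNPs matrix with entries in \{0, 1, 2, NA\}.
#' @param populations optional per-clone population labels.
#' @return a `snp_matrix`.
#' @export
snp_matrix <- function(dosages, populations = NULL) {
  dosages <- as.matrix(dosages)
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok))
    stop_bad_arg("dosages must be 0, 1, 2 or NA; found ",
                 paste(utils::head(unique(dosages[!ok]), 3), collapse = ", "))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("clone_%03d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp_%05d", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)) || anyDuplicated(colnames(dosages)))
    stop_bad_arg("duplicate clone or SNP identifiers")
  structure(list(dosages = dosages, populations = populations,
                 summaries = NULL),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("snp_matrix: %d clones x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Per-SNP summary statistics
#'
#' Populates call rate (non-missing fraction), allele frequency (mean dosage
#' over non-missing clones / 2), observed heterozygosity (fraction of
#' heterozygotes among non-missing) and the Hardy-Weinberg p-value for each
#' SNP. SNPs with no calls get call rate 0 and `NA` frequency — never a
#' silent 0.
#'
#' @param geno a `snp_matrix`.
#' @param hwe_method `"exact"` (default) or `"chi2"`.
#' @return the `snp_matrix` with a `summaries` data.frame attached.
#' @export
snp_summaries <- function(geno, hwe_method = c("exact", "chi2")) {
  stopifnot(inherits(geno, "snp_matrix"))
  hwe_method <- match.arg(hwe_method)
  d <- geno$dosages
  n_called <- colSums(!is.na(d))
  call_rate <- n_called / nrow(d)
  freq <- ifelse(n_called > 0, colMeans(d, na.rm = TRUE) / 2, NA_real_)
  n_het <- colSums(d == 1, na.rm = TRUE)
  n_hom_alt <- colSums(d == 2, na.rm = TRUE)
  n_hom_ref <- n_called - n_het - n_hom_alt
  het <- ifelse(n_called > 0, n_het / n_called, NA_real_)
  hwe_p <- mapply(function(a, h, b) {
    if (a + h + b < 1) return(NA_real_)
    hwe_test(a, h, b, method = hwe_method)
  }, n_hom_ref, n_het, n_hom_alt)
  geno$summaries <- data.frame(
    snp = colnames(d), call_rate = call_rate, freq = freq,
    maf = pmin(freq, 1 - freq), het = het, hwe_p = hwe_p,
    row.names = NULL)
  geno
}

#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' The exact test sums, over all heterozygote counts compatible with the
#' observed allele counts, the conditional probabilities that are no larger
#' than that of the observed table. The chi-square variant is the classical
#' 1-df goodness-of-fit test against expected HWE counts. Monomorphic input
#' returns p = 1 by convention.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @param method `"exact"` or `"chi2"`.
#' @return a p-value in \[0, 1\].
#' @export
hwe_test <- function(n_hom_ref, n_het, n_hom_alt,
                     method = c("exact", "chi2")) {
  method <- match.arg(method)
  cnt <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(cnt < 0) || any(cnt != floor(cnt)))
    stop_bad_arg("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n < 1) stop_bad_arg("at least one genotyped individual required")
  n_alt <- n_het + 2 * n_hom_alt
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  if (method == "chi2") {
    p <- n_alt / (2 * n)
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((cnt - expd)^2 / expd)
    return(stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
  # exact: log-probability of each possible heterozygote count h (same
  # parity as the minor-allele count), conditional on allele counts
  h_obs <- n_het
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  logp <- vapply(hs, function(h) {
    n_hom_min <- (n_minor - h) / 2
    n_hom_maj <- n - h - n_hom_min
    lgamma(n + 1) - lgamma(n_hom_min + 1) - lgamma(h + 1) -
      lgamma(n_hom_maj + 1) + h * log(2) +
      lgamma(n_minor + 1) + lgamma(2 * n - n_minor + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p_obs <- logp[match(h_obs, hs)]
  min(1, sum(exp(logp[logp <= p_obs + 1e-10])))
}

#' Filter SNPs on call rate, minor allele frequency, HWE and heterozygosity
#'
#' Retains exactly the SNPs with call rate >= `min_call_rate`, minor allele
#' frequency >= `min_maf`, HWE p-value >= `hwe_alpha`, and observed
#' heterozygosity <= `max_heterozygosity`. A removal log (first-failure and
#' any-failure tallies per criterion) is attached as the `filter_log`
#' attribute.
#'
#' @param geno a `snp_matrix` (summaries computed if absent).
#' @param min_call_rate,min_maf,hwe_alpha,max_heterozygosity thresholds in
#'   \[0, 1\].
#' @param hwe_method passed to [snp_summaries()].
#' @return the filtered `snp_matrix`.
#' @export
filter_snps <- function(geno, min_call_rate = 0.90, min_maf = 0.01,
                        hwe_alpha = 0.001, max_heterozygosity = 0.60,
                        hwe_method = "exact") {
  check_prob(c(min_call_rate, min_maf, hwe_alpha, max_heterozygosity),
             "filter thresholds")
  if (is.null(geno$summaries)) geno <- snp_summaries(geno, hwe_method)
  s <- geno$summaries
  fail <- cbind(
    call_rate = s$call_rate < min_call_rate,
    maf = is.na(s$maf) | s$maf < min_maf,
    hwe = !is.na(s$hwe_p) & s$hwe_p < hwe_alpha,
    het = !is.na(s$het) & s$het > max_heterozygosity)
  keep <- rowSums(fail) == 0
  if (!any(keep))
    stop_bad_arg("no SNPs survive filtering; review thresholds")
  first_fail <- apply(fail[!keep, , drop = FALSE], 1,
                      function(f) colnames(fail)[which(f)[1]])
  log <- list(
    n_in = nrow(s), n_out = sum(keep),
    any_failure = colSums(fail),
    first_failure = table(factor(first_fail, levels = colnames(fail))))
  out <- geno
  out$dosages <- geno$dosages[, keep, drop = FALSE]
  out$summaries <- s[keep, , drop = FALSE]
  attr(out, "filter_log") <- log
  out
}

#' Genomic relationship matrix (Yang et al. estimator)
#'
#' Off-diagonals: `A_jk = (1/m) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) /
#' (2 p_i (1 - p_i))`; diagonals: `A_jj = 1 + (1/m) sum_i (x_ij^2 -
#' (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`, with `p_i` the sample
#' allele frequency. Missing dosages are imputed to `2 p_i` for that SNP
#' only within this computation (an imputed dosage contributes exactly zero
#' to off-diagonal terms). SNPs with frequency within `min_freq_guard` of
#' fixation are excluded to avoid division blow-up.
#'
#' @param geno a `snp_matrix`.
#' @param min_freq_guard frequencies outside
#'   `(min_freq_guard, 1 - min_freq_guard)` are skipped (default 0.005).
#' @return a `grm`: list with `values` (symmetric clones x clones matrix),
#'   `clone_ids`, `n_snps_used`.
#' @export
grm_yang <- function(geno, min_freq_guard = 0.005) {
  stopifnot(inherits(geno, "snp_matrix"))
  d <- geno$dosages
  if (nrow(d) < 2) stop_bad_arg("GRM needs >= 2 clones")
  p <- colMeans(d, na.rm = TRUE) / 2
  use <- !is.na(p) & p > min_freq_guard & p < 1 - min_freq_guard
  if (sum(use) < 1) stop_bad_arg("no usable SNPs for the GRM")
  d <- d[, use, drop = FALSE]
  p <- p[use]
  m <- length(p)
  denom <- 2 * p * (1 - p)
  # centred, scaled dosages; NA -> 0 is exactly mean imputation to 2p
  W <- sweep(d, 2, 2 * p)
  W <- sweep(W, 2, sqrt(denom), "/")
  W[is.na(W)] <- 0
  A <- tcrossprod(W) / m
  # diagonal uses its own estimator (not the cross-product formula)
  X <- d
  Ximp <- X
  Ximp[is.na(Ximp)] <- 0
  impute_mask <- is.na(X)
  term <- sweep(Ximp^2 - sweep(Ximp, 2, 1 + 2 * p, "*"), 2, 2 * p^2, "+")
  # imputed entries contribute the value at x = 2p: (2p)^2 - (1+2p)(2p) + 2p^2
  if (any(impute_mask)) {
    at2p <- matrix(rep((2 * p)^2 - (1 + 2 * p) * (2 * p) + 2 * p^2,
                       each = nrow(X)), nrow(X), m)
    term[impute_mask] <- at2p[impute_mask]
  }
  diag(A) <- 1 + rowSums(sweep(term, 2, denom, "/")) / m
  dimnames(A) <- list(rownames(d), rownames(d))
  structure(list(values = A, clone_ids = rownames(d), n_snps_used = m,
                 stabilized = FALSE),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d clones, %d SNPs used, mean diag %.3f%s\n",
              nrow(x$values), x$n_snps_used, mean(diag(x$values)),
              if (isTRUE(x$stabilized)) " (stabilized)" else ""))
  invisible(x)
}

#' Stabilize a relationship matrix to be positive definite
#'
#' Adds `jitter` to the diagonal only when the smallest eigenvalue falls
#' below `jitter`; records whether stabilization occurred.
#'
#' @param grm a `grm` or plain symmetric matrix.
#' @param jitter small positive ridge (default 1e-6).
#' @return a `grm` with `stabilized` flag.
#' @export
stabilize_psd <- function(grm, jitter = 1e-6) {
  if (!inherits(grm, "grm")) {
    grm <- structure(list(values = as.matrix(grm),
                          clone_ids = rownames(grm) %||%
                            as.character(seq_len(nrow(as.matrix(grm)))),
                          n_snps_used = NA_integer_, stabilized = FALSE),
                     class = "grm")
  }
  M <- grm$values
  if (max(abs(M - t(M))) > 1e-8 * max(abs(M), 1))
    stop_bad_arg("matrix is not symmetric")
  ev_min <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < jitter) {
    grm$values <- M + diag(jitter - min(ev_min, 0), nrow(M))
    grm$stabilized <- TRUE
  }
  grm
}
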