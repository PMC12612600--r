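# Independent from-definition oracles used across the suite. These stay
# deliberately naive (explicit matrices, solve(), full enumeration) so they
# share no code path with the package implementation.

# Restricted log-likelihood straight from the definition, with the explicit
# REML projection matrix P = Vi - Vi X (X' Vi X)^-1 X' Vi.
naive_reml_loglik <- function(y, X, V) {
  n <- length(y); p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  ld_V <- determinant(V, logarithm = TRUE)$modulus
  ld_X <- determinant(XtViX, logarithm = TRUE)$modulus
  as.numeric(-0.5 * (ld_V + ld_X + t(y) %*% P %*% y + (n - p) * log(2 * pi)))
}

# Exact HWE p-value by full enumeration over heterozygote counts using
# choose() arithmetic (no recurrences, no lgamma).
enum_hwe_p <- function(a, h, b) {
  n <- a + h + b
  n_alt <- h + 2 * b
  n_minor <- min(n_alt, 2 * n - n_alt)
  if (n_minor == 0) return(1)
  hs <- seq(n_minor %% 2, n_minor, by = 2)
  probs <- sapply(hs, function(k) {
    hom_min <- (n_minor - k) / 2
    hom_maj <- n - k - hom_min
    # multinomial count of genotype assignments x 2^het allele orderings,
    # over the count of ways to place the minor alleles among 2n slots
    exp(lchoose(n, k) + lchoose(n - k, hom_min) + k * log(2) -
          lchoose(2 * n, n_minor))
  })
  p_obs <- probs[match(h, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# Elementwise Kronecker expansion by loops.
naive_kronecker <- function(A, B) {
  out <- matrix(0, nrow(A) * nrow(B), ncol(A) * ncol(B))
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    out[(i - 1) * nrow(B) + seq_len(nrow(B)),
        (j - 1) * ncol(B) + seq_len(ncol(B))] <- A[i, j] * B
  out
}

# Small relationship matrix from simulated markers, shared by many tests.
test_grm <- function(n_clones, n_snps = 800, seed = 42) {
  g <- simulate_genotypes(n_clones, n_snps, seed = seed)
  stabilize_psd(grm_yang(snp_summaries(g)))
}

# Compact single-site study for fitting tests.
quick_study <- function(n_clones = 20, n_ramets = 80, h2 = 0.3,
                        spatial = TRUE, seed = 7, K = NULL) {
  if (is.null(K)) K <- test_grm(n_clones, seed = seed + 500)
  sv <- if (spatial) (1 - h2) / 2 else 0
  nug <- if (spatial) (1 - h2) / 2 else 1 - h2
  cfg <- sim_config(n_clones = n_clones, ramets_per_site = n_ramets,
                    genetic_variance = h2, spatial_variance = sv,
                    nugget = nug, seed = seed)
  design <- simulate_orchard_design(cfg)
  study <- simulate_phenotypes(design, K, cfg)
  list(study = study, K = K, cfg = cfg)
}
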