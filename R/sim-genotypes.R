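#' Simulate a biallelic SNP dosage matrix for a set of clones
#'
#' Draws per-SNP allele frequencies from a Beta distribution rescaled to
#' (0.02, 0.5) — mimicking array-ascertained markers that are guaranteed
#' polymorphic — then samples genotype dosages as Binomial(2, p) per clone.
#' With more than one population, per-population frequencies are perturbed
#' around the ancestral frequency (Balding-Nichols model), creating mild
#' structure such as arises when plus trees are selected from different
#' stands.
#'
#' @param n_clones number of clones (rows), >= 2 for any downstream
#'   relationship matrix.
#' @param n_snps number of SNPs (columns).
#' @param maf_distribution two Beta shape parameters, or a single fixed
#'   allele frequency in (0, 1).
#' @param n_populations number of source populations.
#' @param pop_fst Balding-Nichols differentiation parameter.
#' @param populations optional integer vector assigning each clone to a
#'   population; defaults to a balanced round-robin assignment.
#' @param missing_rate fraction of dosages set missing at random (default 0).
#' @param seed integer seed; identical arguments and seed give identical
#'   matrices.
#'
#' @return a `snp_matrix`: integer matrix clones x SNPs with entries in
#'   \{0, 1, 2, NA\}, dimnames set, and a `populations` attribute.
#' @export
simulate_genotypes <- function(n_clones, n_snps,
                               maf_distribution = c(0.5, 0.5),
                               n_populations = 1L,
                               pop_fst = 0.02,
                               populations = NULL,
                               missing_rate = 0,
                               seed = 1L) {
  n_clones <- check_scalar_count(n_clones, "n_clones", min = 1L)
  n_snps <- check_scalar_count(n_snps, "n_snps", min = 1L)
  n_populations <- check_scalar_count(n_populations, "n_populations", min = 1L)
  if (is.null(populations)) {
    populations <- rep_len(seq_len(n_populations), n_clones)
  }
  with_seed(seed, {
    if (length(maf_distribution) == 1L) {
      p <- rep(maf_distribution, n_snps)
    } else {
      p <- 0.02 + 0.48 * stats::rbeta(n_snps, maf_distribution[1], maf_distribution[2])
    }
    dos <- matrix(NA_integer_, n_clones, n_snps)
    for (k in seq_len(n_populations)) {
      idx <- which(populations == k)
      if (!length(idx)) next
      pk <- p
      if (n_populations > 1L && pop_fst > 0) {
        a <- p * (1 - pop_fst) / pop_fst
        b <- (1 - p) * (1 - pop_fst) / pop_fst
        pk <- stats::rbeta(n_snps, a, b)
      }
      dos[idx, ] <- matrix(stats::rbinom(length(idx) * n_snps, 2L,
                                         rep(pk, each = length(idx))),
                           length(idx), n_snps)
    }
    if (missing_rate > 0) {
      miss <- stats::runif(length(dos)) < missing_rate
      dos[miss] <- NA_integer_
    }
    dimnames(dos) <- list(sprintf("clone_%03d", seq_len(n_clones)),
                          sprintf("snp_%05d", seq_len(n_snps)))
    snp_matrix(dos, populations = populations)
  })
}
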