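# Assembly of response, fixed-effect and random-effect structures for the
# REML engine.

# Merge population-within-site levels with a single observation into a
# catch-all level so the fixed-effect design stays estimable.
merge_singleton_pops <- function(pop, site) {
  lab <- paste(site, pop, sep = ":")
  tab <- table(lab)
  single <- names(tab)[tab == 1L]
  if (length(single)) {
    message("merging ", length(single),
            " single-observation population-within-site level(s)")
    lab[lab %in% single] <- paste(site[lab %in% single], "other", sep = ":")
  }
  lab
}

build_fixed_design <- function(site, pop = NULL, n_sites) {
  df <- data.frame(site = factor(site))
  form <- ~1
  if (n_sites > 1L) form <- ~site
  if (!is.null(pop) && length(unique(pop)) > 1L) {
    df$pop <- factor(merge_singleton_pops(pop, site))
    form <- if (n_sites > 1L) ~ site + pop else ~pop
  }
  X <- stats::model.matrix(form, df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- qx$pivot[-seq_len(qx$rank)]
    message("dropping ", length(drop), " aliased fixed-effect column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
  }
  X
}

#' Assemble model data for a univariate (single- or multi-site) genomic fit
#'
#' Builds the response vector, the fixed-effect design (overall mean, site,
#' population-within-site), the ramet-to-(clone x site) random-effect
#' mapping, and attaches the relationship matrix.
#'
#' @param phenotypes data.frame with columns `site`, `row`, `col`, `clone`
#'   (and optionally `population`) plus the trait column; typically the
#'   `phenotypes` element of a `sim_study` or a parsed trait table joined to
#'   the design.
#' @param trait name of the response column.
#' @param grm a `grm` whose clone ids cover the design's clones (matched by
#'   position for integer clones, by id otherwise).
#' @return a `model_data` list consumed by [fit_reml()] and
#'   [restricted_loglik()].
#' @export
model_data <- function(phenotypes, trait, grm) {
  stopifnot(is.data.frame(phenotypes))
  if (!trait %in% names(phenotypes))
    stop_bad_arg("response column '", trait, "' not found")
  design <- phenotypes[c("site", "row", "col", "clone",
                         intersect("population", names(phenotypes)))]
  class(design) <- c("orchard_design", "data.frame")
  validate_design(design)
  y <- phenotypes[[trait]]
  keep <- !is.na(y)
  y <- y[keep]; design <- design[keep, , drop = FALSE]
  K <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  clone_map <- match_clones(design$clone, grm, K)
  sites <- sort(unique(design$site))
  site_idx <- match(design$site, sites)
  n_sites <- length(sites)
  X <- build_fixed_design(site_idx, design$population, n_sites)
  nK <- nrow(K)
  structure(list(
    model = "univariate", y = y, X = X, design = design,
    K = K, clone_map = clone_map, site_idx = site_idx,
    n_sites = n_sites, u_idx = (site_idx - 1L) * nK + clone_map,
    clone_ids = rownames(K) %||% as.character(seq_len(nK))),
    class = "model_data")
}

match_clones <- function(clone, grm, K) {
  ids <- if (inherits(grm, "grm")) grm$clone_ids else rownames(K)
  if (is.numeric(clone) && max(clone) <= nrow(K) && min(clone) >= 1) {
    as.integer(clone)
  } else {
    m <- match(as.character(clone), ids)
    if (anyNA(m))
      stop_bad_arg("clones absent from the GRM: ",
                   paste(utils::head(unique(clone[is.na(m)]), 5), collapse = ", "))
    m
  }
}

#' Assemble model data for a bivariate genomic fit
#'
#' Stacks two responses (two traits, or the same trait in two years) over
#' the same design. Fixed effects are the per-response mean and, when
#' available, population within response. Residual covariance between the
#' two responses is estimated only for co-observed ramets; ramets with one
#' missing response still contribute to their own trait.
#'
#' @param phenotypes data.frame as in [model_data()] with two response
#'   columns.
#' @param traits character vector of the two response column names.
#' @param grm a `grm`.
#' @return a `model_data` of model type `"bivariate"`.
#' @export
model_data_bivariate <- function(phenotypes, traits, grm) {
  stopifnot(length(traits) == 2L, all(traits %in% names(phenotypes)))
  design <- phenotypes[c("site", "row", "col", "clone",
                         intersect("population", names(phenotypes)))]
  class(design) <- c("orchard_design", "data.frame")
  validate_design(design)
  K <- if (inherits(grm, "grm")) grm$values else as.matrix(grm)
  clone_map <- match_clones(design$clone, grm, K)
  y1 <- phenotypes[[traits[1]]]
  y2 <- phenotypes[[traits[2]]]
  obs1 <- !is.na(y1); obs2 <- !is.na(y2)
  if (sum(obs1) < 2L || sum(obs2) < 2L)
    stop_bad_arg("each response needs >= 2 observations")
  shared <- unique(clone_map[obs1 & obs2])
  if (length(unique(clone_map[obs1])) < 2L ||
      length(unique(clone_map[obs2])) < 2L)
    stop_bad_arg("each response needs >= 2 clones")
  if (length(intersect(unique(clone_map[obs1]), unique(clone_map[obs2]))) < 2L)
    stop_bad_arg("fewer than 2 clones shared between the responses")
  balanced <- all(obs1) && all(obs2)
  n <- nrow(design)
  trait_idx <- c(rep(1L, sum(obs1)), rep(2L, sum(obs2)))
  ramet_idx <- c(which(obs1), which(obs2))
  y <- c(y1[obs1], y2[obs2])
  pop <- design$population
  Xpop <- if (!is.null(pop) && length(unique(pop)) > 1L)
    pop[ramet_idx] else NULL
  X <- build_fixed_design(trait_idx, Xpop, n_sites = 2L)
  nK <- nrow(K)
  structure(list(
    model = "bivariate", y = y, X = X, design = design,
    K = K, clone_map = clone_map[ramet_idx], trait_idx = trait_idx,
    ramet_idx = ramet_idx, balanced = balanced, n_ramets = n,
    u_idx = (trait_idx - 1L) * nK + clone_map[ramet_idx],
    clone_ids = rownames(K) %||% as.character(seq_len(nK)),
    traits = traits),
    class = "model_data")
}
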