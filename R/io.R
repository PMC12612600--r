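# Readers and writers for the plain-text interchange formats: PLINK .raw
# additive dosages, genotype/GRM CSV, design and trait tables, spectra in
# wide and long layout.

#' Read genotypes from a PLINK .raw additive-dosage file
#'
#' Expects the standard header `FID IID PAT MAT SEX PHENOTYPE SNP1_A ...`
#' (whitespace-separated), dosages 0/1/2 with `NA` for missing. Clone ids
#' are taken from IID.
#'
#' @param path file path.
#' @return a `snp_matrix`.
#' @export
read_plink_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = c("NA", "-9"))
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(tab))
  if (!"IID" %in% meta) stop_bad_arg("not a PLINK .raw file: no IID column")
  d <- as.matrix(tab[setdiff(names(tab), meta)])
  rownames(d) <- as.character(tab$IID)
  colnames(d) <- sub("_[ACGT12]$", "", colnames(d))
  snp_matrix(d)
}

#' Write genotypes in PLINK .raw additive-dosage layout
#'
#' @param geno a `snp_matrix`.
#' @param path output path.
#' @export
write_plink_raw <- function(geno, path) {
  stopifnot(inherits(geno, "snp_matrix"))
  d <- geno$dosages
  out <- data.frame(FID = rownames(d), IID = rownames(d), PAT = 0, MAT = 0,
                    SEX = 0, PHENOTYPE = -9, check.names = FALSE)
  dos <- as.data.frame(d)
  names(dos) <- paste0(colnames(d), "_A")
  utils::write.table(cbind(out, dos), path, quote = FALSE, sep = " ",
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a clones-by-SNPs CSV (NA for missing)
#'
#' First column holds clone ids; remaining columns are SNP dosages.
#'
#' @param path file path.
#' @return a `snp_matrix`.
#' @export
read_genotype_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  d <- as.matrix(tab[-1])
  rownames(d) <- as.character(tab[[1]])
  snp_matrix(d)
}

#' Read genotypes from a VCF, reduced to additive dosages
#'
#' Counts alternate alleles in the GT field (0/0 -> 0, 0/1 -> 1, 1/1 -> 2;
#' missing stays `NA`). Samples become clones (rows). Requires the vcfR
#' package.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a `snp_matrix`.
#' @export
read_genotype_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_bad_arg("vcfR is required for VCF ingestion")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(a != "0")
  })
  ids <- v@fix[, "ID"]
  rownames(dos) <- ifelse(is.na(ids) | ids == ".",
                          paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"]), ids)
  snp_matrix(t(dos))
}

#' Write a relationship matrix as labeled square CSV
#' @param grm a `grm`.
#' @param path output path.
#' @export
write_grm_csv <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  tab <- data.frame(clone = grm$clone_ids, grm$values, check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a relationship matrix as id1/id2/value triplets (lower triangle)
#' @param grm a `grm`.
#' @param path output path.
#' @export
write_grm_triplet <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  idx <- which(lower.tri(grm$values, diag = TRUE), arr.ind = TRUE)
  tab <- data.frame(id1 = grm$clone_ids[idx[, 1]],
                    id2 = grm$clone_ids[idx[, 2]],
                    value = grm$values[idx])
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Read a labeled square GRM CSV written by [write_grm_csv()]
#' @param path file path.
#' @return a `grm`.
#' @export
read_grm_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(tab[-1])
  rownames(M) <- colnames(M) <- as.character(tab[[1]])
  structure(list(values = M, clone_ids = rownames(M),
                 n_snps_used = NA_integer_, stabilized = FALSE),
            class = "grm")
}

#' Write a spectra table as wide CSV (header = wavelengths in nm)
#' @param spectra a `spectra_table`.
#' @param path output path.
#' @export
write_spectra_wide <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_table"))
  tab <- data.frame(ramet = spectra$ramet_ids, spectra$reflectance,
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a wide-CSV spectra table
#' @param path file path.
#' @param level `"canopy"` or `"needle"`.
#' @return a `spectra_table`.
#' @export
read_spectra_wide <- function(path, level = "canopy") {
  tab <- utils::read.csv(path, check.names = FALSE)
  wl <- as.numeric(names(tab)[-1])
  if (anyNA(wl)) stop_bad_arg("non-numeric wavelength headers")
  spectra_table(tab[[1]], wl, as.matrix(tab[-1]), level = level)
}

#' Convert a spectra table to long format (ramet, wavelength, reflectance)
#' @param spectra a `spectra_table`.
#' @return data.frame in long layout.
#' @export
spectra_long <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_table"))
  data.frame(
    ramet = rep(spectra$ramet_ids, times = length(spectra$wavelengths)),
    wavelength = rep(spectra$wavelengths, each = length(spectra$ramet_ids)),
    reflectance = as.vector(spectra$reflectance))
}
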