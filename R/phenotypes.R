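# Needle functional traits and reflectance preprocessing.

#' Spectra table container
#'
#' @param ramet_ids identifiers, one per row.
#' @param wavelengths strictly increasing nm grid.
#' @param reflectance ramets x bands matrix.
#' @param level `"needle"` or `"canopy"`.
#' @return a `spectra_table`.
#' @export
spectra_table <- function(ramet_ids, wavelengths, reflectance,
                          level = c("canopy", "needle")) {
  level <- match.arg(level)
  reflectance <- as.matrix(reflectance)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop_bad_arg("wavelengths must be strictly increasing")
  if (length(wavelengths) != ncol(reflectance))
    stop_bad_arg("one wavelength per reflectance column required")
  if (length(ramet_ids) != nrow(reflectance))
    stop_bad_arg("one ramet id per reflectance row required")
  rownames(reflectance) <- as.character(ramet_ids)
  colnames(reflectance) <- as.character(wavelengths)
  structure(list(ramet_ids = as.character(ramet_ids),
                 wavelengths = as.numeric(wavelengths),
                 reflectance = reflectance, level = level),
            class = "spectra_table")
}

#' @export
print.spectra_table <- function(x, ...) {
  cat(sprintf("spectra_table (%s level): %d ramets x %d bands, %.0f-%.0f nm\n",
              x$level, nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Reflectance as the ratio of sample to white-reference radiance
#'
#' @param sample_radiance,white_radiance per-band radiance vectors on the
#'   same band grid; the white reference must be positive at every band.
#' @return per-band reflectance.
#' @export
reflectance_from_radiance <- function(sample_radiance, white_radiance) {
  if (length(sample_radiance) != length(white_radiance))
    stop_bad_arg("band grids differ in length")
  bad <- which(white_radiance <= 0)
  if (length(bad))
    stop_bad_arg("non-positive white-reference radiance at band(s) ",
                 paste(utils::head(bad, 5), collapse = ", "))
  sample_radiance / white_radiance
}

#' Median spectrum over repeated scans
#'
#' Per-band median over the scans (rows). With an even number of scans the
#' mean of the two middle values is used (the standard median convention).
#'
#' @param scans matrix scans x bands, or list of equal-length vectors.
#' @return per-band median vector.
#' @export
median_needle_spectrum <- function(scans) {
  if (is.list(scans)) {
    len <- lengths(scans)
    if (length(unique(len)) != 1L)
      stop_bad_arg("ragged band grids: scans have lengths ",
                   paste(unique(len), collapse = ", "))
    scans <- do.call(rbind, scans)
  }
  scans <- as.matrix(scans)
  if (nrow(scans) < 1L) stop_bad_arg("at least one scan required")
  apply(scans, 2, stats::median)
}

#' Smooth and trim canopy bands
#'
#' Removes the fluctuation affecting every second wavelength by replacing
#' band i with the mean of bands (i, i+1) (last band unchanged), then drops
#' the first `head_drop` and last `tail_drop` noisy bands. A 269-band input
#' with the default drops yields exactly 220 analysis bands.
#'
#' @param raw a `spectra_table`.
#' @param head_drop,tail_drop number of leading/trailing bands to remove
#'   (defaults 13 and 36).
#' @return a `spectra_table` with the retained wavelength range as the
#'   `range_nm` attribute.
#' @export
preprocess_canopy_bands <- function(raw, head_drop = 13L, tail_drop = 36L) {
  stopifnot(inherits(raw, "spectra_table"))
  n <- length(raw$wavelengths)
  if (n < head_drop + tail_drop + 1L)
    stop_bad_arg("too few bands: ", n, " <= ", head_drop + tail_drop)
  R <- raw$reflectance
  sm <- R
  if (n > 1L)
    sm[, seq_len(n - 1L)] <- (R[, seq_len(n - 1L)] + R[, 2:n]) / 2
  keep <- seq.int(head_drop + 1L, n - tail_drop)
  out <- spectra_table(raw$ramet_ids, raw$wavelengths[keep],
                       sm[, keep, drop = FALSE], level = raw$level)
  attr(out, "range_nm") <- range(out$wavelengths)
  out
}

#' Flag implausible reflectance values
#'
#' Marks cells outside `[0, limit]` and reports rows whose flagged fraction
#' exceeds `max_flagged`.
#'
#' @param spectra a `spectra_table`.
#' @param limit upper plausibility bound (default 1.1).
#' @param max_flagged per-row tolerated flagged fraction (default 0.05).
#' @return list with `flags` (logical matrix) and `bad_rows` (ramet ids).
#' @export
screen_reflectance <- function(spectra, limit = 1.1, max_flagged = 0.05) {
  stopifnot(inherits(spectra, "spectra_table"))
  flags <- spectra$reflectance < 0 | spectra$reflectance > limit
  frac <- rowMeans(flags)
  list(flags = flags, bad_rows = spectra$ramet_ids[frac > max_flagged])
}

#' Photosynthetic pigment concentrations from extract absorbances
#'
#' Applies the N,N-dimethylformamide solvent equations of Wellburn (1994)
#' after subtracting the 750 nm turbidity blank: chl a = 11.65 A'664 - 2.69
#' A'647; chl b = 20.81 A'647 - 4.53 A'664; carotenoids = (1000 A'480 - 0.89
#' chl a - 52.02 chl b) / 245 (all ug/mL). Concentrations are converted to
#' mg per g dry mass via the extract volume. Negative turbidity-corrected
#' absorbances are clipped to zero with a warning.
#'
#' @param a480,a647,a664,a750 absorbances (unitless optical densities).
#' @param extract_volume extract volume in mL.
#' @param dry_mass sample dry mass in g.
#' @return data.frame with `chl_a_M`, `chl_b_M`, `chl_T_M`, `car_M` (mg/g)
#'   and `car_chlT_ratio` (NA-flagged when total chlorophyll is zero).
#' @export
pigment_concentrations <- function(a480, a647, a664, a750 = 0,
                                   extract_volume, dry_mass) {
  if (any(c(a480, a647, a664, a750) < 0))
    stop_bad_arg("absorbances must be >= 0")
  if (any(extract_volume <= 0) || any(dry_mass <= 0))
    stop_bad_arg("extract volume and dry mass must be > 0")
  A480 <- a480 - a750; A647 <- a647 - a750; A664 <- a664 - a750
  if (any(c(A480, A647, A664) < 0)) {
    warning("turbidity-corrected absorbance below zero; clipped to 0")
    A480 <- pmax(A480, 0); A647 <- pmax(A647, 0); A664 <- pmax(A664, 0)
  }
  chl_a <- 11.65 * A664 - 2.69 * A647          # ug/mL
  chl_b <- 20.81 * A647 - 4.53 * A664
  car <- (1000 * A480 - 0.89 * chl_a - 52.02 * chl_b) / 245
  # ug/mL * mL / g = ug/g; /1000 -> mg/g
  to_mass <- extract_volume / dry_mass / 1000
  chl_a_M <- chl_a * to_mass
  chl_b_M <- chl_b * to_mass
  chl_T_M <- chl_a_M + chl_b_M
  car_M <- car * to_mass
  ratio <- ifelse(chl_T_M > 0, car_M / chl_T_M, NA_real_)
  data.frame(chl_a_M = chl_a_M, chl_b_M = chl_b_M, chl_T_M = chl_T_M,
             car_M = car_M, car_chlT_ratio = ratio)
}

#' Structural and water-related needle traits
#'
#' LMA = dry mass / projected area (g/cm^2); NWC = 100 (fresh - dry) /
#' fresh (percent of fresh mass); EWT = (fresh - dry) / projected area
#' (g/cm^2); needle length is passed through.
#'
#' @param fresh_mass,dry_mass masses in g (dry <= fresh required).
#' @param projected_area projected needle area in cm^2.
#' @param needle_length needle length in cm (optional pass-through).
#' @return data.frame with `LMA`, `NWC`, `EWT`, `NL`.
#' @export
structural_traits <- function(fresh_mass, dry_mass, projected_area,
                              needle_length = NA_real_) {
  if (any(dry_mass <= 0) || any(projected_area <= 0))
    stop_bad_arg("dry mass and projected area must be > 0")
  if (any(dry_mass > fresh_mass))
    stop_bad_arg("dry mass exceeds fresh mass: physically impossible input")
  data.frame(LMA = dry_mass / projected_area,
             NWC = 100 * (fresh_mass - dry_mass) / fresh_mass,
             EWT = (fresh_mass - dry_mass) / projected_area,
             NL = needle_length)
}

#' Convert mass-based pigment values to area basis
#'
#' `value_A (ug/cm^2) = value_M (mg/g) * LMA (g/cm^2) * 1000 (ug/mg)`.
#'
#' @param mass_based mg/g values (vector or data.frame of pigment columns).
#' @param LMA leaf mass per area in g/cm^2, > 0.
#' @return area-based values in ug/cm^2 (same shape as input).
#' @export
area_based_pigments <- function(mass_based, LMA) {
  if (any(LMA <= 0)) stop_bad_arg("LMA must be > 0")
  if (is.data.frame(mass_based)) {
    out <- mass_based
    out[] <- lapply(mass_based, function(v) v * LMA * 1000)
    names(out) <- sub("_M$", "_A", names(out))
    out
  } else mass_based * LMA * 1000
}

#' Assemble a needle functional trait table
#'
#' Combines pigment assays and structural measurements into the analysis
#' trait table with both mass- and area-based pigment values. Invariant
#' violations (negative values, chl_T mismatch) raise errors.
#'
#' @param pigments output of [pigment_concentrations()].
#' @param structure output of [structural_traits()].
#' @param ramet_ids identifiers, one per row of both inputs.
#' @return data.frame with one row per ramet and the standard NFT columns.
#' @export
nft_table <- function(pigments, structure, ramet_ids) {
  if (nrow(pigments) != nrow(structure) ||
      length(ramet_ids) != nrow(pigments))
    stop_bad_arg("pigments, structure and ramet_ids must align row-wise")
  area <- area_based_pigments(
    pigments[c("chl_a_M", "chl_b_M", "chl_T_M", "car_M")], structure$LMA)
  out <- cbind(data.frame(ramet = as.character(ramet_ids)),
               pigments[c("chl_a_M", "chl_b_M", "chl_T_M", "car_M")],
               area, pigments["car_chlT_ratio"], structure)
  num <- out[vapply(out, is.numeric, logical(1))]
  vals <- unlist(num[setdiff(names(num), "NL")])
  if (any(vals < -1e-12, na.rm = TRUE))
    stop_bad_arg("negative trait value in NFT table")
  if (any(abs(out$chl_T_M - out$chl_a_M - out$chl_b_M) > 1e-8, na.rm = TRUE) ||
      any(abs(out$chl_T_A - out$chl_a_A - out$chl_b_A) > 1e-6, na.rm = TRUE))
    stop_bad_arg("total chlorophyll is not the sum of chl a and chl b")
  if (any(out$NWC < 0 | out$NWC >= 100, na.rm = TRUE))
    stop_bad_arg("NWC outside [0, 100)")
  out
}
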