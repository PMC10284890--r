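# CDOM absorption and FDOM fluorescence indices.
#
# Spectra are stored as decadic absorbance; Napierian conversion (x 2.303)
# happens here. Interpolation is linear for absorbance and bilinear for EEMs,
# which is adequate on the ~1 nm grids these instruments produce.

.interp_abs <- function(spec, wavelength) {
  rng <- range(spec$wavelength_nm)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("wavelength %g nm outside spectrum range [%g, %g]",
                 wavelength[1], rng[1], rng[2]))
  stats::approx(spec$wavelength_nm, spec$absorbance, xout = wavelength)$y
}

#' Napierian absorption coefficient
#'
#' a(lambda) = 2.303 x A(lambda) / path length, with A linearly interpolated
#' between grid points. a(300) is the standard proxy for CDOM amount.
#'
#' @param spec An [absorbance_spectrum()].
#' @param wavelength Wavelength in nm (default 300).
#' @return Absorption coefficient in 1/m.
#' @export
napierian_a <- function(spec, wavelength = 300) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  2.303 * .interp_abs(spec, wavelength) / spec$path_length_m
}

#' DOC-specific UV absorbance at 254 nm
#'
#' SUVA254 = A(254) / (path length in m x DOC in mg C/L), a proxy for DOC
#' aromaticity, in L/(mg C x m).
#'
#' @param spec An [absorbance_spectrum()].
#' @param doc_mgC_L DOC concentration (mg C/L, > 0).
#' @return SUVA254.
#' @export
suva254 <- function(spec, doc_mgC_L) {
  stopifnot(inherits(spec, "absorbance_spectrum"))
  if (!is.numeric(doc_mgC_L) || doc_mgC_L <= 0)
    stop("DOC concentration must be positive")
  .interp_abs(spec, 254) / (spec$path_length_m * doc_mgC_L)
}

#' Spectral slope over a wavelength window
#'
#' Ordinary least squares of ln(absorbance) on wavelength over \[lo, hi\];
#' the negated slope is returned so that the usual exponential decline gives
#' a positive S (1/nm). A flat spectrum gives S = 0. At least five grid
#' points with positive absorbance are required.
#'
#' @param spec An [absorbance_spectrum()].
#' @param lo,hi Window bounds in nm.
#' @return Spectral slope S in 1/nm.
#' @export
spectral_slope <- function(spec, lo, hi) {
  stopifnot(inherits(spec, "absorbance_spectrum"), lo < hi)
  sel <- spec$wavelength_nm >= lo & spec$wavelength_nm <= hi &
    spec$absorbance > 0
  if (sum(sel) < 5)
    stop(sprintf(
      "fewer than 5 positive-absorbance points in [%g, %g] nm", lo, hi))
  x <- spec$wavelength_nm[sel]
  y <- log(spec$absorbance[sel])
  -unname(stats::coef(stats::lm(y ~ x))[2])
}

#' Spectral slope ratio
#'
#' S_R = S(275-295) / S(350-400); inversely related to DOM molecular weight.
#'
#' @param spec An [absorbance_spectrum()].
#' @return Dimensionless slope ratio.
#' @export
slope_ratio <- function(spec) {
  s1 <- spectral_slope(spec, 275, 295)
  s2 <- spectral_slope(spec, 350, 400)
  if (!is.finite(s2) || s2 == 0)
    stop("S(350-400) fit failed or is zero; slope ratio undefined")
  s1 / s2
}

.interp_eem <- function(e, ex, em) {
  if (ex < min(e$excitation_nm) || ex > max(e$excitation_nm) ||
      em < min(e$emission_nm) || em > max(e$emission_nm))
    stop(sprintf("EEM grid does not cover ex %g / em %g nm", ex, em))
  ix <- findInterval(ex, e$excitation_nm, all.inside = TRUE)
  iy <- findInterval(em, e$emission_nm, all.inside = TRUE)
  x1 <- e$excitation_nm[ix]; x2 <- e$excitation_nm[ix + 1]
  y1 <- e$emission_nm[iy]; y2 <- e$emission_nm[iy + 1]
  tx <- if (x2 > x1) (ex - x1) / (x2 - x1) else 0
  ty <- if (y2 > y1) (em - y1) / (y2 - y1) else 0
  (1 - tx) * (1 - ty) * e$intensity[ix, iy] +
    tx * (1 - ty) * e$intensity[ix + 1, iy] +
    (1 - tx) * ty * e$intensity[ix, iy + 1] +
    tx * ty * e$intensity[ix + 1, iy + 1]
}

#' Biological index (BIX)
#'
#' Emission intensity at 380 nm divided by that at 430 nm, both at 310 nm
#' excitation (bilinear interpolation on the EEM grid). An indicator of
#' recent autochthonous DOM production.
#'
#' @param e An [eem()].
#' @return Dimensionless BIX.
#' @export
bix <- function(e) {
  stopifnot(inherits(e, "eem"))
  den <- .interp_eem(e, 310, 430)
  if (den <= 0) stop("BIX undefined: zero intensity at ex 310 / em 430")
  .interp_eem(e, 310, 380) / den
}

.trapz_band <- function(em_grid, row, lo, hi) {
  # trapezoid integral of the emission row over [lo, hi], with the band
  # endpoints added by linear interpolation
  xs <- sort(unique(c(lo, hi, em_grid[em_grid > lo & em_grid < hi])))
  ys <- stats::approx(em_grid, row, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Humification index (HIX)
#'
#' Integrated emission over 435-480 nm divided by integrated emission over
#' 300-445 nm, at 254 nm excitation (the overlapping-band Zsolnay form).
#' The excitation row nearest 254 nm within +/- 2 nm is used; band integrals
#' are trapezoidal.
#'
#' @param e An [eem()].
#' @return Dimensionless HIX.
#' @export
hix <- function(e) {
  stopifnot(inherits(e, "eem"))
  d <- abs(e$excitation_nm - 254)
  if (min(d) > 2)
    stop("no excitation row within 2 nm of 254 nm")
  row <- e$intensity[which.min(d), ]
  if (min(e$emission_nm) > 300 || max(e$emission_nm) < 480)
    stop("emission grid must cover 300-480 nm")
  den <- .trapz_band(e$emission_nm, row, 300, 445)
  if (den <= 0) stop("HIX undefined: zero emission over 300-445 nm")
  .trapz_band(e$emission_nm, row, 435, 480) / den
}

#' All optical indices for one sample
#'
#' @param spec An [absorbance_spectrum()].
#' @param doc_mgC_L DOC concentration (mg C/L) for SUVA254.
#' @param e Optional [eem()] for BIX/HIX (`NA` returned when absent).
#' @return One-row data frame: `a300_per_m`, `suva254`, `s275_295`,
#'   `s350_400`, `sr`, `bix`, `hix`.
#' @export
optical_summary <- function(spec, doc_mgC_L, e = NULL) {
  s1 <- spectral_slope(spec, 275, 295)
  s2 <- spectral_slope(spec, 350, 400)
  data.frame(
    a300_per_m = napierian_a(spec, 300),
    suva254 = suva254(spec, doc_mgC_L),
    s275_295 = s1, s350_400 = s2,
    sr = if (s2 != 0) s1 / s2 else NA_real_,
    bix = if (is.null(e)) NA_real_ else bix(e),
    hix = if (is.null(e)) NA_real_ else hix(e)
  )
}
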