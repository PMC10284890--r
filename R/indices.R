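# Per-formula molecular indices and the four-class compound taxonomy.
#
# DBE    = 1 + (2C - H + N)/2
# NOSC   = 4 - (4C + H - 3N - 2O - 2S)/C
# AImod  = (1 + C - O/2 - S - (N + H)/2) / (C - O/2 - N - S)
#
# Classes, evaluated with CA > Pol > Uns > Ali precedence:
#   CA  (combustion-derived polycyclic aromatics)    AImod > 0.66
#   Pol (vascular plant-derived polyphenols)          0.50 < AImod <= 0.66
#   Uns (highly unsaturated and phenolic)             AImod <= 0.50, H/C < 1.5
#   Ali (aliphatics)                                  1.5 <= H/C <= 2.0
#   Other                                             residual 2.0 < H/C < 2.2

#' Double bond equivalence
#'
#' Rings-plus-double-bonds count of a CHONS composition.
#'
#' @param c,h,n Atom counts (vectorised).
#' @return Numeric vector.
#' @export
dbe <- function(c, h, n = 0) {
  stopifnot(all(c >= 1))
  1 + (2 * c - h + n) / 2
}

#' Nominal oxidation state of carbon
#'
#' Average carbon oxidation state inferred from stoichiometry; more positive
#' values indicate more oxidised material.
#'
#' @param c,h,o,n,s Atom counts (vectorised).
#' @return Numeric vector in \[-4, 4\] for valence-sensible formulas.
#' @export
nosc <- function(c, h, o = 0, n = 0, s = 0) {
  stopifnot(all(c >= 1))
  4 - (4 * c + h - 3 * n - 2 * o - 2 * s) / c
}

#' Modified aromaticity index
#'
#' Conservative lower bound on aromatic character, treating half the oxygen
#' as carbonyl-like. When the AI carbon denominator or the numerator is
#' non-positive the raw value is not a meaningful aromaticity and the index
#' is clamped to 0 (the conventional treatment); values above 1 are returned
#' as computed (they can only arise for hydrogen-poor compositions outside
#' the usual H/C filter) and can be detected by comparison with 1.
#'
#' @param c,h,o,n,s Atom counts (vectorised).
#' @return Numeric vector, >= 0.
#' @export
ai_mod <- function(c, h, o = 0, n = 0, s = 0) {
  stopifnot(all(c >= 1))
  num <- 1 + c - o / 2 - s - (n + h) / 2
  den <- c - o / 2 - n - s
  out <- ifelse(den <= 0 | num <= 0, 0, num / den)
  out
}

#' Compound-class labels
#'
#' @return Character vector of the five labels in precedence order.
#' @export
compound_classes <- function() c("CA", "Pol", "Uns", "Ali", "Other")

#' Classify formulas into the four compound classes
#'
#' Thresholds are applied in decreasing order of aromaticity so that every
#' composition receives exactly one label; compositions with 2.0 < H/C < 2.2
#' fall outside the four printed classes and are labelled `Other`.
#'
#' @param c,h,o,n,s Atom counts (vectorised).
#' @return Character vector of class labels.
#' @export
classify_formula <- function(c, h, o = 0, n = 0, s = 0) {
  ai <- ai_mod(c, h, o, n, s)
  hc <- h / c
  out <- rep("Other", length(ai))
  out[ai > 0.66] <- "CA"
  out[ai <= 0.66 & ai > 0.50] <- "Pol"
  out[ai <= 0.50 & hc < 1.5] <- "Uns"
  out[ai <= 0.50 & hc >= 1.5 & hc <= 2.0] <- "Ali"
  out
}

#' Attach molecular indices to a formula table
#'
#' @param f Formula table with columns `c`, `h`, `o`, `n`, `s`.
#' @return `f` with added columns `dbe`, `nosc`, `ai_mod`, `class`.
#' @export
formula_indices <- function(f) {
  f$dbe <- dbe(f$c, f$h, f$n)
  f$nosc <- nosc(f$c, f$h, f$o, f$n, f$s)
  f$ai_mod <- ai_mod(f$c, f$h, f$o, f$n, f$s)
  f$class <- classify_formula(f$c, f$h, f$o, f$n, f$s)
  f
}

# --- annotated sample --------------------------------------------------------

#' Build an annotated sample from a per-peak assignment table
#'
#' Collapses assigned peaks onto distinct formulas (summing intensities with
#' a warning when two peaks map to the same formula), attaches molecular
#' indices and total/relative intensities.
#'
#' @param sample_id Sample identifier.
#' @param assignments Per-peak assignment data frame as produced by
#'   [assign_peaklist()].
#' @return An object of class `annotated_sample`.
#' @export
annotated_sample_from_assignments <- function(sample_id, assignments) {
  ok <- !is.na(assignments$formula)
  f <- assignments[ok, c("formula", "c", "h", "o", "n", "s", "mass",
                         "intensity", "snr", "mass_error_ppm"), drop = FALSE]
  if (nrow(f) > 0 && anyDuplicated(f$formula)) {
    warning("multiple peaks assigned to one formula; intensities summed")
    agg <- stats::aggregate(intensity ~ formula, data = f, FUN = sum)
    first <- f[!duplicated(f$formula), , drop = FALSE]
    first$intensity <- agg$intensity[match(first$formula, agg$formula)]
    f <- first
  }
  f <- formula_indices(f)
  f$hc <- f$h / f$c
  f$oc <- f$o / f$c
  total <- sum(f$intensity)
  f$rel_intensity <- if (total > 0) f$intensity / total else rep(0, nrow(f))
  rownames(f) <- NULL
  structure(list(sample_id = sample_id,
                 assignments = assignments,
                 formulas = f,
                 total_intensity = total),
            class = "annotated_sample")
}

#' Construct an annotated sample directly from formulas and intensities
#'
#' Convenience constructor used by the synthetic generator and in tests,
#' bypassing peak-level assignment.
#'
#' @param sample_id Sample identifier.
#' @param f Formula table (columns `formula`, `c`, `h`, `o`, `n`, `s`,
#'   `mass`) as from [molecular_formula()].
#' @param intensity Positive intensities, one per formula.
#' @return An `annotated_sample`.
#' @export
annotated_sample <- function(sample_id, f, intensity) {
  stopifnot(nrow(f) == length(intensity), all(intensity > 0),
            !anyDuplicated(f$formula))
  a <- f
  a$intensity <- intensity
  a$snr <- NA_real_
  a$mass_error_ppm <- 0
  annotated_sample_from_assignments(
    sample_id,
    cbind(a, data.frame(rejection_reason = NA_character_))
  )
}

.weighted_mean <- function(x, w) sum(x * w) / sum(w)

.weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  i <- which(cw >= 0.5)[1]
  # midpoint convention at an exact 0.5 crossing, matching stats::median
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1]) / 2
  else x[i]
}

#' Summarise the molecular composition of an annotated sample
#'
#' Reports the formula count, mean and median of DBE, NOSC, AImod and H/C,
#' the intensity-weighted relative abundance of each compound class and the
#' class ratios Uns/Ali, Pol/Ali, CA/Ali. By default index means/medians are
#' unweighted and class shares are intensity-weighted (both estimators are
#' available).
#'
#' @param sample An `annotated_sample`.
#' @param index_weighting `"none"` (default) or `"intensity"` for the index
#'   means and medians.
#' @param share_weighting `"intensity"` (default) or `"none"` for the class
#'   relative abundances.
#' @return A list with elements `n_formulas`, `mean`, `median` (named vectors
#'   over dbe/nosc/ai_mod/hc), `class_share` (named over all classes, sums to
#'   1) and `class_ratio` (Uns_Ali, Pol_Ali, CA_Ali).
#' @export
summarize_sample <- function(sample,
                             index_weighting = c("none", "intensity"),
                             share_weighting = c("intensity", "none")) {
  index_weighting <- match.arg(index_weighting)
  share_weighting <- match.arg(share_weighting)
  f <- sample$formulas
  if (nrow(f) == 0) stop("no formulas in sample")
  iw <- if (index_weighting == "intensity") f$intensity else rep(1, nrow(f))
  sw <- if (share_weighting == "intensity") f$intensity else rep(1, nrow(f))
  vars <- c(dbe = "dbe", nosc = "nosc", ai_mod = "ai_mod", hc = "hc")
  means <- vapply(vars, function(v) .weighted_mean(f[[v]], iw), numeric(1))
  medians <- vapply(vars, function(v) .weighted_median(f[[v]], iw),
                    numeric(1))
  share <- vapply(compound_classes(),
                  function(cl) sum(sw[f$class == cl]) / sum(sw), numeric(1))
  ratio <- c(Uns_Ali = unname(share["Uns"] / share["Ali"]),
             Pol_Ali = unname(share["Pol"] / share["Ali"]),
             CA_Ali = unname(share["CA"] / share["Ali"]))
  list(n_formulas = nrow(f), mean = means, median = medians,
       class_share = share, class_ratio = ratio)
}
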