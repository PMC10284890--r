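# Partition formulas into produced / degraded / unchanged sets from paired
# sample comparisons (dark vs light-exposed, or pre vs post incubation).
#
# The dual-threshold rule: a shared formula counts as produced (degraded)
# only when BOTH its raw-intensity relative change AND its total-normalised
# relative-intensity change exceed +frac (fall below -frac). Formulas present
# in only one member of the pair are produced/degraded by presence alone.

.intensity_map <- function(sample) {
  stats::setNames(sample$formulas$intensity, sample$formulas$formula)
}

.diff_table <- function(reference, treated, status, dr, drel) {
  ref_f <- reference$formulas
  trt_f <- treated$formulas
  all_f <- union(ref_f$formula, trt_f$formula)
  src <- rbind(trt_f[, c("formula", "class", "ai_mod", "dbe", "nosc", "hc")],
               ref_f[, c("formula", "class", "ai_mod", "dbe", "nosc", "hc")])
  src <- src[!duplicated(src$formula), , drop = FALSE]
  out <- src[match(all_f, src$formula), , drop = FALSE]
  out$status <- status[all_f]
  out$delta_raw_frac <- dr[all_f]
  out$delta_rel_frac <- drel[all_f]
  rownames(out) <- NULL
  out[, c("formula", "status", "delta_raw_frac", "delta_rel_frac",
          "class", "ai_mod", "dbe", "nosc", "hc")]
}

.differential_set <- function(reference, treated, status, dr, drel, method) {
  tab <- .diff_table(reference, treated, status, dr, drel)
  structure(list(
    reference_id = reference$sample_id,
    treated_id = treated$sample_id,
    method = method,
    produced = tab$formula[tab$status == "produced"],
    degraded = tab$formula[tab$status == "degraded"],
    unchanged = tab$formula[tab$status == "unchanged"],
    table = tab
  ), class = "differential_set")
}

#' Differential formulas by the dual 20% intensity-change rule
#'
#' Formulas present only in the treated sample are produced, those present
#' only in the reference are degraded. A shared formula is produced when both
#' its raw-intensity ratio and its total-normalised relative-intensity ratio
#' (treated over reference) exceed `1 + frac`, and degraded when both fall
#' below `1 / (1 + frac)`; anything else is unchanged. Thresholding the
#' ratio, rather than the signed percent change, makes the rule exactly
#' symmetric: swapping the two samples swaps produced and degraded, and
#' letting `frac` grow without bound recovers the presence/absence method on
#' shared formulas.
#'
#' @param reference,treated `annotated_sample` objects from the same
#'   assignment settings (e.g. dark control and light-exposed water).
#' @param frac Change threshold as a fraction (default 0.20); any positive
#'   value is allowed.
#' @return A `differential_set`: produced/degraded/unchanged formula vectors,
#'   the method token and a per-formula table with both change fractions
#'   (reported as signed changes relative to the reference) and molecular
#'   indices.
#' @export
compare_threshold <- function(reference, treated, frac = 0.20) {
  stopifnot(inherits(reference, "annotated_sample"),
            inherits(treated, "annotated_sample"),
            frac > 0)
  if (identical(reference$sample_id, treated$sample_id))
    stop("reference and treated must be different samples")
  ir <- .intensity_map(reference)
  it <- .intensity_map(treated)
  all_f <- union(names(ir), names(it))
  rr <- ir[all_f]; tt <- it[all_f]
  names(rr) <- names(tt) <- all_f
  rir <- rr / reference$total_intensity
  rit <- tt / treated$total_intensity
  status <- stats::setNames(rep("unchanged", length(all_f)), all_f)
  dr <- stats::setNames(rep(NA_real_, length(all_f)), all_f)
  drel <- dr
  only_t <- is.na(rr)
  only_r <- is.na(tt)
  both <- !only_t & !only_r
  status[only_t] <- "produced"
  status[only_r] <- "degraded"
  dr[both] <- (tt[both] - rr[both]) / rr[both]
  drel[both] <- (rit[both] - rir[both]) / rir[both]
  ratio_raw <- tt / rr
  ratio_rel <- rit / rir
  status[both & ratio_raw > 1 + frac & ratio_rel > 1 + frac] <- "produced"
  status[both & ratio_raw < 1 / (1 + frac) &
           ratio_rel < 1 / (1 + frac)] <- "degraded"
  .differential_set(reference, treated, status, dr, drel, "threshold20")
}

#' Differential formulas by presence/absence
#'
#' The cross-validation method: produced formulas are those only present in
#' the treated sample, degraded only in the reference; shared formulas are
#' unchanged regardless of intensity.
#'
#' @inheritParams compare_threshold
#' @return A `differential_set`.
#' @export
compare_presence_absence <- function(reference, treated) {
  stopifnot(inherits(reference, "annotated_sample"),
            inherits(treated, "annotated_sample"))
  if (identical(reference$sample_id, treated$sample_id))
    stop("reference and treated must be different samples")
  fr <- reference$formulas$formula
  ft <- treated$formulas$formula
  all_f <- union(fr, ft)
  status <- stats::setNames(rep("unchanged", length(all_f)), all_f)
  status[setdiff(ft, fr)] <- "produced"
  status[setdiff(fr, ft)] <- "degraded"
  dr <- stats::setNames(rep(NA_real_, length(all_f)), all_f)
  .differential_set(reference, treated, status, dr, dr, "presence_absence")
}

.set_summary_indices <- function(dset, label) {
  tab <- dset$table
  sub <- tab[tab$status == label, , drop = FALSE]
  if (nrow(sub) == 0)
    return(c(ai_mod = NA_real_, dbe = NA_real_, nosc = NA_real_,
             hc = NA_real_))
  c(ai_mod = mean(sub$ai_mod), dbe = mean(sub$dbe),
    nosc = mean(sub$nosc), hc = mean(sub$hc))
}

#' Concordance between the threshold and presence/absence methods
#'
#' For each differential label, reports the per-pair Jaccard index of the
#' formula sets and (given at least three pairs) the Pearson correlation of
#' per-set mean molecular indices (AImod, DBE, NOSC, H/C) across pairs.
#'
#' @param a,b Lists of `differential_set` objects of equal length, the i-th
#'   elements coming from the same sample pair analysed with two methods.
#'   A single pair may be given directly (not in a list).
#' @return A list with `jaccard` (labels x pairs matrix), `mean_jaccard`
#'   (named by label) and `correlation` (named by label; `NA` with fewer than
#'   3 pairs).
#' @export
method_concordance <- function(a, b) {
  if (inherits(a, "differential_set")) a <- list(a)
  if (inherits(b, "differential_set")) b <- list(b)
  stopifnot(length(a) == length(b), length(a) >= 1)
  labels <- c("produced", "degraded", "unchanged")
  jac <- sapply(seq_along(a), function(i) {
    vapply(labels, function(lab) {
      sa <- a[[i]][[lab]]; sb <- b[[i]][[lab]]
      u <- length(union(sa, sb))
      if (u == 0) 1 else length(intersect(sa, sb)) / u
    }, numeric(1))
  })
  jac <- matrix(jac, nrow = length(labels),
                dimnames = list(labels, NULL))
  corr <- stats::setNames(rep(NA_real_, length(labels)), labels)
  if (length(a) >= 3) {
    for (lab in labels) {
      ia <- t(vapply(a, .set_summary_indices, numeric(4), label = lab))
      ib <- t(vapply(b, .set_summary_indices, numeric(4), label = lab))
      ok <- stats::complete.cases(ia) & stats::complete.cases(ib)
      if (sum(ok) >= 3) {
        va <- as.vector(ia[ok, , drop = FALSE])
        vb <- as.vector(ib[ok, , drop = FALSE])
        if (stats::sd(va) > 0 && stats::sd(vb) > 0)
          corr[lab] <- stats::cor(va, vb)
      }
    }
  }
  list(jaccard = jac, mean_jaccard = rowMeans(jac), correlation = corr)
}

#' Aromaticity overlap of photo-produced, photo-degraded and bio-degraded sets
#'
#' For each lake, reports the median AImod of the photo-produced (PP),
#' photo-degraded (PD) and bio-degraded (BD) formula sets, two-sided Wilcoxon
#' rank-sum p-values for the PP-BD and PD-BD contrasts (omitted when a set
#' has fewer than two values), and which pair has the smaller absolute median
#' difference -- the overlap diagnostic separating lakes where sunlight
#' produces, versus removes, the compounds microbes consume.
#'
#' @param pp,pd,bd Named lists (lake -> numeric vector of per-formula AImod
#'   values) for the three sets; names must match across the three lists.
#' @return Data frame with one row per lake: medians, p-values and
#'   `overlaps_with` (`"PP"` or `"PD"`). Lakes with an empty set are skipped
#'   with a warning.
#' @export
set_overlap_analysis <- function(pp, pd, bd) {
  lakes <- names(pp)
  stopifnot(!is.null(lakes), identical(sort(lakes), sort(names(pd))),
            identical(sort(lakes), sort(names(bd))))
  rows <- lapply(lakes, function(lk) {
    x_pp <- pp[[lk]]; x_pd <- pd[[lk]]; x_bd <- bd[[lk]]
    if (length(x_pp) == 0 || length(x_pd) == 0 || length(x_bd) == 0) {
      warning(sprintf("lake '%s' skipped: empty differential set", lk))
      return(NULL)
    }
    m_pp <- stats::median(x_pp); m_pd <- stats::median(x_pd)
    m_bd <- stats::median(x_bd)
    p_pp_bd <- if (length(x_pp) >= 2 && length(x_bd) >= 2)
      group_rank_test(x_pp, x_bd)$p_value else NA_real_
    p_pd_bd <- if (length(x_pd) >= 2 && length(x_bd) >= 2)
      group_rank_test(x_pd, x_bd)$p_value else NA_real_
    data.frame(lake_id = lk,
               median_pp = m_pp, median_pd = m_pd, median_bd = m_bd,
               gap_pp_bd = abs(m_pp - m_bd), gap_pd_bd = abs(m_pd - m_bd),
               p_pp_bd = p_pp_bd, p_pd_bd = p_pd_bd,
               overlaps_with = if (abs(m_pp - m_bd) <= abs(m_pd - m_bd))
                 "PP" else "PD",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
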