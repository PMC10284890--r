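# Molecular formula assignment for negative-ESI FT-ICR MS peak lists.
#
# All peaks are treated as singly charged deprotonated ions [M-H]-.
# Monoisotopic masses are IUPAC/CODATA values; carbon is exactly 12 by
# definition of the unified atomic mass scale.

#' Monoisotopic masses used throughout the package
#'
#' Named vector of exact monoisotopic masses (Da) for C, H, O, N, S plus the
#' proton mass used for the \eqn{[M-H]^-} ion convention.
#'
#' @format Named numeric vector.
#' @export
ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503207,
  O = 15.99491461956,
  N = 14.0030740048,
  S = 31.97207100,
  proton = 1.00727646677
)

#' Exact neutral monoisotopic mass of a CHONS composition
#'
#' @param c,h,o,n,s Integer atom counts (vectorised).
#' @return Numeric vector of neutral monoisotopic masses in Da.
#' @export
formula_mass <- function(c, h, o = 0, n = 0, s = 0) {
  12 * c + ATOMIC_MASS[["H"]] * h + ATOMIC_MASS[["O"]] * o +
    ATOMIC_MASS[["N"]] * n + ATOMIC_MASS[["S"]] * s
}

#' Construct a table of molecular formulas
#'
#' Builds a validated data frame of CHONS compositions with the derived
#' columns used by the rest of the package: exact neutral mass, H/C and O/C
#' ratios, heteroatom count and a Hill-order formula string.
#'
#' @param c,h,o,n,s Non-negative integer atom counts (vectorised; `n` and `s`
#'   must be 0 or 1).
#' @return A `data.frame` with columns `formula`, `c`, `h`, `o`, `n`, `s`,
#'   `mass`, `hc`, `oc`, `heteroatoms`.
#' @export
molecular_formula <- function(c, h, o = 0, n = 0, s = 0) {
  len <- max(length(c), length(h), length(o), length(n), length(s))
  c <- rep_len(as.integer(c), len); h <- rep_len(as.integer(h), len)
  o <- rep_len(as.integer(o), len); n <- rep_len(as.integer(n), len)
  s <- rep_len(as.integer(s), len)
  if (any(c < 1)) stop("formula must contain at least one carbon")
  if (any(h < 0 | o < 0)) stop("atom counts must be non-negative")
  if (any(n > 1 | n < 0 | s > 1 | s < 0))
    stop("N and S counts are restricted to 0 or 1")
  data.frame(
    formula = hill_formula(c, h, o, n, s),
    c = c, h = h, o = o, n = n, s = s,
    mass = formula_mass(c, h, o, n, s),
    hc = h / c, oc = o / c,
    heteroatoms = n + s,
    stringsAsFactors = FALSE
  )
}

#' Hill-order formula strings (C, H, then other elements alphabetically)
#'
#' @inheritParams formula_mass
#' @return Character vector, e.g. `"C16H32O2"`, `"C10H15NO4S"`.
#' @export
hill_formula <- function(c, h, o = 0, n = 0, s = 0) {
  piece <- function(sym, k) {
    ifelse(k == 0, "", ifelse(k == 1, sym, paste0(sym, k)))
  }
  paste0(piece("C", c), piece("H", h), piece("N", n), piece("O", o),
         piece("S", s))
}

#' Neutral mass of the molecule behind an [M-H]- ion
#'
#' Converts an observed mass-to-charge ratio to the neutral monoisotopic mass
#' under the deprotonated, singly charged ion convention standard for
#' negative-ESI DOM analysis.
#'
#' @param mz Observed m/z (Th), vectorised.
#' @param charge Ion charge; only 1 is supported.
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass_from_mz <- function(mz, charge = 1L) {
  if (!identical(as.integer(charge), 1L))
    stop("only singly charged [M-H]- ions are supported")
  if (any(mz <= 0)) stop("m/z must be positive")
  mz + ATOMIC_MASS[["proton"]]
}

#' Enumerate all CHONS formula candidates for a neutral mass
#'
#' Exhaustively enumerates elemental compositions C(>=1) H O N(0-1) S(0-1)
#' whose exact mass lies within a relative tolerance of the target neutral
#' mass. Oxygen runs from 0 to `floor(mass / 15.994)` and carbon from 1 to
#' `floor(mass / 12)`; the hydrogen count is solved from the mass balance and
#' rounded to the nearest integer (at sub-2-ppm tolerances no second hydrogen
#' value can fall inside the window, since one hydrogen is ~1250 ppm at
#' 800 Da).
#'
#' @param neutral_mass Target neutral monoisotopic mass (Da), in (50, 1000).
#' @param tol_ppm Relative mass tolerance in ppm, in (0, 2].
#' @return A formula table as from [molecular_formula()] with an extra
#'   `mass_error_ppm` column (signed, candidate minus target), sorted by
#'   `c`, `h`, `o`, `n`, `s`. May have zero rows.
#' @export
enumerate_candidates <- function(neutral_mass, tol_ppm) {
  stopifnot(length(neutral_mass) == 1, neutral_mass > 50, neutral_mass < 1000,
            tol_ppm > 0, tol_ppm <= 2)
  grid <- expand.grid(
    c = seq_len(floor(neutral_mass / 12)),
    o = 0:floor(neutral_mass / 15.994),
    n = 0:1, s = 0:1,
    KEEP.OUT.ATTRS = FALSE
  )
  rem <- neutral_mass - 12 * grid$c - ATOMIC_MASS[["O"]] * grid$o -
    ATOMIC_MASS[["N"]] * grid$n - ATOMIC_MASS[["S"]] * grid$s
  h <- round(rem / ATOMIC_MASS[["H"]])
  ok <- h >= 0
  grid <- grid[ok, , drop = FALSE]
  h <- h[ok]
  err_ppm <- (formula_mass(grid$c, h, grid$o, grid$n, grid$s) - neutral_mass) /
    neutral_mass * 1e6
  keep <- abs(err_ppm) <= tol_ppm
  out <- molecular_formula(grid$c[keep], h[keep], grid$o[keep],
                           grid$n[keep], grid$s[keep])
  out$mass_error_ppm <- err_ppm[keep]
  out <- out[order(out$c, out$h, out$o, out$n, out$s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Elemental-ratio and mass-window rules for formula filtering
#'
#' H/C bounds are exclusive, the O/C bound is exclusive, and the neutral-mass
#' window is inclusive, matching standard DOM assignment practice
#' (0.3 < H/C < 2.2, O/C < 1.2, 100-800 Da). A valence sanity rule
#' DBE >= 0 (i.e. H <= 2C + N + 2) is always applied: compositions more
#' hydrogen-rich than a fully saturated acyclic molecule cannot exist.
#'
#' @param hc_min,hc_max Exclusive bounds on H/C.
#' @param oc_max Exclusive upper bound on O/C.
#' @param mass_min,mass_max Inclusive neutral-mass window (Da).
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(hc_min = 0.3, hc_max = 2.2, oc_max = 1.2,
                         mass_min = 100, mass_max = 800) {
  stopifnot(hc_min < hc_max, oc_max > 0, mass_min < mass_max)
  structure(list(hc_min = hc_min, hc_max = hc_max, oc_max = oc_max,
                 mass_min = mass_min, mass_max = mass_max),
            class = "filter_rules")
}

#' Apply elemental-ratio and mass-window rules to candidate formulas
#'
#' @param candidates Formula table (from [enumerate_candidates()] or
#'   [molecular_formula()]).
#' @param rules A [filter_rules()] object.
#' @return The subset of `candidates` passing all rules.
#' @export
filter_candidates <- function(candidates, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  keep <- candidates$hc > rules$hc_min & candidates$hc < rules$hc_max &
    candidates$oc < rules$oc_max &
    candidates$mass >= rules$mass_min & candidates$mass <= rules$mass_max &
    candidates$h <= 2 * candidates$c + candidates$n + 2
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pick a unique formula by the least-heteroatom rule
#'
#' When several candidate formulas fit a peak within tolerance, the one with
#' the fewest non-oxygen heteroatoms (N + S) is retained; ties on the
#' heteroatom count are broken by the smallest absolute mass error, and a
#' residual exact tie is reported as ambiguous rather than resolved
#' arbitrarily.
#'
#' @param candidates Formula table carrying a `mass_error_ppm` column.
#' @return A list with elements `formula` (one-row formula table or `NULL`)
#'   and `rejection_reason` (`NA`, `"no_candidate"` or `"ambiguous"`).
#' @export
disambiguate <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0)
    return(list(formula = NULL, rejection_reason = "no_candidate"))
  het <- candidates$heteroatoms
  pool <- candidates[het == min(het), , drop = FALSE]
  aerr <- abs(pool$mass_error_ppm)
  pool <- pool[aerr == min(aerr), , drop = FALSE]
  if (nrow(pool) > 1)
    return(list(formula = NULL, rejection_reason = "ambiguous"))
  rownames(pool) <- NULL
  list(formula = pool, rejection_reason = NA_character_)
}

# --- cached library of all rule-passing formulas -----------------------------

.domphoto_cache <- new.env(parent = emptyenv())

#' Enumerate every CHONS formula passing the assignment rules
#'
#' Vectorised exhaustive enumeration of all C(>=1) H O N(0-1) S(0-1)
#' compositions whose neutral mass lies inside `rules$mass_min`..
#' `rules$mass_max` and which satisfy the H/C and O/C bounds. Used both as
#' the fast lookup table for [assign_peaklist()] and as the sampling space of
#' the synthetic-data generator. The result is cached per rule set.
#'
#' @param rules A [filter_rules()] object.
#' @return Formula table sorted by `mass`.
#' @export
enumerate_formula_space <- function(rules = filter_rules()) {
  key <- paste(unlist(rules), collapse = "|")
  hit <- .domphoto_cache[[key]]
  if (!is.null(hit)) return(hit)
  c_max <- floor(rules$mass_max / 12)
  parts <- vector("list", 4)
  i <- 0
  for (n in 0:1) for (s in 0:1) {
    base_ns <- ATOMIC_MASS[["N"]] * n + ATOMIC_MASS[["S"]] * s
    co <- expand.grid(c = seq_len(c_max),
                      o = 0:floor(rules$mass_max / ATOMIC_MASS[["O"]]),
                      KEEP.OUT.ATTRS = FALSE)
    co <- co[co$o < rules$oc_max * co$c - 1e-9, , drop = FALSE]
    base <- 12 * co$c + ATOMIC_MASS[["O"]] * co$o + base_ns
    co <- co[base <= rules$mass_max, , drop = FALSE]
    base <- base[base <= rules$mass_max]
    h_lo <- floor(rules$hc_min * co$c + 1e-9) + 1
    h_hi <- pmin(ceiling(rules$hc_max * co$c - 1e-9) - 1,
                 2 * co$c + n + 2,
                 floor((rules$mass_max - base) / ATOMIC_MASS[["H"]]))
    n_h <- pmax(h_hi - h_lo + 1, 0)
    keep <- n_h > 0
    idx <- rep(which(keep), n_h[keep])
    h <- sequence(n_h[keep]) - 1 + h_lo[idx]
    mass <- base[idx] + ATOMIC_MASS[["H"]] * h
    inwin <- mass >= rules$mass_min
    i <- i + 1
    parts[[i]] <- data.frame(c = co$c[idx][inwin], h = h[inwin],
                             o = co$o[idx][inwin], n = n, s = s,
                             mass = mass[inwin])
  }
  lib <- do.call(rbind, parts)
  lib <- lib[order(lib$mass), , drop = FALSE]
  lib$hc <- lib$h / lib$c
  lib$oc <- lib$o / lib$c
  lib$heteroatoms <- lib$n + lib$s
  lib$formula <- hill_formula(lib$c, lib$h, lib$o, lib$n, lib$s)
  rownames(lib) <- NULL
  .domphoto_cache[[key]] <- lib
  lib
}

#' Assign molecular formulas to a peak list
#'
#' Runs the full assignment chain for each peak: S/N gate, m/z-to-neutral-mass
#' conversion, exhaustive candidate enumeration, elemental-ratio filtering and
#' least-heteroatom disambiguation. Internally the enumeration+filter step is
#' served from a precomputed sorted table of all rule-passing formulas
#' ([enumerate_formula_space()]), which yields identical results to running
#' [enumerate_candidates()] then [filter_candidates()] per peak because the
#' rules do not depend on the peak.
#'
#' @param pl A [peaklist()].
#' @param tol_ppm Assignment mass tolerance in ppm (default 1).
#' @param snr_min Peaks with S/N at or below this value are skipped with
#'   reason `"low_snr"` (default 4).
#' @param rules A [filter_rules()] object.
#' @return An object of class `annotated_sample`: list with `sample_id`,
#'   `assignments` (one row per peak: peak fields, formula fields or `NA`,
#'   `mass_error_ppm`, `candidates_considered`, `rejection_reason`) and
#'   `formulas` (one row per distinct assigned formula with summed
#'   `intensity`, `rel_intensity` and molecular indices).
#' @export
assign_peaklist <- function(pl, tol_ppm = 1.0, snr_min = 4.0,
                            rules = filter_rules()) {
  stopifnot(inherits(pl, "peaklist"), tol_ppm > 0, tol_ppm <= 2)
  lib <- enumerate_formula_space(rules)
  pk <- pl$peaks
  np <- nrow(pk)
  res <- data.frame(
    mz = pk$mz, intensity = pk$intensity, snr = pk$snr,
    formula = NA_character_, c = NA_integer_, h = NA_integer_,
    o = NA_integer_, n = NA_integer_, s = NA_integer_,
    mass = NA_real_, mass_error_ppm = NA_real_,
    candidates_considered = 0L,
    rejection_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  if (np > 0) {
    nm <- neutral_mass_from_mz(pk$mz)
    lo <- findInterval(nm * (1 - tol_ppm * 1e-6) - 1e-9, lib$mass) + 1L
    hi <- findInterval(nm * (1 + tol_ppm * 1e-6) + 1e-9, lib$mass)
    # plain-vector views of the library: the per-peak loop below implements
    # the same least-heteroatom / smallest-error rule as disambiguate()
    l_mass <- lib$mass; l_het <- lib$heteroatoms
    pick <- rep(NA_integer_, np)
    err <- rep(NA_real_, np)
    for (i in seq_len(np)) {
      if (pk$snr[i] <= snr_min) {
        res$rejection_reason[i] <- "low_snr"
        next
      }
      if (hi[i] < lo[i]) {
        res$rejection_reason[i] <- "no_candidate"
        next
      }
      idx <- lo[i]:hi[i]
      e <- (l_mass[idx] - nm[i]) / nm[i] * 1e6
      ok <- abs(e) <= tol_ppm
      idx <- idx[ok]; e <- e[ok]
      res$candidates_considered[i] <- length(idx)
      if (length(idx) == 0) {
        res$rejection_reason[i] <- "no_candidate"
        next
      }
      het <- l_het[idx]
      best_het <- het == min(het)
      idx <- idx[best_het]; e <- e[best_het]
      ae <- abs(e)
      best <- ae == min(ae)
      if (sum(best) > 1) {
        res$rejection_reason[i] <- "ambiguous"
        next
      }
      pick[i] <- idx[best]
      err[i] <- e[best]
    }
    hit <- !is.na(pick)
    res$formula[hit] <- lib$formula[pick[hit]]
    res$c[hit] <- lib$c[pick[hit]]; res$h[hit] <- lib$h[pick[hit]]
    res$o[hit] <- lib$o[pick[hit]]; res$n[hit] <- lib$n[pick[hit]]
    res$s[hit] <- lib$s[pick[hit]]
    res$mass[hit] <- lib$mass[pick[hit]]
    res$mass_error_ppm[hit] <- err[hit]
  }
  annotated_sample_from_assignments(pl$sample_id, res)
}
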